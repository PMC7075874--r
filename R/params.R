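#' NLARI model parameters
#'
#' Bundle the physiological parameters of the NLARI heart-rate process:
#' the disturbance mean \eqn{\omega} and standard deviation \eqn{\sigma}
#' (log-HR units per beat), the resistance coefficient \eqn{\alpha > 0}
#' (myocardial electrical resistance), the restoration coefficient
#' \eqn{\beta \ge 0} (relative PNS-versus-SNS activity) and the
#' restoration lag \eqn{\kappa_2}.  The resistance lag \eqn{\kappa_1}
#' is fixed to 1, the form in which the process equations are stated.
#'
#' @param omega mean of the disturbances (log-HR units per step).
#' @param sigma standard deviation of the disturbances, `>= 0`.
#' @param alpha resistance coefficient, `> 0`.
#' @param beta restoration coefficient, `>= 0`; `beta = 0` removes the
#'   restoring force and leaves a unit-root process.
#' @param kappa2 restoration lag, a positive integer (default 1).
#'
#' @return An object of class `nlari_params`.
#' @seealso [derived_params()], [classify_regime()], [simulate_nlari()]
#' @examples
#' p <- nlari_params(omega = 1e-4, sigma = 0.0275, alpha = 0.7786, beta = 0.3)
#' derived_params(p)$gamma
#' @export
nlari_params <- function(omega = 0, sigma = 0.0275, alpha = 0.7786,
                         beta = 0.3, kappa2 = 1L) {
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta),  length(beta)  == 1L, is.finite(beta))
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  kappa2 <- as.integer(kappa2)
  if (is.na(kappa2) || kappa2 < 1L) stop("`kappa2` must be a positive integer", call. = FALSE)
  structure(list(omega = omega, sigma = sigma, alpha = alpha, beta = beta,
                 kappa1 = 1L, kappa2 = kappa2),
            class = "nlari_params")
}

#' @export
print.nlari_params <- function(x, ...) {
  cat("NLARI parameters\n")
  cat(sprintf("  omega = %g, sigma = %g, alpha = %g, beta = %g, kappa2 = %d\n",
              x$omega, x$sigma, x$alpha, x$beta, x$kappa2))
  d <- try(derived_params(x), silent = TRUE)
  if (!inherits(d, "try-error")) {
    cat(sprintf("  gamma = %s, eta1 = %g, eta2 = %s\n",
                format(d$gamma), d$eta1,
                if (is.na(d$eta2)) "undefined (beta = 0)" else format(d$eta2)))
  }
  invisible(x)
}

#' Derived NLARI quantities
#'
#' Map the physiological parameters to the autoregressive coefficients
#' and summary indicators: \eqn{\theta_0 = \omega}, \eqn{\theta_1 = 1 - \alpha},
#' \eqn{\theta_2 = \beta}, the stability coefficient
#' \eqn{\gamma = \beta / (4 - 2\alpha)}, the slope indicator
#' \eqn{\eta_1 = \omega / \alpha} (slope of the mean log-HR line per beat)
#' and the amplitude indicator \eqn{\eta_2 = \sigma / \beta}.
#'
#' @param p an [nlari_params()] object.
#' @return A list with components `theta0`, `theta1`, `theta2`, `gamma`,
#'   `eta1` and `eta2`.  `eta2` is `NA` (undefined) when `beta = 0`.
#' @examples
#' derived_params(nlari_params(alpha = 1, beta = 2))$gamma  # exactly 1
#' @export
derived_params <- function(p) {
  stopifnot(inherits(p, "nlari_params"))
  if (p$alpha == 2)
    stop("gamma is undefined for alpha = 2 (division by zero in beta/(4 - 2*alpha))",
         call. = FALSE)
  list(theta0 = p$omega,
       theta1 = 1 - p$alpha,
       theta2 = p$beta,
       gamma  = p$beta / (4 - 2 * p$alpha),
       eta1   = p$omega / p$alpha,
       eta2   = if (p$beta > 0) p$sigma / p$beta else NA_real_)
}

#' Classify the dynamical regime of an NLARI process
#'
#' The stability coefficient \eqn{\gamma = \beta/(4 - 2\alpha)} controls
#' the deterministic skeleton: the origin is an exponentially
#' asymptotically stable fixed point for \eqn{0 < \gamma < 1}, a stable
#' period-two cycle \eqn{(-1)^t \sqrt{\ln\gamma}} exists for
#' \eqn{1 < \gamma < \sqrt{e}}, and the dynamics are unstable for
#' \eqn{\gamma > \sqrt{e}}.  With `beta = 0` the restoring force vanishes
#' and the process is a nonstationary unit-root process.  The intervals
#' are open; the boundary values \eqn{\gamma = 1} and
#' \eqn{\gamma = \sqrt{e}} are reported with `boundary = TRUE` and
#' labelled by the regime they close.
#'
#' @param p an [nlari_params()] object.
#' @return A list with `label` (one of `"unit_root"`,
#'   `"stable_fixed_point"`, `"stable_two_cycle"`, `"unstable"`),
#'   `gamma`, and `boundary` (logical).
#' @export
classify_regime <- function(p) {
  stopifnot(inherits(p, "nlari_params"))
  if (p$beta == 0)
    return(list(label = "unit_root", gamma = 0, boundary = FALSE))
  g <- derived_params(p)$gamma
  sqrt_e <- sqrt(exp(1))
  if (g < 0) {
    # alpha > 2 makes the denominator negative; outside the stated theory
    label <- "unstable"; boundary <- FALSE
  } else if (g == 1) {
    label <- "stable_fixed_point"; boundary <- TRUE
  } else if (g == sqrt_e) {
    label <- "stable_two_cycle"; boundary <- TRUE
  } else if (g < 1) {
    label <- "stable_fixed_point"; boundary <- FALSE
  } else if (g < sqrt_e) {
    label <- "stable_two_cycle"; boundary <- FALSE
  } else {
    label <- "unstable"; boundary <- FALSE
  }
  list(label = label, gamma = g, boundary = boundary)
}

#' Amplitude of the period-two cycle
#'
#' For \eqn{\gamma > 1} the noise-free NLARI map (with unit lags) has a
#' period-two cycle alternating between \eqn{\pm\sqrt{\ln\gamma}}.
#'
#' @param gamma stability coefficient, `>= 1`.
#' @return `sqrt(log(gamma))`; at `gamma = 1` the amplitude is 0 and the
#'   result carries attribute `boundary = TRUE`.
#' @examples
#' two_cycle_amplitude(exp(1))  # 1
#' @export
two_cycle_amplitude <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma < 1)
    stop("the two-period cycle exists only for gamma > 1", call. = FALSE)
  if (gamma == 1) return(structure(0, boundary = TRUE))
  sqrt(log(gamma))
}

# beta that produces a given gamma at fixed alpha (inverts gamma = beta/(4-2*alpha))
beta_for_gamma <- function(gamma, alpha) {
  stopifnot(alpha > 0, alpha < 2)
  gamma * (4 - 2 * alpha)
}
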