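#' OLS fit of the NLARI difference equation
#'
#' Estimates \eqn{(\theta_1, \theta_2)} in the differenced form
#' \deqn{\Delta Y_t = \theta_1 \Delta Y_{t-1}
#'      + \theta_2 (-Y_{t-\kappa_2} e^{-Y_{t-\kappa_2}^2}) + \varepsilon_t}
#' by the normal equations
#' \eqn{\hat\theta = (Y'Y)^{-1} Y'y}, together with the classical
#' standard errors \eqn{s_i = \hat\sigma \sqrt{[(Y'Y)^{-1}]_{ii}}}, the
#' residual standard deviation
#' \eqn{\hat\sigma = \sqrt{\mathrm{RSS}/(n-2)}} and the delta-method
#' standard error of \eqn{\hat\gamma = \hat\theta_2 / (2(1+\hat\theta_1))}.
#' The first `max(3, kappa2 + 2) - 1` observations are lost as presample;
#' `rows_used` reports the effective regression length that plays the
#' role of \eqn{n} in all degrees-of-freedom formulas.
#'
#' @param y detrended log-HR series (e.g. `detrend(...)$y`).
#' @param kappa2 restoration lag used in the regressor (default 1).
#' @return An object of class `nlari_fit` with components `theta1_hat`,
#'   `theta2_hat`, `s1`, `s2`, `sigma_hat`, `gamma_hat`,
#'   `sigma_gamma_hat`, `rss`, `rows_used`, `kappa2`, `xtx_inv`, and the
#'   regression `residuals`.
#' @export
fit_nlari <- function(y, kappa2 = 1L) {
  if (inherits(y, "trend_fit")) y <- y$y
  stopifnot(is.numeric(y))
  kappa2 <- as.integer(kappa2)
  start <- max(3L, kappa2 + 2L)
  n <- length(y)
  if (n - start + 1L <= 2L)
    stop("not enough rows after presample loss (need > 2)", call. = FALSE)
  t <- start:n
  dy  <- y[t] - y[t - 1L]
  dy1 <- y[t - 1L] - y[t - 2L]
  yk  <- y[t - kappa2]
  X <- cbind(dy1, -yk * exp(-yk^2))
  m <- length(t)

  # Columns can differ in scale by many orders of magnitude when Y strays
  # from the active range of the restoring kernel; normalise before solving.
  cn <- sqrt(colSums(X^2))
  if (any(cn == 0) || any(!is.finite(cn)))
    stop("degenerate design matrix (a regressor is identically zero)",
         call. = FALSE)
  Xs <- sweep(X, 2L, cn, "/")
  xtx_s <- crossprod(Xs)
  inv_s <- tryCatch(solve(xtx_s), error = function(e)
    stop("rank-deficient design matrix", call. = FALSE))
  theta <- unname(drop(inv_s %*% crossprod(Xs, dy)) / cn)
  xtx_inv <- unname(inv_s / tcrossprod(cn))

  res <- dy - drop(X %*% theta)
  rss <- sum(res^2)
  sigma_hat <- sqrt(rss / (m - 2))
  s1 <- sigma_hat * sqrt(xtx_inv[1L, 1L])
  s2 <- sigma_hat * sqrt(xtx_inv[2L, 2L])
  gamma_hat <- theta[2L] / (2 * (1 + theta[1L]))
  v <- c(-2 * gamma_hat, 1)
  sigma_gamma_hat <- 0.5 * sigma_hat / (1 + theta[1L]) *
    sqrt(drop(t(v) %*% xtx_inv %*% v))

  structure(list(theta1_hat = theta[1L], theta2_hat = theta[2L],
                 s1 = s1, s2 = s2, sigma_hat = sigma_hat,
                 gamma_hat = gamma_hat, sigma_gamma_hat = sigma_gamma_hat,
                 rss = rss, rows_used = m, kappa2 = kappa2,
                 xtx_inv = xtx_inv, residuals = res),
            class = "nlari_fit")
}

#' @export
print.nlari_fit <- function(x, ...) {
  cat(sprintf("NLARI OLS fit (kappa2 = %d, rows used = %d)\n",
              x$kappa2, x$rows_used))
  cat(sprintf("  theta1 = %.5f (s1 = %.5f)\n", x$theta1_hat, x$s1))
  cat(sprintf("  theta2 = %.5f (s2 = %.5f)\n", x$theta2_hat, x$s2))
  cat(sprintf("  sigma  = %.5g, gamma = %.5f (se %.5f)\n",
              x$sigma_hat, x$gamma_hat, x$sigma_gamma_hat))
  invisible(x)
}

# Map an OLS fit + trend slope to the physiological parameter estimates.
map_hr_estimates <- function(fit, b_hat) {
  list(omega_hat = b_hat * (1 - fit$theta1_hat),
       alpha_hat = 1 - fit$theta1_hat,
       beta_hat  = fit$theta2_hat,
       gamma_hat = fit$gamma_hat,
       eta1_hat  = b_hat,
       eta2_hat  = fit$sigma_hat / fit$theta2_hat,
       sigma_hat = fit$sigma_hat)
}

# Detrend an already-log-scale series and run the full estimation.
estimate_from_x <- function(x, kappa2 = 1L) {
  tr <- detrend(x)
  fit <- fit_nlari(tr$y, kappa2 = kappa2)
  structure(c(map_hr_estimates(fit, tr$b_hat),
              list(fit = fit, trend = tr, n = length(x))),
            class = "nlari_estimate")
}

#' Estimate NLARI heart-rate parameters from a beat series
#'
#' Full estimation pipeline: log-transform (`to_log_hr()`), removal of
#' the OLS trend line (`detrend()`), OLS fit of the differenced model
#' (`fit_nlari()`), and the parameter mapping
#' \eqn{\hat\alpha = 1 - \hat\theta_1}, \eqn{\hat\beta = \hat\theta_2},
#' \eqn{\hat\gamma = \hat\theta_2/(2(1+\hat\theta_1))},
#' \eqn{\hat\omega = \hat b (1 - \hat\theta_1)},
#' \eqn{\hat\eta_1 = \hat b}, \eqn{\hat\eta_2 = \hat\sigma/\hat\theta_2}.
#'
#' @param series numeric beat values, or an `hr_series` from
#'   [to_log_hr()] / [read_beat_series()] (then `kind` is ignored).
#' @param kind `"rr_seconds"` or `"hr_bpm"`.
#' @param kappa2 restoration lag (default 1).
#' @return An object of class `nlari_estimate`: the seven mapped
#'   estimates plus the underlying `fit` (class `nlari_fit`) and
#'   `trend` (class `trend_fit`).
#' @examples
#' s <- simulate_nlari(nlari_params(), n = 900, seed = 3)
#' est <- estimate_nlari(60 / exp(s$x), kind = "rr_seconds")
#' c(est$alpha_hat, est$beta_hat)
#' @export
estimate_nlari <- function(series, kind = c("rr_seconds", "hr_bpm"),
                           kappa2 = 1L) {
  h <- if (inherits(series, "hr_series")) series else to_log_hr(series, kind)
  estimate_from_x(h$x, kappa2 = kappa2)
}

#' @export
print.nlari_estimate <- function(x, ...) {
  cat("NLARI parameter estimates\n")
  cat(sprintf("  alpha = %.4f  beta = %.4f  gamma = %.4f\n",
              x$alpha_hat, x$beta_hat, x$gamma_hat))
  cat(sprintf("  omega = %.3g  sigma = %.4g  eta1 = %.3g  eta2 = %.4g\n",
              x$omega_hat, x$sigma_hat, x$eta1_hat, x$eta2_hat))
  invisible(x)
}
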