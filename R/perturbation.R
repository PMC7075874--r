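#' Block-mean aggregation of a series
#'
#' Enlarges the observation scale by averaging consecutive
#' non-overlapping blocks:
#' \eqn{Y^{(m)}_t = m^{-1} \sum_{i=1}^m Y_{(t-1)m+i}} for
#' \eqn{t = 1, \dots, \lfloor T/m \rfloor}.  A trailing remainder
#' shorter than `m` is dropped.
#'
#' @param y numeric series.
#' @param m block length (positive integer, `<= length(y)`).
#' @return Numeric vector of length `floor(length(y)/m)`.
#' @examples
#' aggregate_series(1:10, 3)  # 2 5 8
#' @export
aggregate_series <- function(y, m) {
  stopifnot(is.numeric(y))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer", call. = FALSE)
  if (m > length(y)) stop("`m` exceeds the series length", call. = FALSE)
  if (m == 1L) return(y)
  tm <- length(y) %/% m
  colMeans(matrix(y[seq_len(tm * m)], nrow = m))
}

# Average the mapped parameter estimates over seeded replicates of a
# (possibly disturbed) NLARI simulation.
average_estimates <- function(p, omega_i, sigma_i, n, reps, seeds, x0) {
  acc <- matrix(NA_real_, nrow = reps, ncol = 7L,
                dimnames = list(NULL, c("omega", "alpha", "beta", "gamma",
                                        "sigma", "eta1", "eta2")))
  for (r in seq_len(reps)) {
    s <- simulate_disturbed(p, omega_i = omega_i, sigma_i = sigma_i,
                            n = n, x0 = x0, seed = seeds[r])
    e <- estimate_from_x(s$x, kappa2 = p$kappa2)
    acc[r, ] <- c(e$omega_hat, e$alpha_hat, e$beta_hat, e$gamma_hat,
                  e$sigma_hat, e$eta1_hat, e$eta2_hat)
  }
  colMeans(acc)
}

#' Sensitivity of HR parameter estimates to input disturbances
#'
#' Local sensitivity of each estimated parameter \eqn{\phi} to a shift
#' in the disturbance mean (`kind = "mean_shift"`, grid of
#' \eqn{\omega_i}) or in the disturbance standard deviation
#' (`kind = "sd_shift"`, grid of \eqn{\sigma_i}), by the ratio of
#' relative changes:
#' \deqn{S(\omega_i, \phi) = |(\phi_i - \phi)\,\omega / (\omega_i \phi)|,
#'  \quad
#'  S(\sigma_i, \phi) = |(\phi_i - \phi)\,\sigma /
#'   [(\sqrt{\sigma^2 + \sigma_i^2} - \sigma)\,\phi]|}
#' where \eqn{\phi_i} is the parameter estimate averaged over `reps`
#' seeded replicates of the disturbed process.  Mean shifts report
#' \eqn{\phi \in \{\alpha, \beta, \gamma, \sigma, \eta_2\}}; sd shifts
#' report \eqn{\phi \in \{\omega, \alpha, \beta, \gamma, \eta_1\}}.
#' Values classify as `perfectly_insensitive` (S = 0), `insensitive`
#' (S < 1), `unit_sensitive` (S = 1) or `sensitive` (S > 1).
#'
#' @param p base [nlari_params()]; for mean shifts the base `omega`
#'   must be nonzero.
#' @param kind `"mean_shift"` or `"sd_shift"`.
#' @param grid perturbation values (\eqn{\omega_i} or \eqn{\sigma_i}),
#'   all nonzero.
#' @param n series length per replicate (default 900).
#' @param reps replicates per grid point (default 300).
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param x0 baseline level passed to the simulator.
#' @param baseline `"simulated"` (default) compares the disturbed
#'   average estimate with the undisturbed average estimate over the
#'   same number of replicates, so finite-sample estimator bias cancels;
#'   `"params"` compares with the generating parameter values.
#' @return A `data.frame` of class `nlari_sensitivity` with one row per
#'   (grid value, parameter): the base value `phi`, disturbed average
#'   `phi_i`, sensitivity `S` and its `class`.  A zero base value gives
#'   `S = NA` and class `"undefined"`.
#' @export
sensitivity_table <- function(p, kind = c("mean_shift", "sd_shift"), grid,
                              n = 900L, reps = 300L, seed, x0 = log(60),
                              baseline = c("simulated", "params")) {
  kind <- match.arg(kind)
  baseline <- match.arg(baseline)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(p, "nlari_params"), length(grid) >= 1L)
  if (any(grid == 0)) stop("grid entries must be nonzero", call. = FALSE)
  if (kind == "mean_shift" && p$omega == 0)
    stop("mean-shift sensitivity needs a nonzero base omega", call. = FALSE)
  pars <- if (kind == "mean_shift") c("alpha", "beta", "gamma", "sigma", "eta2")
          else c("omega", "alpha", "beta", "gamma", "eta1")

  base_seeds <- seed + seq_len(reps)
  phi0 <- if (baseline == "simulated") {
    average_estimates(p, 0, 0, n, reps, base_seeds, x0)
  } else {
    d <- derived_params(p)
    c(omega = p$omega, alpha = p$alpha, beta = p$beta, gamma = d$gamma,
      sigma = p$sigma, eta1 = d$eta1, eta2 = d$eta2)
  }

  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    v <- grid[gi]
    seeds <- seed + gi * reps + seq_len(reps)
    phi_i <- if (kind == "mean_shift")
      average_estimates(p, omega_i = v, sigma_i = 0, n, reps, seeds, x0)
    else
      average_estimates(p, omega_i = 0, sigma_i = v, n, reps, seeds, x0)
    denom_in <- if (kind == "mean_shift") v / p$omega
                else (sqrt(p$sigma^2 + v^2) - p$sigma) / p$sigma
    S <- ifelse(phi0[pars] == 0, NA_real_,
                abs((phi_i[pars] - phi0[pars]) / phi0[pars]) / abs(denom_in))
    cls <- ifelse(is.na(S), "undefined",
           ifelse(S == 0, "perfectly_insensitive",
           ifelse(S < 1, "insensitive",
           ifelse(S == 1, "unit_sensitive", "sensitive"))))
    rows[[gi]] <- data.frame(kind = kind, input = v, parameter = pars,
                             phi = unname(phi0[pars]),
                             phi_i = unname(phi_i[pars]),
                             S = unname(S), class = cls,
                             row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "baseline") <- baseline
  class(out) <- c("nlari_sensitivity", "data.frame")
  out
}

#' Time-scale sweep of the HR parameter estimates
#'
#' Assesses how block-mean aggregation of the observation scale distorts
#' the basic parameter estimates \eqn{(\alpha, \beta, \omega, \sigma)}:
#' for each scale `m` the process is simulated at base scale, aggregated
#' with [aggregate_series()], re-estimated, and the estimates averaged
#' over seeded replicates.  At beat-length scales the base parameters
#' are recovered; at minute scales (large `m`) the aggregated series
#' approaches white noise, for which the differenced-model fit drives
#' both \eqn{\hat\alpha} and \eqn{\hat\beta} towards 1.
#'
#' @param p base [nlari_params()].
#' @param m_list aggregation scales (positive integers).
#' @param n_base base-scale series length per replicate; must leave at
#'   least 100 aggregated points at the largest scale.
#' @param reps replicates per scale (default 100).
#' @param seed base seed.
#' @param x0 baseline level for the simulator.
#' @return A `data.frame` of class `nlari_scale_sweep` with one row per
#'   scale: averaged `alpha_hat`, `beta_hat`, `omega_hat`, `sigma_hat`
#'   and the aggregated length.
#' @export
scale_sweep <- function(p, m_list, n_base, reps = 100L, seed, x0 = log(60)) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(p, "nlari_params"), all(m_list >= 1))
  if (n_base %/% max(m_list) < 100L)
    stop("n_base leaves fewer than 100 aggregated points at the largest scale",
         call. = FALSE)
  out <- vector("list", length(m_list))
  for (k in seq_along(m_list)) {
    m <- as.integer(m_list[k])
    acc <- matrix(NA_real_, reps, 4L,
                  dimnames = list(NULL, c("alpha", "beta", "omega", "sigma")))
    for (r in seq_len(reps)) {
      s <- simulate_nlari(p, n = n_base, x0 = x0, seed = seed + (k - 1L) * reps + r)
      xa <- aggregate_series(s$x, m)
      e <- estimate_from_x(xa, kappa2 = p$kappa2)
      acc[r, ] <- c(e$alpha_hat, e$beta_hat, e$omega_hat, e$sigma_hat)
    }
    mu <- colMeans(acc)
    out[[k]] <- data.frame(m = m, alpha_hat = mu[["alpha"]],
                           beta_hat = mu[["beta"]], omega_hat = mu[["omega"]],
                           sigma_hat = mu[["sigma"]],
                           n_aggregated = as.integer(n_base %/% m),
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "reps") <- reps
  attr(res, "seed") <- seed
  attr(res, "params") <- p
  class(res) <- c("nlari_scale_sweep", "data.frame")
  res
}
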