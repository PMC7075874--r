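# Run the responder recursion for given coefficients and innovations,
# prepending the supplied initial history to the returned trace.
responder_trace <- function(theta1, theta2, kappa2, eps, y_init, guard = 1e6) {
  sim <- .nlari_recurse(eps, theta1, theta2, kappa2, y_init, guard)
  c(y_init, sim)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Grid search of (theta1, theta2) over the CI box of a fit, scoring each
# candidate by the median RMSE of seeded noise-driven runs against a
# target Y segment.  Innovations are shared across candidates (common
# random numbers) so the comparison is exact under one seed.
search_ci_box <- function(fit, target, y_init, seed, grid_size = 21L,
                          realizations = 20L, level = 0.95) {
  q <- qt(1 - (1 - level) / 2, df = fit$rows_used - 2)
  th1 <- seq(fit$theta1_hat - q * fit$s1, fit$theta1_hat + q * fit$s1,
             length.out = grid_size)
  th2 <- seq(fit$theta2_hat - q * fit$s2, fit$theta2_hat + q * fit$s2,
             length.out = grid_size)
  horizon <- length(target)
  set.seed(seed)
  eps <- matrix(rnorm(horizon * realizations, 0, fit$sigma_hat),
                nrow = horizon)
  best <- list(score = Inf)
  scores <- matrix(NA_real_, grid_size, grid_size)
  for (i in seq_along(th1)) {
    for (j in seq_along(th2)) {
      sc <- vapply(seq_len(realizations), function(r) {
        y <- tryCatch(
          .nlari_recurse(eps[, r], th1[i], th2[j], fit$kappa2, y_init, 1e6),
          error = function(e) NULL)
        if (is.null(y)) Inf else rmse(y, target)
      }, numeric(1))
      scores[i, j] <- median(sc)
      if (scores[i, j] < best$score) {
        best <- list(theta1 = th1[i], theta2 = th2[j],
                     score = scores[i, j], eps_first = eps[, 1L])
      }
    }
  }
  best$grid_theta1 <- th1
  best$grid_theta2 <- th2
  best$scores <- scores
  best
}

#' Out-of-sample prediction with the noise-driven responder
#'
#' Splits the series at \eqn{\lfloor n/2 \rfloor}, estimates the model
#' on the in-sample half, then searches \eqn{(\theta_1, \theta_2)} over
#' the in-sample confidence box \eqn{\hat\theta_i \pm q\, s_i} for the
#' candidate whose noise-driven responder output
#' (\eqn{\varepsilon_t \sim N(0, \hat\sigma^2)}) comes closest to the
#' actual out-sample HRV.  Closeness is the median RMSE over seeded
#' realizations; the out-sample HRV is obtained by extrapolating the
#' in-sample trend line (out-sample information is never used for
#' detrending).
#'
#' @inheritParams estimate_nlari
#' @param seed RNG seed for the scoring realizations (required).
#' @param grid_size grid points per coefficient axis (default 21).
#' @param realizations noise runs per candidate (default 20).
#' @param level confidence level defining the search box (default 0.95).
#' @return An object of class `nlari_prediction`: the in-sample fit,
#'   `chosen_params`, the predicted out-sample trace (first realization
#'   at the chosen parameters) with its ensemble mean, the achieved
#'   `score`, and the actual out-sample HRV.
#' @export
predict_out_of_sample <- function(series, kind = c("rr_seconds", "hr_bpm"),
                                  kappa2 = 1L, seed, grid_size = 21L,
                                  realizations = 20L, level = 0.95) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  h <- if (inherits(series, "hr_series")) series else to_log_hr(series, kind)
  n <- h$n
  if (n < 20L) stop("need at least 20 observations", call. = FALSE)
  split <- as.integer(n %/% 2)
  x_in <- h$x[seq_len(split)]
  tr <- detrend(x_in)
  fit <- fit_nlari(tr$y, kappa2 = kappa2)
  t_out <- (split + 1L):n
  y_out <- h$x[t_out] - (tr$a_hat + tr$b_hat * t_out)
  p <- max(2L, as.integer(kappa2))
  y_init <- tr$y[(split - p + 1L):split]
  best <- search_ci_box(fit, y_out, y_init, seed = seed,
                        grid_size = grid_size,
                        realizations = realizations, level = level)
  predicted <- .nlari_recurse(best$eps_first, best$theta1, best$theta2,
                              as.integer(kappa2), y_init, 1e6)
  structure(list(in_sample = fit, trend = tr, split = split,
                 chosen_params = c(theta1 = best$theta1,
                                   theta2 = best$theta2),
                 predicted = predicted, actual = y_out,
                 score = best$score, seed = seed,
                 grid = best[c("grid_theta1", "grid_theta2", "scores")]),
            class = "nlari_prediction")
}

#' Full-sample noise-driven responder fit
#'
#' Same search as [predict_out_of_sample()] but over the full sample:
#' given a detrended series and its fit, finds the
#' \eqn{(\theta_1, \theta_2)} in the confidence box whose noise-driven
#' responder output best matches the observed HRV (median RMSE over
#' seeded realizations).
#'
#' @param y detrended HRV series (or a `trend_fit`).
#' @param fit the `nlari_fit` of `y`; refitted if omitted.
#' @inheritParams predict_out_of_sample
#' @return A list with `chosen_params`, the `fitted` trace (first
#'   realization, initial history taken from the observed start),
#'   `score`, and the search grid.
#' @export
fit_noise_driven <- function(y, fit = NULL, seed, grid_size = 21L,
                             realizations = 20L, level = 0.95) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (inherits(y, "trend_fit")) y <- y$y
  if (is.null(fit)) fit <- fit_nlari(y)
  p <- max(2L, fit$kappa2)
  y_init <- y[seq_len(p)]
  target <- y[(p + 1L):length(y)]
  best <- search_ci_box(fit, target, y_init, seed = seed,
                        grid_size = grid_size,
                        realizations = realizations, level = level)
  fitted <- responder_trace(best$theta1, best$theta2, fit$kappa2,
                            best$eps_first, y_init)
  list(chosen_params = c(theta1 = best$theta1, theta2 = best$theta2),
       fitted = fitted, score = best$score, seed = seed,
       grid = best[c("grid_theta1", "grid_theta2", "scores")])
}

#' Stimulus-driven responder fit
#'
#' Drives the responder with the observed deviations themselves, clipped
#' at a threshold \eqn{c > 0}:
#' \eqn{\hat\varepsilon_t = \max(-c, \min(Y_t, c))}.  The responder
#' output at each step combines the observed lagged HRV (the
#' autoregressive and restoring terms are evaluated at the observed
#' \eqn{Y_{t-1}, Y_{t-2}, Y_{t-\kappa_2}}) with the clipped stimulus,
#' with the coefficients fixed at the OLS estimates; the threshold is
#' chosen from `c_grid` to minimise the RMSE against the observed HRV.
#' Because the stimulus carries the actual deviations, this variant can
#' track series at the edge of stability that the noise-driven
#' responder cannot.
#'
#' @param y detrended HRV series (or a `trend_fit`).
#' @param fit the `nlari_fit` of `y`; refitted if omitted.
#' @param c_grid positive candidate thresholds (default: 25 values
#'   spanning (0, max|Y|]).
#' @return A list of class `nlari_stimulus_fit` with the chosen `c`,
#'   the `fitted` trace, `score`, and the per-threshold scores.
#' @export
fit_stimulus_driven <- function(y, fit = NULL, c_grid = NULL) {
  if (inherits(y, "trend_fit")) y <- y$y
  if (is.null(fit)) fit <- fit_nlari(y)
  if (is.null(c_grid))
    c_grid <- seq(max(abs(y)) / 25, max(abs(y)), length.out = 25L)
  if (!length(c_grid) || any(c_grid <= 0))
    stop("`c_grid` must be a nonempty vector of positive thresholds",
         call. = FALSE)
  p <- max(2L, fit$kappa2)
  n <- length(y)
  t <- (p + 1L):n
  yk <- y[t - fit$kappa2]
  base <- (1 + fit$theta1_hat) * y[t - 1L] - fit$theta1_hat * y[t - 2L] +
    fit$theta2_hat * (-yk * exp(-yk^2))
  stim_trace <- function(cc) {
    eps <- pmin(pmax(y[t], -cc), cc)
    c(y[seq_len(p)], base + eps)
  }
  scores <- vapply(c_grid, function(cc) rmse(stim_trace(cc), y), numeric(1))
  best <- which.min(scores)
  cc <- c_grid[best]
  structure(list(c = cc, fitted = stim_trace(cc), score = scores[best],
                 c_grid = c_grid, scores = scores,
                 innovations = pmin(pmax(y[t], -cc), cc)),
            class = "nlari_stimulus_fit")
}

#' Sample autocorrelation with a long-memory flag
#'
#' Computes the sample ACF and flags long memory when the tail of the
#' absolute ACF exceeds the exponential envelope fitted to its early
#' lags, or when sign changes persist across most of the lag range
#' (an oscillatory, slowly damped dependence, typical of even
#' restoration delays).
#'
#' @param series numeric series.
#' @param max_lag largest lag (must be `< length(series)/2`; default
#'   `min(40, n/2 - 1)`).
#' @return A list of class `nlari_acf` with `lags`, `values`,
#'   `long_memory` (flag), `oscillatory`, and `slow_decay`.
#' @export
acf_curve <- function(series, max_lag = NULL) {
  stopifnot(is.numeric(series))
  n <- length(series)
  if (is.null(max_lag)) max_lag <- min(40L, floor(n / 2) - 1L)
  if (max_lag >= n / 2) stop("`max_lag` must be < n/2", call. = FALSE)
  a <- acf(series, lag.max = max_lag, plot = FALSE)
  vals <- drop(a$acf)
  lags <- 0:max_lag
  r <- vals[-1L]
  sig <- 2 / sqrt(n)   # approximate white-noise band
  # oscillation: the ACF swings between significantly positive and
  # significantly negative values more than once, with real amplitude
  signif <- abs(r) > sig
  s_sig <- sign(r)[signif]
  oscillatory <- sum(diff(s_sig) != 0) >= 2 &&
    length(s_sig) > 0 && max(abs(r[signif])) > 2 * sig
  # slow decay: the tail sits above the exponential envelope implied by
  # the initial (pre-sign-change) decay
  first_flip <- which(diff(sign(r)) != 0)[1L]
  k0 <- min(if (is.na(first_flip)) length(r) else first_flip,
            max(5L, floor(max_lag / 4)))
  k0 <- max(k0, 3L)
  env_fit <- lm.fit(cbind(1, seq_len(k0)),
                    log(pmax(abs(r[seq_len(k0)]), 1e-8)))
  env <- exp(env_fit$coefficients[1L] + env_fit$coefficients[2L] * seq_along(r))
  tail_idx <- (length(r) - max(3L, floor(max_lag / 3)) + 1L):length(r)
  slow_decay <- mean(abs(r[tail_idx])) > max(1.5 * mean(env[tail_idx]), sig)
  structure(list(lags = lags, values = vals,
                 long_memory = slow_decay || oscillatory,
                 oscillatory = oscillatory, slow_decay = slow_decay),
            class = "nlari_acf")
}

#' Compare the ACF of an actual and a predicted series
#'
#' @param actual,predicted numeric series (compared over the shorter
#'   common length).
#' @param max_lag largest lag for both ACFs.
#' @return A list with both `nlari_acf` curves, the correlation of their
#'   values over positive lags, and the maximum absolute difference.
#' @export
compare_acf <- function(actual, predicted, max_lag = NULL) {
  n <- min(length(actual), length(predicted))
  a <- acf_curve(actual[seq_len(n)], max_lag)
  p <- acf_curve(predicted[seq_len(n)], max_lag)
  list(actual = a, predicted = p,
       correlation = cor(a$values[-1L], p$values[-1L]),
       max_abs_diff = max(abs(a$values - p$values)),
       flags_agree = a$long_memory == p$long_memory)
}
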