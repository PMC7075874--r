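#' Confidence-interval membership test for the stable fixed-point range
#'
#' Inside the stable fixed-point regime the autoregressive coefficients
#' satisfy \eqn{\theta_1 \in (-1, 1)} and \eqn{\theta_2 \in (0, 4)}.
#' This test checks whether the two-sided confidence intervals
#' \eqn{\hat\theta_i \pm q \, s_i} fall entirely inside those open
#' intervals, with \eqn{q} the two-tailed Student-t critical value at the
#' requested level with `rows_used - 2` degrees of freedom.
#'
#' @param fit an `nlari_fit`.
#' @param level confidence level (default 0.95).
#' @return A list with the two intervals, membership flags
#'   `theta1_pass`, `theta2_pass`, and `pass` (both).
#' @export
ci_interval_test <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nlari_fit"))
  q <- qt(1 - (1 - level) / 2, df = fit$rows_used - 2)
  ci1 <- fit$theta1_hat + c(-1, 1) * q * fit$s1
  ci2 <- fit$theta2_hat + c(-1, 1) * q * fit$s2
  p1 <- ci1[1L] > -1 && ci1[2L] < 1
  p2 <- ci2[1L] > 0 && ci2[2L] < 4
  list(ci_theta1 = ci1, ci_theta2 = ci2,
       theta1_pass = p1, theta2_pass = p2, pass = p1 && p2, level = level)
}

#' F-test of the bifurcation boundary gamma = 1
#'
#' Tests the null \eqn{\gamma = 1} (loss of fixed-point stability)
#' against the fitted model.  Substituting the restriction
#' \eqn{\theta_2 = 2(1 + \theta_1)} into the differenced model gives the
#' restricted single-regressor regression of
#' \eqn{\Delta Y_t + 2 Y_{t-\kappa_2} e^{-Y_{t-\kappa_2}^2}} on
#' \eqn{\Delta Y_{t-1} - 2 Y_{t-\kappa_2} e^{-Y_{t-\kappa_2}^2}}, whose
#' residual sum of squares is RSS0; the statistic is
#' \deqn{F = \frac{RSS_0 - RSS_1}{RSS_1 / (n - 2)}}
#' with RSS1 from the unrestricted fit, referred to an
#' \eqn{F(1, n-2)} distribution (n = rows used).
#'
#' @param y detrended series the fit was computed on.
#' @param fit the unrestricted `nlari_fit` of `y`; refitted if omitted.
#' @param level test level as the quantile of the reference F
#'   distribution (default 0.99, the 1% test).
#' @return A list with `f_stat`, `crit`, `reject` (reject gamma = 1),
#'   `rss0`, `rss1`, `df2`.
#' @export
f_test_gamma_one <- function(y, fit = NULL, level = 0.99) {
  if (inherits(y, "trend_fit")) y <- y$y
  if (is.null(fit)) fit <- fit_nlari(y)
  stopifnot(inherits(fit, "nlari_fit"))
  kappa2 <- fit$kappa2
  start <- max(3L, kappa2 + 2L)
  n <- length(y)
  t <- start:n
  stopifnot(length(t) == fit$rows_used)
  dy  <- y[t] - y[t - 1L]
  dy1 <- y[t - 1L] - y[t - 2L]
  yk  <- y[t - kappa2]
  g <- -yk * exp(-yk^2)
  # gamma = 1  <=>  theta2 = 2 (1 + theta1):
  #   dy - 2 g = theta1 (dy1 + 2 g) + eps
  resp <- dy - 2 * g
  reg  <- dy1 + 2 * g
  if (sum(reg^2) == 0) stop("degenerate restricted design", call. = FALSE)
  th1_r <- sum(reg * resp) / sum(reg^2)
  rss0 <- sum((resp - th1_r * reg)^2)
  rss1 <- fit$rss
  if (rss1 == 0) stop("degenerate fit: RSS1 = 0", call. = FALSE)
  m <- fit$rows_used
  f_stat <- (rss0 - rss1) / (rss1 / (m - 2))
  crit <- qf(level, 1, m - 2)
  list(f_stat = f_stat, crit = crit, reject = f_stat > crit,
       rss0 = rss0, rss1 = rss1, df2 = m - 2, level = level,
       theta1_restricted = th1_r)
}

#' Critical values for the gamma_n test
#'
#' Container for the two-sided critical values of the \eqn{\gamma_n}
#' statistic.  The defaults are the tabled 1% values \eqn{-3.50} and
#' \eqn{11.9} quoted for samples of 900 to 10000 beats.  Note that the
#' statistic's null distribution depends strongly on the innovation
#' scale (see [null_critical_values()]), so Monte-Carlo calibration at a
#' matched \eqn{(n, \sigma)} is recommended whenever the fixed values
#' are not known to apply to the data at hand.
#'
#' @param lower,upper rejection thresholds, `lower < upper`.
#' @param source `"tabled"` for the quoted defaults, `"monte_carlo"` for
#'   simulated values.
#' @param ... further metadata stored alongside (reps, seed, n, ...).
#' @return An object of class `nlari_cv`.
#' @export
critical_values <- function(lower = -3.50, upper = 11.9,
                            source = "tabled", ...) {
  stopifnot(lower < upper)
  structure(list(lower = lower, upper = upper, source = source, ...),
            class = "nlari_cv")
}

#' @export
print.nlari_cv <- function(x, ...) {
  cat(sprintf("gamma_n critical values [%s]: lower %.4g, upper %.4g\n",
              x$source, x$lower, x$upper))
  invisible(x)
}

#' The gamma_n test of the no-restoring-force null gamma = 0
#'
#' Computes
#' \deqn{\gamma_n = 4 \sqrt{\pi n (32 \hat\sigma^6)^{-1}}
#'       \sqrt{1 - \hat\theta_1}\, \hat\theta_2}
#' (n = rows used) and rejects \eqn{\gamma = 0} when the value falls
#' below `cv$lower` or above `cv$upper`.  Under the null the statistic
#' has an asymmetric distribution related to the Brownian functional
#' \eqn{W(1)/\sqrt{L(1,0)}}.
#'
#' @param fit an `nlari_fit`.
#' @param cv a [critical_values()] object.
#' @return A list with `statistic`, `reject` and the `cv` used.
#' @export
gamma_n_test <- function(fit, cv = critical_values()) {
  stopifnot(inherits(fit, "nlari_fit"), inherits(cv, "nlari_cv"))
  if (fit$theta1_hat >= 1)
    stop("gamma_n undefined: theta1_hat >= 1", call. = FALSE)
  if (fit$sigma_hat == 0)
    stop("gamma_n undefined: sigma_hat = 0", call. = FALSE)
  n <- fit$rows_used
  stat <- 4 * sqrt(pi * n / (32 * fit$sigma_hat^6)) *
    sqrt(1 - fit$theta1_hat) * fit$theta2_hat
  list(statistic = stat, reject = stat < cv$lower || stat > cv$upper,
       cv = cv)
}

#' Monte-Carlo critical values for gamma_n under the beta = 0 null
#'
#' Simulates the no-restoring-force null
#' \eqn{\Delta Y_t = \theta_1 \Delta Y_{t-1} + \varepsilon_t}
#' (a unit-root process), fits the NLARI difference equation to each
#' replicate and computes \eqn{\gamma_n}, returning the empirical
#' two-sided test quantiles.  The null distribution is not pivotal in
#' the innovation scale: to calibrate a test for real data, set
#' `sigma_null` near the residual scale of the fitted series.
#'
#' @param n series length per replicate (default 900).
#' @param reps number of replicates (>= 1000; default 10000).
#' @param seed RNG seed (required).
#' @param theta1_null AR coefficient of the differenced null (default 0).
#' @param sigma_null innovation standard deviation (default 1).
#' @param level two-sided test level (default 0.01).
#' @param tail_split fraction of `level` allocated to the lower tail
#'   (default 0.5, i.e. level/2 per tail).
#' @param detrend if `TRUE`, mirror the estimation pipeline by removing
#'   the OLS line from each null replicate before fitting (default
#'   `FALSE`: the null is fit as simulated).
#' @return A [critical_values()] object (`source = "monte_carlo"`) with
#'   the quantiles, their Monte-Carlo standard errors (`lower_se`,
#'   `upper_se`, density-based), and the simulated statistics in
#'   `statistics`.
#' @export
null_critical_values <- function(n = 900L, reps = 10000L, seed,
                                 theta1_null = 0, sigma_null = 1,
                                 level = 0.01, tail_split = 0.5,
                                 detrend = FALSE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(reps >= 1000L, level > 0, level < 1,
            tail_split > 0, tail_split < 1)
  set.seed(seed)
  gn <- numeric(reps)
  tt <- seq_len(n)
  for (r in seq_len(reps)) {
    eps <- rnorm(n, 0, sigma_null)
    dy <- if (theta1_null != 0)
      as.numeric(stats::filter(eps, theta1_null, method = "recursive"))
    else eps
    y <- cumsum(dy)
    if (detrend) y <- lm.fit(cbind(1, tt), y)$residuals
    fit <- fit_nlari(y)
    gn[r] <- 4 * sqrt(pi * fit$rows_used / (32 * fit$sigma_hat^6)) *
      sqrt(1 - fit$theta1_hat) * fit$theta2_hat
  }
  p_lo <- level * tail_split
  p_hi <- 1 - level * (1 - tail_split)
  q <- unname(quantile(gn, c(p_lo, p_hi), type = 7))
  # density-based large-sample standard error of an empirical quantile
  f <- density(gn, n = 1024)
  fq <- pmax(stats::approx(f$x, f$y, xout = q, rule = 2)$y, .Machine$double.eps)
  se <- sqrt(c(p_lo * (1 - p_lo), p_hi * (1 - p_hi)) / reps) / fq
  critical_values(lower = q[1L], upper = q[2L], source = "monte_carlo",
                  reps = reps, seed = seed, n = n, level = level,
                  tail_split = tail_split, theta1_null = theta1_null,
                  sigma_null = sigma_null, detrend = detrend,
                  lower_se = se[1L], upper_se = se[2L], statistics = gn)
}

#' Simulate the limiting ratio W(1) / sqrt(L(1,0))
#'
#' Cross-check for the \eqn{\gamma_n} null: draws the Brownian endpoint
#' over the square root of the local time at zero, the stated limiting
#' functional.  Each replicate discretises a standard Brownian path on
#' `steps` increments and estimates the local time by
#' \eqn{(2\epsilon)^{-1} \int 1\{|W| \le \epsilon\}} with
#' \eqn{\epsilon = \mathrm{steps}^{-1/4}}.
#'
#' @param reps replicates (default 2000).
#' @param steps path discretisation (default `1e5`).
#' @param seed RNG seed (required).
#' @return Numeric vector of simulated ratios.
#' @export
limit_ratio_sim <- function(reps = 2000L, steps = 1e5, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  eps <- steps^(-1 / 4)
  out <- numeric(reps)
  for (i in seq_len(reps)) {
    w <- cumsum(rnorm(steps, 0, 1 / sqrt(steps)))
    L <- sum(abs(w) <= eps) / (2 * eps * steps)
    out[i] <- if (L > 0) w[steps] / sqrt(L) else NA_real_
  }
  out
}

#' Homeostasis test battery for a beat series
#'
#' Runs the full decision procedure for whether a beat series is
#' consistent with the stable homeostatic responder (the NLARI process
#' in the stable fixed-point range): (1) estimate the model; (2) check
#' that the confidence intervals for \eqn{\theta_1} and \eqn{\theta_2}
#' fall within \eqn{(-1,1)} and \eqn{(0,4)}; (3) reject \eqn{\gamma = 1}
#' by the F-test; (4) reject \eqn{\gamma = 0} by the \eqn{\gamma_n}
#' test.  The verdict is homeostatic only if all sub-tests pass.
#'
#' @inheritParams estimate_nlari
#' @param level confidence level for the interval test (default 0.95).
#' @param f_level level of the F-test (default 0.99).
#' @param cv [critical_values()] for the \eqn{\gamma_n} decision.
#' @return An object of class `nlari_test_report`.
#' @examples
#' s <- simulate_nlari(nlari_params(), n = 900, seed = 11)
#' r <- homeostasis_test(exp(s$x), kind = "hr_bpm")
#' r$verdict
#' @export
homeostasis_test <- function(series, kind = c("rr_seconds", "hr_bpm"),
                             kappa2 = 1L, level = 0.95, f_level = 0.99,
                             cv = critical_values()) {
  est <- estimate_nlari(series, kind, kappa2 = kappa2)
  ci <- ci_interval_test(est$fit, level = level)
  ft <- f_test_gamma_one(est$trend$y, est$fit, level = f_level)
  gt <- gamma_n_test(est$fit, cv = cv)
  verdict <- ci$pass && ft$reject && gt$reject
  structure(list(estimate = est, ci = ci, f_test = ft, gamma_n = gt,
                 verdict = verdict),
            class = "nlari_test_report")
}

#' @export
print.nlari_test_report <- function(x, ...) {
  cat("Homeostasis test battery\n")
  cat(sprintf("  theta1 CI (%.4f, %.4f) in (-1,1): %s\n",
              x$ci$ci_theta1[1], x$ci$ci_theta1[2], x$ci$theta1_pass))
  cat(sprintf("  theta2 CI (%.4f, %.4f) in (0,4):  %s\n",
              x$ci$ci_theta2[1], x$ci$ci_theta2[2], x$ci$theta2_pass))
  cat(sprintf("  F (gamma=1): %.3f vs crit %.3f -> reject: %s\n",
              x$f_test$f_stat, x$f_test$crit, x$f_test$reject))
  cat(sprintf("  gamma_n (gamma=0): %.4g vs (%.4g, %.4g) -> reject: %s\n",
              x$gamma_n$statistic, x$gamma_n$cv$lower, x$gamma_n$cv$upper,
              x$gamma_n$reject))
  cat(sprintf("  verdict: %s\n",
              if (x$verdict) "homeostatic" else "not homeostatic"))
  invisible(x)
}
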