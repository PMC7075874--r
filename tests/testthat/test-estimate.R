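test_that("log-HR conversion and its error handling", {
  h <- to_log_hr(1.0, "rr_seconds")
  expect_equal(h$x, log(60))
  expect_equal(to_log_hr(60, "hr_bpm")$x, h$x)  # path equivalence
  rr <- c(0.9, 1.0, 1.1)
  expect_equal(to_log_hr(rr, "rr_seconds")$x, to_log_hr(60 / rr, "hr_bpm")$x)
  expect_error(to_log_hr(c(1, 0, 1), "rr_seconds"), "index 2")
  expect_error(to_log_hr(c(1, -2), "hr_bpm"), "index 2")
})

test_that("detrending removes an exact line and tolerates constants", {
  t <- 1:100
  tr <- detrend(2 + 0.01 * t)
  expect_equal(tr$a_hat, 2)
  expect_equal(tr$b_hat, 0.01)
  expect_equal(tr$y, rep(0, 100), tolerance = 1e-12)

  trc <- detrend(rep(3.5, 50))
  expect_equal(trc$b_hat, 0)
  expect_equal(trc$y, rep(0, 50), tolerance = 1e-12)
})

test_that("the normal-equations fit agrees with independent least-squares oracles", {
  s <- simulate_nlari(stable_params(), n = 30, seed = 77)
  y <- detrend(s$x)$y
  fit <- fit_nlari(y)

  # oracle 1: stats::lm on the same regressors
  t <- 3:30
  dy <- y[t] - y[t - 1]; dy1 <- y[t - 1] - y[t - 2]
  g <- -y[t - 1] * exp(-y[t - 1]^2)
  lmfit <- lm(dy ~ 0 + dy1 + g)
  expect_equal(unname(coef(lmfit)),
               c(fit$theta1_hat, fit$theta2_hat), tolerance = 1e-10)
  expect_equal(unname(summary(lmfit)$coefficients[, "Std. Error"]),
               c(fit$s1, fit$s2), tolerance = 1e-8)
  expect_equal(summary(lmfit)$sigma, fit$sigma_hat, tolerance = 1e-10)

  # oracle 2: brute-force RSS minimisation on a fine grid
  rss_fun <- function(t1, t2) sum((dy - t1 * dy1 - t2 * g)^2)
  t1g <- seq(fit$theta1_hat - 0.2, fit$theta1_hat + 0.2, length.out = 81)
  t2g <- seq(fit$theta2_hat - 0.2, fit$theta2_hat + 0.2, length.out = 81)
  grid_rss <- outer(t1g, t2g, Vectorize(rss_fun))
  expect_lte(fit$rss, min(grid_rss) + 1e-12)
  idx <- which(grid_rss == min(grid_rss), arr.ind = TRUE)
  expect_equal(t1g[idx[1]], fit$theta1_hat, tolerance = 0.006)
  expect_equal(t2g[idx[2]], fit$theta2_hat, tolerance = 0.006)
})

test_that("residual degrees of freedom and presample bookkeeping are as printed", {
  s <- simulate_nlari(stable_params(), n = 100, seed = 3)
  y <- detrend(s$x)$y
  fit <- fit_nlari(y)
  expect_identical(fit$rows_used, 98L)            # starts at t = 3
  expect_equal(fit$sigma_hat, sqrt(fit$rss / (fit$rows_used - 2)))
  fit10 <- fit_nlari(y, kappa2 = 10)
  expect_identical(fit10$rows_used, 100L - 12L + 1L)  # starts at kappa2 + 2
})

test_that("degenerate designs are rejected", {
  expect_error(fit_nlari(rep(0, 50)), "zero|rank")
  expect_error(fit_nlari(c(0, 0, 0, 0)), "rows|zero|rank")
})

test_that("the two algebraic routes to gamma_hat coincide", {
  s <- simulate_nlari(stable_params(), n = 400, seed = 12)
  est <- estimate_nlari(exp(s$x), kind = "hr_bpm")
  f <- est$fit
  expect_equal(f$gamma_hat, f$theta2_hat / (2 * (1 + f$theta1_hat)))
  expect_equal(est$gamma_hat, est$beta_hat / (4 - 2 * est$alpha_hat),
               tolerance = 1e-12)
  # mapping identities are definitions
  expect_identical(est$alpha_hat, 1 - f$theta1_hat)
  expect_identical(est$beta_hat, f$theta2_hat)
  expect_identical(est$eta1_hat, est$trend$b_hat)
  expect_equal(est$omega_hat, est$trend$b_hat * (1 - f$theta1_hat))
  expect_equal(est$eta2_hat, f$sigma_hat / f$theta2_hat)
})

test_that("parameters are recovered from long stable-regime simulations", {
  s <- simulate_nlari(stable_params(), n = 5000, seed = 7)
  est <- estimate_nlari(60 / exp(s$x), kind = "rr_seconds")
  f <- est$fit
  # within 3 standard errors of the generating values
  expect_lt(abs(f$theta1_hat - (1 - 0.7786)), 3 * f$s1)
  expect_lt(abs(f$theta2_hat - 0.3), 3 * f$s2)
  expect_equal(est$sigma_hat, 0.0275, tolerance = 0.05)
})

test_that("a 900-beat window recovers the generating parameters to working tolerance", {
  ests <- sapply(1:5, function(seed) {
    s <- simulate_nlari(stable_params(), n = 900, seed = 100 + seed)
    e <- estimate_nlari(exp(s$x), kind = "hr_bpm")
    c(e$alpha_hat, e$beta_hat, e$sigma_hat)
  })
  m <- rowMeans(ests)
  expect_equal(m[1], 0.7786, tolerance = 0.10)
  expect_equal(m[2], 0.3, tolerance = 0.25)
  expect_equal(m[3], 0.0275, tolerance = 0.05)
})

test_that("unit-root data yield near-zero restoring-force estimates", {
  s <- simulate_nlari(unit_root_params(), n = 5000, seed = 8)
  est <- estimate_nlari(exp(s$x), kind = "hr_bpm")
  expect_lt(abs(est$beta_hat), 0.05)
  expect_lt(abs(est$gamma_hat), 0.05)
})

test_that("fitting small-amplitude white noise approaches theta1 = 0, theta2 = 1", {
  set.seed(1)
  y <- rnorm(1e5, 0, 0.01)
  f <- fit_nlari(y)
  expect_lt(abs(f$theta1_hat), 0.05)
  expect_lt(abs(f$theta2_hat - 1), 0.05)
})

test_that("estimated amplitude indicator tracks the sample spread across a parameter grid", {
  grid <- expand.grid(beta = c(0.1, 0.2, 0.4, 0.6), seed = 1:3)
  res <- apply(grid, 1, function(row) {
    p <- nlari_params(omega = 0, sigma = 0.0275, alpha = 0.7786,
                      beta = row[["beta"]])
    s <- simulate_nlari(p, n = 900, seed = 200 + row[["seed"]])
    e <- estimate_nlari(exp(s$x), kind = "hr_bpm")
    c(eta2 = e$eta2_hat, sdy = sd(s$y))
  })
  expect_gt(cor(res["eta2", ], res["sdy", ], method = "spearman"), 0.7)
})
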