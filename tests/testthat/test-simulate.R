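test_that("the origin is a fixed point of the deterministic skeleton", {
  p <- params_at_gamma(1.2)
  y <- iterate_nlari(p, 100, init = 0)
  expect_identical(y, rep(0, 100))
})

test_that("long-run iterates reach the period-two attractor for 1 < gamma < sqrt(e)", {
  p <- params_at_gamma(1.2)
  y <- iterate_nlari(p, 4000, init = 0.1)
  amp <- two_cycle_amplitude(1.2)
  last <- tail(y, 10)
  expect_equal(abs(last), rep(amp, 10), tolerance = 1e-6)
  expect_true(all(sign(last) == rep(c(-1, 1), length.out = 10)) ||
                all(sign(last) == rep(c(1, -1), length.out = 10)))
})

test_that("iterates decay exponentially inside the stable fixed-point range", {
  p <- params_at_gamma(0.5)
  y <- iterate_nlari(p, 3000, init = 0.1)
  expect_lt(abs(tail(y, 1)), 1e-8)
  # envelope shrinks over blocks (non-strict once it underflows)
  blocks <- sapply(split(abs(y), rep(1:10, each = 300)), max)
  expect_true(all(diff(blocks) <= 0))
  expect_lt(blocks[5], blocks[1])
})

test_that("the divergence guard aborts with the failing step", {
  p <- params_at_gamma(1.2)
  expect_error(iterate_nlari(p, 4000, init = 0.1, guard = 0.3),
               "diverged at step")
})

test_that("trend reconstruction is exact: x - x0 - eta1 * t = y", {
  for (seed in 1:3) {
    p <- stable_params(omega = 5e-4)
    s <- simulate_nlari(p, n = 500, seed = seed)
    eta1 <- derived_params(p)$eta1
    expect_equal(s$x - s$x0 - eta1 * seq_len(500), s$y, tolerance = 1e-12)
  }
})

test_that("zero noise gives a flat HRV component and a straight mean line", {
  p <- nlari_params(omega = 1e-3, sigma = 0, alpha = 0.7786, beta = 0.3)
  s <- simulate_nlari(p, n = 200, seed = 1)
  expect_identical(s$y, rep(0, 200))
  expect_equal(diff(s$x), rep(derived_params(p)$eta1, 199))
})

test_that("without restoring force the simulator reproduces an independent unit-root recursion", {
  # theta1 = 0: Y is exactly the cumulative sum of the innovations
  p <- nlari_params(omega = 0, sigma = 0.0275, alpha = 1, beta = 0)
  s <- simulate_nlari(p, n = 300, seed = 42, burn_in = 100)
  set.seed(42)
  eps <- rnorm(400, 0, 0.0275)
  walk <- cumsum(eps)
  expect_equal(s$y, walk[101:400], tolerance = 1e-12)
  expect_equal(s$innovations, eps[101:400])

  # theta1 = 0.5: ARIMA(1,1,0)-style oracle via stats::filter + cumsum
  p2 <- nlari_params(omega = 0, sigma = 0.0275, alpha = 0.5, beta = 0)
  s2 <- simulate_nlari(p2, n = 300, seed = 43, burn_in = 100)
  set.seed(43)
  eps2 <- rnorm(400, 0, 0.0275)
  dy <- as.numeric(stats::filter(eps2, 0.5, method = "recursive"))
  expect_equal(s2$y, cumsum(dy)[101:400], tolerance = 1e-10)

  # sample variance of the walk grows along the series on average
  ratios <- sapply(1:5, function(seed) {
    w <- simulate_nlari(p, n = 300, seed = 900 + seed, burn_in = 0)$y
    var(w[1:300]) / var(w[1:100])
  })
  expect_gt(mean(ratios), 1)
})

test_that("a larger amplitude indicator gives a larger sample spread under matched seeds", {
  for (seed in 1:3) {
    lo <- simulate_nlari(stable_params(), n = 900, seed = seed)
    hi_p <- nlari_params(omega = 1e-4, sigma = 3 * 0.0275, alpha = 0.7786,
                         beta = 0.3)
    hi <- simulate_nlari(hi_p, n = 900, seed = seed)
    expect_gt(sd(hi$y), sd(lo$y))
  }
})

test_that("regressing the simulated mean line on time recovers the slope omega/alpha", {
  p <- stable_params(omega = 0.7786e-3)  # eta1 = 1e-3
  s <- simulate_nlari(p, n = 20000, seed = 9)
  b <- detrend(s$x)$b_hat
  expect_equal(b, 1e-3, tolerance = 0.2)  # relative Monte-Carlo tolerance
})

test_that("disturbance shifts compose as stated", {
  p <- stable_params()
  s0 <- simulate_nlari(p, n = 300, seed = 5)
  s1 <- simulate_disturbed(p, omega_i = 0, sigma_i = 0, n = 300, seed = 5)
  expect_identical(s0$y, s1$y)

  s2 <- simulate_disturbed(p, sigma_i = p$sigma, n = 300, seed = 5)
  expect_equal(s2$params$sigma, p$sigma * sqrt(2))

  s3 <- simulate_disturbed(p, omega_i = 2e-4, n = 300, seed = 5)
  expect_equal(derived_params(s3$params)$eta1,
               (p$omega + 2e-4) / p$alpha)
  # same noise path, shifted trend only
  expect_identical(s3$y, s0$y)
})

test_that("stability bisection requires a straddling bracket", {
  expect_error(find_stability_boundary("fixed_point", bracket = c(0.1, 0.5)),
               "straddle")
})
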