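test_that("out-of-sample prediction is the grid optimum and is reproducible", {
  s <- simulate_nlari(stable_params(), n = 300, seed = 41)
  pr <- predict_out_of_sample(exp(s$x), kind = "hr_bpm", seed = 1,
                              grid_size = 7, realizations = 5)
  expect_identical(pr$split, 150L)
  expect_length(pr$predicted, 150L)
  expect_equal(pr$score, min(pr$grid$scores))
  # chosen parameters sit inside the confidence box
  q <- qt(0.975, df = pr$in_sample$rows_used - 2)
  expect_true(abs(pr$chosen_params["theta1"] - pr$in_sample$theta1_hat) <=
                q * pr$in_sample$s1 + 1e-12)
  expect_true(abs(pr$chosen_params["theta2"] - pr$in_sample$theta2_hat) <=
                q * pr$in_sample$s2 + 1e-12)

  pr2 <- predict_out_of_sample(exp(s$x), kind = "hr_bpm", seed = 1,
                               grid_size = 7, realizations = 5)
  expect_identical(pr$predicted, pr2$predicted)
  expect_identical(pr$score, pr2$score)
})

test_that("noise-driven fit improves (weakly) under grid refinement", {
  s <- simulate_nlari(stable_params(), n = 240, seed = 42)
  y <- detrend(s$x)$y
  f <- fit_nlari(y)
  coarse <- fit_noise_driven(y, f, seed = 2, grid_size = 3, realizations = 6)
  fine <- fit_noise_driven(y, f, seed = 2, grid_size = 9, realizations = 6)
  expect_lte(fine$score, coarse$score)
  expect_equal(coarse$score, min(coarse$grid$scores))
})

test_that("stimulus clipping honours its contract", {
  s <- simulate_nlari(stable_params(), n = 300, seed = 43)
  y <- detrend(s$x)$y
  f <- fit_nlari(y)
  sf <- fit_stimulus_driven(y, f, c_grid = c(0.005, 0.02, 0.1))
  expect_true(all(abs(sf$innovations) <= sf$c + 1e-15))

  # threshold beyond the data range leaves the stimulus unclipped
  big <- max(abs(y)) * 2
  sf2 <- fit_stimulus_driven(y, f, c_grid = big)
  expect_identical(sf2$innovations, y[3:length(y)])

  # a value at twice the threshold is clipped to the threshold exactly
  yy <- c(0.01, -0.01, 0.02, 2 * 0.05, 0.01, -0.02, 0.015, -0.01, 0.01, 0.02)
  sf3 <- fit_stimulus_driven(rep(yy, 10), fake_fit(rows = 98L),
                             c_grid = 0.05)
  expect_true(any(sf3$innovations == 0.05))
  expect_error(fit_stimulus_driven(y, f, c_grid = numeric(0)), "c_grid")
  expect_error(fit_stimulus_driven(y, f, c_grid = c(0.1, -1)), "c_grid")
})

test_that("the stimulus-driven responder outperforms the noise-driven one at the stability edge", {
  p <- nlari_params(omega = 0, sigma = 0.0275, alpha = 0.7786, beta = 0.005)
  s <- simulate_nlari(p, n = 400, seed = 31)
  y <- detrend(s$x)$y
  f <- fit_nlari(y)
  nf <- fit_noise_driven(y, f, seed = 1, grid_size = 9, realizations = 10)
  sf <- fit_stimulus_driven(y, f)
  expect_lt(sf$score, nf$score)
})

test_that("sample autocorrelations start at one and flag the right structures", {
  set.seed(51)
  wn <- rnorm(900)
  a <- acf_curve(wn, max_lag = 40)
  expect_equal(a$values[1], 1)
  expect_lt(max(abs(a$values[-1])), 4 / sqrt(900))
  expect_false(a$long_memory)
  expect_error(acf_curve(wn, max_lag = 500), "n/2")

  # an even restoration delay produces a slowly decaying oscillation
  p10 <- stable_params(omega = 0, kappa2 = 10L)
  for (seed in 52:54) {
    s10 <- simulate_nlari(p10, n = 900, seed = seed)
    a10 <- acf_curve(s10$y, max_lag = 60)
    expect_true(a10$oscillatory)
    expect_true(a10$long_memory)
  }
})

test_that("predicted realizations reproduce the oscillatory ACF shape of an even delay", {
  p10 <- stable_params(omega = 0, kappa2 = 10L)
  s10 <- simulate_nlari(p10, n = 600, seed = 55)
  y <- detrend(s10$x)$y
  f <- fit_nlari(y, kappa2 = 10)
  nf <- fit_noise_driven(y, f, seed = 3, grid_size = 5, realizations = 5)
  cmp <- compare_acf(y, nf$fitted, max_lag = 50)
  expect_true(cmp$predicted$oscillatory)
  expect_true(cmp$flags_agree)
  expect_gt(cmp$correlation, 0.5)
})
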