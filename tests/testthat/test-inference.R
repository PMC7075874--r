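test_that("confidence-interval membership uses interval arithmetic correctly", {
  # tiny standard error: interval collapses inside the target range
  f <- fake_fit(theta1 = 0, theta2 = 0.3, s1 = 1e-9, s2 = 1e-9)
  r <- ci_interval_test(f)
  expect_true(r$theta1_pass && r$theta2_pass && r$pass)

  # upper bound of theta2 spills past 4
  f2 <- fake_fit(theta2 = 3.9, s2 = 0.1)
  r2 <- ci_interval_test(f2)
  expect_false(r2$theta2_pass)
  expect_false(r2$pass)

  # the multiplier is the two-tailed t critical value at rows - 2 df
  f3 <- fake_fit(theta1 = 0.2, s1 = 0.05, rows = 52L)
  r3 <- ci_interval_test(f3, level = 0.95)
  q <- qt(0.975, df = 50)
  expect_equal(r3$ci_theta1, 0.2 + c(-1, 1) * q * 0.05)
})

test_that("interval tests pass on almost all stable-regime replicates", {
  passes <- sapply(1:40, function(seed) {
    s <- simulate_nlari(stable_params(), n = 900, seed = 300 + seed)
    ci_interval_test(fit_nlari(detrend(s$x)$y))$pass
  })
  expect_gte(mean(passes), 0.95)
})

test_that("the F statistic is a valid nested-model comparison", {
  # RSS0 >= RSS1 always, hence F >= 0, including at the null
  for (seed in 1:5) {
    s <- simulate_nlari(params_at_gamma(1, sigma = 0.0275), n = 400,
                        seed = 400 + seed)
    y <- detrend(s$x)$y
    ft <- f_test_gamma_one(y)
    expect_gte(ft$rss0, ft$rss1)
    expect_gte(ft$f_stat, 0)
  }
})

test_that("the F test rejects gamma = 1 on stable-regime data and holds size at the null", {
  rej_alt <- sapply(1:30, function(seed) {
    s <- simulate_nlari(stable_params(), n = 900, seed = 500 + seed)
    f_test_gamma_one(detrend(s$x)$y, level = 0.99)$reject
  })
  expect_gte(mean(rej_alt), 0.99)

  rej_null <- sapply(1:150, function(seed) {
    s <- simulate_nlari(params_at_gamma(1, sigma = 0.0275), n = 900,
                        seed = 600 + seed)
    f_test_gamma_one(detrend(s$x)$y, level = 0.95)$reject
  })
  expect_lte(mean(rej_null), 0.12)   # nominal 5%
  expect_gte(mean(rej_null), 0.005)
})

test_that("gamma_n follows its closed form: zero numerator, sign, and sqrt(n) scaling", {
  f0 <- fake_fit(theta2 = 0)
  g0 <- gamma_n_test(f0)
  expect_identical(g0$statistic, 0)
  expect_false(g0$reject)

  fa <- fake_fit(theta2 = 0.3, rows = 898L)
  fb <- fake_fit(theta2 = 0.3, rows = 2L * 898L)
  expect_equal(gamma_n_test(fb)$statistic / gamma_n_test(fa)$statistic,
               sqrt(2))

  fneg <- fake_fit(theta2 = -0.2)
  expect_lt(gamma_n_test(fneg)$statistic, 0)

  expect_error(gamma_n_test(fake_fit(theta1 = 1.2)), "theta1")
  expect_error(gamma_n_test(fake_fit(sigma = 0)), "sigma")
})

test_that("gamma_n rejects gamma = 0 overwhelmingly on stable-regime windows", {
  stats <- sapply(1:50, function(seed) {
    s <- simulate_nlari(stable_params(), n = 900, seed = 700 + seed)
    gamma_n_test(fit_nlari(detrend(s$x)$y))$statistic
  })
  expect_gte(mean(abs(stats) > 11.9), 0.99)
})

test_that("Monte-Carlo null critical values are reproducible and bracket zero", {
  cv <- null_critical_values(n = 300, reps = 1000, seed = 11)
  expect_lt(cv$lower, 0)
  expect_gt(cv$upper, 0)
  expect_gt(cv$lower_se, 0)
  expect_gt(cv$upper_se, 0)
  expect_length(cv$statistics, 1000)
  cv2 <- null_critical_values(n = 300, reps = 1000, seed = 11)
  expect_identical(cv$statistics, cv2$statistics)
  expect_identical(c(cv$lower, cv$upper), c(cv2$lower, cv2$upper))
})

test_that("the homeostasis battery composes its verdict as all-sub-tests-pass", {
  # stable regime: homeostatic
  s <- simulate_nlari(stable_params(), n = 900, seed = 21)
  r <- homeostasis_test(exp(s$x), kind = "hr_bpm")
  expect_true(r$ci$pass)
  expect_true(r$f_test$reject)
  expect_true(r$gamma_n$reject)
  expect_true(r$verdict)

  # on the flip boundary gamma = 1 the F test cannot reject: not homeostatic
  sb <- simulate_nlari(params_at_gamma(1, sigma = 0.0275), n = 900, seed = 22)
  rb <- homeostasis_test(exp(sb$x), kind = "hr_bpm")
  expect_false(rb$f_test$reject)
  expect_false(rb$verdict)
})

test_that("without restoring force the gamma_n test fails to reject at calibrated critical values", {
  # critical values calibrated at the matched (n, sigma) null, mirroring
  # the detrending pipeline
  cv <- null_critical_values(n = 900, reps = 1000, seed = 31,
                             sigma_null = 0.0275, detrend = TRUE)
  hits <- sapply(1:10, function(seed) {
    s <- simulate_nlari(unit_root_params(), n = 900, seed = 800 + seed)
    r <- homeostasis_test(exp(s$x), kind = "hr_bpm", cv = cv)
    c(gn_reject = r$gamma_n$reject, verdict = r$verdict)
  })
  expect_lte(mean(hits["gn_reject", ]), 0.3)   # mostly inside the null bulk
  expect_lte(mean(hits["verdict", ]), 0.3)
})
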