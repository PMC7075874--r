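# Shared parameter sets used across the suite.

# Stable fixed-point regime at the package's documented reference conditions
# (gamma ~ 0.123, eta2 ~ 0.092).
stable_params <- function(omega = 1e-4, kappa2 = 1L) {
  nlari_params(omega = omega, sigma = 0.0275, alpha = 0.7786, beta = 0.3,
               kappa2 = kappa2)
}

# Boundary of the stable fixed-point range (gamma = 0.0171).
boundary_params <- function() {
  nlari_params(omega = 1e-4, sigma = 0.0275, alpha = 1.5, beta = 0.0171)
}

# No restoring force: unit-root process.
unit_root_params <- function(alpha = 0.7786) {
  nlari_params(omega = 0, sigma = 0.0275, alpha = alpha, beta = 0)
}

# gamma exactly at a target value, at the default resistance.
params_at_gamma <- function(gamma, alpha = 0.7786, sigma = 0.0275,
                            omega = 0) {
  nlari_params(omega = omega, sigma = sigma, alpha = alpha,
               beta = gamma * (4 - 2 * alpha))
}

# A hand-built nlari_fit for interval/statistic arithmetic tests.
fake_fit <- function(theta1 = 0, theta2 = 0.3, s1 = 0.03, s2 = 0.03,
                     sigma = 0.0275, rows = 898L) {
  structure(list(theta1_hat = theta1, theta2_hat = theta2, s1 = s1, s2 = s2,
                 sigma_hat = sigma,
                 gamma_hat = theta2 / (2 * (1 + theta1)),
                 sigma_gamma_hat = 0.01, rss = sigma^2 * (rows - 2),
                 rows_used = rows, kappa2 = 1L,
                 xtx_inv = diag(c(s1, s2)^2 / sigma^2),
                 residuals = numeric(rows)),
            class = "nlari_fit")
}
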