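Package: nlari
Title: Nonlinear Autoregressive Modelling of Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, estimation and inference for the nonlinear
    autoregressive integrated (NLARI) model of beat-to-beat heart rate.
    The model describes log heart rate as a stochastic self-restoring
    process with a resistance coefficient, a saturating restoring force
    and Gaussian disturbances.  The package provides the stochastic
    simulator and its deterministic skeleton, bifurcation tools for the
    stability coefficient, ordinary least squares estimation of the
    physiological parameters from RR-interval or heart-rate series, a
    homeostasis test battery with Monte-Carlo critical values,
    noise-driven and stimulus-driven responder fits, parameter
    sensitivity and time-scale aggregation analyses, autoregressive
    spectral (LF/HF) comparisons, and a multiplicative sudden-cardiac-
    death risk score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
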