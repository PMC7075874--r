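---
title: "The NLARI heart-rate model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The NLARI heart-rate model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlari)
```

## The model

`nlari` treats beat-to-beat heart rate as the output of a stochastic
self-restoring system.  Work on the log scale, $X_t = \log \mathrm{HR}_t$
(HR in bpm; for RR intervals in seconds, $\mathrm{HR} = 60/\mathrm{RR}$).
With Gaussian disturbances the conditional mean of $X_t$ is the line
$\mu_t = X_0 + (\omega/\alpha)\,t$, and the detrended component
$Y_t = X_t - X_0 - (\omega/\alpha) t$ — the HRV proper — follows

$$Y_t = (1+\theta_1) Y_{t-1} - \theta_1 Y_{t-2}
      + \theta_2 \frac{-Y_{t-\kappa_2}}{\exp(Y_{t-\kappa_2}^2)}
      + \varepsilon_t, \qquad
  \theta_1 = 1-\alpha,\; \theta_2 = \beta,\;
  \varepsilon_t \sim N(0, \sigma^2).$$

The three forces have direct physiological readings: $\varepsilon_t$
(mean $\omega$, sd $\sigma$) is the stream of metabolic
disturbances; the saturating restoring term
$-\beta Y e^{-Y^2}$ models the parasympathetic-versus-sympathetic
correction, strongest for moderate deviations and vanishing for extreme
ones; the $\alpha$-damping models myocardial electrical resistance to
fast rate changes.  The resistance lag is fixed at $\kappa_1 = 1$ (the
form in which the equations are stated); the restoration lag $\kappa_2$
defaults to 1 and is configurable — an even $\kappa_2$ (e.g. 10) makes
the dependence oscillate slowly, which `acf_curve()` detects.

Two derived indicators summarise a record: the slope indicator
$\eta_1 = \omega/\alpha$ (slope of the mean heart-rate line per beat)
and the amplitude indicator $\eta_2 = \sigma/\beta$ (how far HRV swings
relative to the restoring strength).

### Regimes and bifurcations

The stability coefficient $\gamma = \beta/(4 - 2\alpha)$ controls the
noise-free skeleton: the origin is exponentially asymptotically stable
for $0 < \gamma < 1$; a period-two cycle $(-1)^t\sqrt{\ln\gamma}$ is
stable for $1 < \gamma < \sqrt e$; beyond $\sqrt e$ the dynamics are
unstable.  $\beta = 0$ removes the restoring force entirely and leaves a
unit-root process.  The intervals are open: `classify_regime()` reports
$\gamma = 1$ and $\gamma = \sqrt e$ with an explicit boundary flag
rather than folding them into either side.

`find_stability_boundary()` verifies these thresholds empirically: it
bisects on $\gamma$ (varying $\beta$ at fixed $\alpha$) an indicator of
whether the deviation of iterates from the candidate attractor still
shrinks after a transient.  Defaults: 2000 transient steps, a 5000-step
probe window, start value 0.1 (any nonnull start works; 0.1 is small
enough to stay in the basin and large enough to avoid underflow),
deviation compared between the first and last fifth of the window with
a 0.99 shrink factor.  A probe whose trajectory trips the divergence
guard counts as unstable.  The stable fixed point is *not globally*
stable, so all iteration paths carry a guard (default $|Y| > 10^6$)
that aborts with the offending step rather than overflowing silently.

### Simulation

`simulate_nlari()` iterates the $Y$ recursion (a small C++ kernel; the
innovations are drawn in R from one seeded generator and stored in the
result, so every run is exactly replayable) from a zero initial history,
discards a burn-in prefix (default 500 steps, enough for the
autocorrelation of stable-regime parameter sets to die out), and
reconstructs $X_t = x_0 + \eta_1 t + Y_t$.  Simulating $Y$ and adding
the trend is equivalent to iterating the $X$ recursion with explicit
$\mu_t$ for Gaussian noise, and numerically simpler.  The default level
$x_0 = \log 60$ corresponds to a 60 bpm baseline.

## Estimation

Differencing gives the regression form
$\Delta Y_t = \theta_1 \Delta Y_{t-1} + \theta_2(-Y_{t-\kappa_2}
e^{-Y_{t-\kappa_2}^2}) + \varepsilon_t$.  The pipeline
(`estimate_nlari()`) is:

1. $X_t = \log$ HR (natural log — it makes the log transform and the
   $e^{-Y^2}$ kernel symmetric, and keeps the data small in magnitude,
   which matters because the estimator can be inconsistent after very
   large shocks);
2. remove the OLS line $X_t = a + bt$ (always, even when $\hat b
   \approx 0$); $\hat b$ estimates $\eta_1$;
3. OLS on the differenced form via the normal equations
   $\hat\theta = (Y'Y)^{-1}Y'y$, with classical standard errors
   $s_i = \hat\sigma\sqrt{[(Y'Y)^{-1}]_{ii}}$,
   $\hat\sigma = \sqrt{RSS/(n-2)}$ (the $n-2$ denominator is part of
   the method's definition), and the delta-method standard error for
   $\hat\gamma$.  No robust/HAC variants: the classical formulas are
   the method;
4. map back: $\hat\alpha = 1-\hat\theta_1$, $\hat\beta = \hat\theta_2$,
   $\hat\gamma = \hat\theta_2/(2(1+\hat\theta_1))$,
   $\hat\omega = \hat b(1-\hat\theta_1)$, $\hat\eta_1 = \hat b$,
   $\hat\eta_2 = \hat\sigma/\hat\theta_2$.

The first $\max(3, \kappa_2+2) - 1$ observations are dropped as
presample (the alternative — assuming presample values — changes
nothing materially at the 900-beat windows the method targets);
`rows_used` is the effective $n$ in every degrees-of-freedom formula.
Because a wandering series can push the restoring regressor many orders
of magnitude below the $\Delta Y$ regressor, the solver normalises
columns before inverting; this is exact algebra, not regularisation,
and rank-deficient designs (e.g. $Y \equiv 0$) raise an error.

## The homeostasis test battery

`homeostasis_test()` decides whether a record is consistent with the
stable homeostatic responder, i.e. the process within the stable
fixed-point range.  Four sub-tests must all pass:

1. the $1-\alpha$-level confidence intervals
   $\hat\theta_i \pm t_{n-2}\, s_i$ fall inside $(-1,1)$ and $(0,4)$
   (the theoretical intervals of the stable range); the multiplier is
   the two-tailed Student-$t$ critical value with $n-2$ df;
2. the F-test rejects $\gamma = 1$.  Substituting the restriction
   $\theta_2 = 2(1+\theta_1)$ into the differenced model gives the
   restricted one-regressor regression of
   $\Delta Y_t + 2Y e^{-Y^2}$ on $\Delta Y_{t-1} - 2Y e^{-Y^2}$, whose
   minimised residual sum RSS$_0$ enters
   $F = (RSS_0 - RSS_1)/(RSS_1/(n-2))$ against $F(1, n-2)$.  Writing
   the restricted fit this way (rather than any fixed plug-in
   $\theta_1$) is required for $F \ge 0$ and for the test to hold its
   size: simulated exactly at $\gamma = 1$, the rejection rate matches
   the nominal level (the suite checks this);
3. the $\gamma_n$ statistic
   $\gamma_n = 4\sqrt{\pi n(32\hat\sigma^6)^{-1}}
   \sqrt{1-\hat\theta_1}\,\hat\theta_2$ rejects $\gamma = 0$ when it
   falls outside the critical pair, by default the tabled values
   $(-3.50, 11.9)$.

### Calibration caveat for $\gamma_n$

The package's own Monte Carlo shows that the null distribution of
$\gamma_n$ under $\beta = 0$ is **strongly scale-dependent**: for fixed
fitted coefficients the statistic carries $\hat\sigma^{-3}$, and across
the null ensemble it scales roughly like $n^{1/4}\sigma^{-3/2}$.  The
fixed pair $(-3.50, 11.9)$ therefore cannot be appropriate for every
$(n, \sigma)$; at physiological scales ($\hat\sigma \approx 0.03$
log-HR units) even a pure random walk produces $\gamma_n$ in the
thousands and would be "rejected".  For a decision that actually
discriminates the unit-root null, calibrate with
`null_critical_values()` at a `sigma_null` matched to the record's
residual scale (and `detrend = TRUE` to mirror the pipeline), and pass
the result to `homeostasis_test(cv = ...)`.  The two-sided test
allocates half its level to each tail by default (`tail_split = 0.5`),
both configurable.  `limit_ratio_sim()` draws the asymptotic reference
functional $W(1)/\sqrt{L(1,0)}$ (Brownian endpoint over root local
time, local time estimated on a discretised path with window
$\varepsilon = N^{-1/4}$) as an independent cross-check of the
Monte-Carlo machinery; note that this limiting ratio is symmetric, so
an asymmetric critical pair is necessarily a finite-sample object.

## Responders

For within-sample description and out-of-sample prediction the fitted
model is run as a *responder*:

* **Noise-driven** (`fit_noise_driven`, `predict_out_of_sample`):
  innovations drawn $N(0, \hat\sigma^2)$; the coefficients are tuned
  over the confidence box $\hat\theta_i \pm t\,s_i$ (21×21 grid by
  default) to bring the output as close as possible to the observed
  HRV.  "As close as possible" is operationalised as minimum RMSE, and
  the objective is de-noised by taking the median over seeded
  realizations (default 20) that share innovations across candidates
  (common random numbers), so the search is exact under one seed.  For
  prediction the series is split at $\lfloor n/2\rfloor$, the model is
  fit in-sample, and the in-sample trend line is extrapolated to
  detrend the out-sample half — using the out-sample trend would leak
  information.
* **Stimulus-driven** (`fit_stimulus_driven`): the innovations are the
  observed deviations clipped at a threshold $c > 0$,
  $\hat\varepsilon_t = \mathrm{clip}(Y_t, \pm c)$, with coefficients
  fixed at the OLS estimates and $c$ tuned by grid search.  The
  autoregressive and restoring terms are evaluated at the *observed*
  lagged values.  This was a genuinely open design point (observed
  versus fitted feedback); the package uses observed lags because with
  fitted feedback the clipped *level* of $Y$ enters an integrating
  recursion and the trace double-integrates, destroying exactly the
  property the stimulus variant exists for — tracking series at the
  edge of stability ($\gamma \approx 0$) where the noise-driven
  responder reduces to an unrelated random path.  The suite asserts
  the stimulus fit beats the noise fit on near-unit-root series.

`acf_curve()` supports the qualitative comparisons: it flags long
memory when the ACF tail exceeds the exponential envelope implied by
the initial decay, or when the ACF swings between significantly
positive and negative values more than once (the signature of an even
restoration delay).  Both criteria are heuristics with the stated
thresholds; they are validated in the suite against white noise and
$\kappa_2 = 10$ simulations.

## Sensitivity analysis

`sensitivity_table()` quantifies how the estimated parameters respond
to shifts in the disturbance stream: a mean shift $\omega_i$ (effective
mean $\omega + \omega_i$, trend slope $(\omega+\omega_i)/\alpha$) or an
added noise stream of sd $\sigma_i$ (effective innovation sd
$\sqrt{\sigma^2 + \sigma_i^2}$).  The sensitivity of parameter $\phi$
is the ratio of relative changes,
$S(\omega_i,\phi) = |(\phi_i - \phi)\,\omega/(\omega_i\,\phi)|$ and
$S(\sigma_i,\phi) = |(\phi_i-\phi)\,\sigma/
[(\sqrt{\sigma^2+\sigma_i^2}-\sigma)\,\phi]|$, with $\phi_i$ the
average estimate over seeded replicates of the disturbed process.
Classification: perfectly insensitive ($S = 0$), insensitive
($S < 1$), unit sensitive ($S = 1$), sensitive ($S > 1$).  Mean shifts
report $\phi \in \{\alpha,\beta,\gamma,\sigma,\eta_2\}$; sd shifts
$\phi \in \{\omega,\alpha,\beta,\gamma,\eta_1\}$.

The baseline $\phi$ is, by default, the average estimate from
*undisturbed* replicates rather than the generating value: finite-sample
estimator bias is common to both arms and cancels from
$\phi_i - \phi$, so $S$ measures the effect of the disturbance, not of
the estimator (`baseline = "params"` restores the raw comparison).  The
documented grids are $\omega_i = 0.00004\,i$ and $\sigma_i = 0.007\,i$,
$i = 1,\dots,20$, at 900-beat windows.  Within the stable regime
(base $\alpha = 0.7786$, $\beta = 0.3$, $\sigma = 0.0275$,
$\omega = 10^{-4}$) all sensitivities stay below 1; on the boundary of
the stable range the representative base is $\gamma = \beta = 0.0171$,
which pins $\alpha = 1.5$ (since $\gamma = \beta/(4-2\alpha)$), and
there the sd-shift sensitivities of $\beta$ and $\gamma$ exceed 1.
Replicates default to 300 per grid point in the acceptance script and
fewer in unit tests; the statistic stabilises well before that.

## Time-scale analysis

Enlarging the observation scale is block-mean aggregation,
$Y^{(m)}_t = m^{-1}\sum_{i=1}^m Y_{(t-1)m+i}$, length
$\lfloor T/m\rfloor$ (`aggregate_series()`).  `scale_sweep()` simulates
at base scale, aggregates, re-estimates, and averages over replicates.
Two regimes matter: at $m = 1$ the base parameters are recovered; at
minute scale (beats are treated as 1 s apart, so $m = 60$) the
aggregated series of a short-memory stable process approaches
small-amplitude white noise, for which the differenced-model fit has
the analytic limit $\hat\theta_1 \to 0$, $\hat\theta_2 \to 1$ — i.e.
$\hat\alpha$ and $\hat\beta$ converge to the common value 1 and stop
carrying physiological information.  (The white-noise limit requires
*small-amplitude* noise: the population normal equations give
$(\theta_1,\theta_2) = (0,1)$ exactly in the linear range of the
restoring kernel, and aggregation shrinks the scale by $1/\sqrt m$ into
that range; the suite checks both the analytic limit on simulated white
noise and the $m = 60$ sweep.)  The acceptance script runs the sweep at
$m = 60$ with 100 replicates of length 60000; the vignette-level
default sizes keep unit tests in seconds.

## Spectral comparison

`ar_psd()` fits an AR model (Burg by default — the standard choice for
short HRV segments; Yule-Walker optional) and evaluates the one-sided
density $S(f) = 2\sigma_p^2|1-\sum_k a_k e^{-2\pi i f k}|^{-2}$ on
$[0, 0.5]$ cycles/sample, normalised so its integral matches the series
variance.  `band_powers()` integrates the conventional bands VLF
0–0.05, LF 0.05–0.15, HF 0.15–1.0 Hz by the trapezoidal rule, treating
samples as 1 s apart so cycles/sample read as Hz; the HF band then
extends past the Nyquist frequency 0.5 and is truncated there, which
the result records (`hf_truncated_at`).  The LF/HF ratio is reported
only when HF power is positive.

Two sweeps connect the spectrum to the restoration coefficient.
`frequency_beta_sweep()` measures the characteristic frequency of
simulated series — by mean zero-crossing rate by default ("frequency of
a time series" has no canonical definition for irregular series;
zero-crossing is model-free, and an AR-peak alternative is provided) —
across $\beta$ and aggregation scales: frequency rises with $\beta$ at
base scale and becomes insensitive to $\beta$ at strongly enlarged
scales.  `lfhf_vs_beta()` reproduces the realization-level LF/HF
design (AR(16), $T = 1500$, scale $m = 3$, several seeded realizations
per $\beta$, because parametric PSD estimates of this process vary
strongly between realizations).  In this pipeline the LF/HF ratio
falls as $\beta$ grows over the low range ($\beta \le 0.1$); over
$\beta \in [0.6, 1.6]$ it keeps falling rather than rising, since
larger $\beta$ pushes the spectral peak into the HF band and the
fold-back into LF after $m = 3$ averaging is sinc-attenuated.  The
suite asserts only the low-range trend; the high-range behaviour is a
known limitation of the reproduction and is flagged openly in the
acceptance battery rather than hidden.

## Group assessment and the SCD risk score

`group_assessment()` pools per-window estimates over the $p$ periods
and $q$ subjects of a group: mean $(pq)^{-1}\sum\sum\hat\phi_{ij}$ and
sd with denominator $pq - 1$.  `compare_to_control()` reports
per-parameter ratios against a control group with qualitative labels at
configurable thresholds (1.25 for increase/decrease, 2 for the "ultra"
bands — the bands are descriptive, not inferential).  `scd_risk()`
combines resistance excess, metabolic-variability excess and stability
deviation relative to control standards $(\alpha_c,\sigma_c,\gamma_c)$:

$$\rho = \frac{\alpha}{\alpha_c}\cdot\frac{\sigma}{\sigma_c}\cdot
  \begin{cases}\gamma_c/\gamma, & \gamma \le \gamma_c\\
  \gamma/\gamma_c, & \gamma > \gamma_c.\end{cases}$$

$\rho$ is continuous across the branch point and deviation of
$\gamma$ in either direction raises it.  Control standards are supplied
by the user (typically healthy-young group means via
`group_assessment()`); the package hard-codes none.

## The synthetic-data generator

`make_fixture()` emulates the shape of typical analysis data: 900-point
windows of NLARI-generated log-HR with a linear trend, Gaussian
innovations, and parameters spanning the stable range and its
boundaries.  Presets:
stable fixed point ($\omega = 10^{-4}$, $\sigma = 0.0275$,
$\alpha = 0.7786$, $\beta = 0.3$, i.e. $\gamma \approx 0.123$,
$\eta_2 \approx 0.092$ — the documented stable-regime set), unit root
($\beta = 0$), and two-cycle ($\gamma = 1.2$).  Output is plain text
(RR seconds or HR bpm) plus a JSON manifest of the generating
parameters, and identical specifications produce byte-identical files.

What the generator does *not* emulate — and hence what green tests do
not certify about real recordings: ectopic beats and artefacts,
heart-rate asymmetry (the model is intrinsically time-symmetric),
non-Gaussian or heavy-tailed disturbances, slow nonstationarity beyond
a linear trend, and the record-selection/windowing choices of any
particular archive.  Estimates on real data should be read with those
caveats.

## Numerical choices, in one place

* burn-in 500, zero initial history for stochastic runs; start value
  0.1 for deterministic probes;
* divergence guard $|Y| > 10^6$, error names the step;
* bisection: 2000-step transient, 5000-step probe, shrink factor 0.99;
* OLS: column-normalised normal equations; errors on rank deficiency;
* presample start $t = \max(3, \kappa_2 + 2)$;
* responder search: 21×21 grid, 20 realizations, median-RMSE objective,
  common random numbers; stimulus threshold grid spans $(0, \max|Y|]$
  in 25 steps by default;
* ACF flags: significance band $2/\sqrt n$, envelope from the
  pre-sign-change lags, tail = last third of lags;
* AR spectra: Burg, order 16, 512 frequencies;
* Monte-Carlo critical values: empirical quantiles with density-based
  standard errors; default null $\theta_1 = 0$, $\sigma = 1$,
  configurable (see the calibration caveat above);
* all randomness flows from explicit seeds; replicate seeds are derived
  deterministically from the base seed.

## Known limitations

* The fixed $\gamma_n$ critical pair is not scale-portable (see the
  calibration caveat); decisions about $\gamma = 0$ should use matched
  Monte-Carlo critical values.
* The minute scale is outside the model's useful range by construction
  — that is a finding (estimates converge to 1), not a defect, but it
  means the package cannot extract physiology from minute-averaged
  data.
* The high-$\beta$ LF/HF trend of the spectral comparison does not
  reproduce in this pipeline (details above).
* Heart-rate asymmetry cannot be captured: the model's deterministic
  core is symmetric under time reversal.
* Estimation assumes the log-scale data stay within the restoring
  kernel's active range; very large shocks can make the estimator
  inconsistent, which the log transform mitigates but does not
  eliminate.
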