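---
title: "Methods: estimating the oxygen cost of ventilation during ramp exercise"
author: "ventcost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the oxygen cost of ventilation during ramp exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventcost)
```

## The problem

During a ramp-incremental cycle test (RIE), whole-body oxygen uptake
(V̇O2) rises with power output. Part of that oxygen is consumed not by the
locomotor muscles but by the respiratory muscles driving the rising minute
ventilation (V̇E): the *oxygen cost of ventilation*, V̇O2vent. Measuring
V̇O2vent directly requires hyperventilation-mimicking trials with CO2-enriched
inspirate, which most testing environments cannot run. `ventcost` implements a
predictive alternative: a composite non-linear regression of peak V̇O2vent on
six routinely measured quantities — peak V̇E (L·min⁻¹, STPD), age (years),
weight (kg), height (cm), V̇O2 peak (L·min⁻¹) and maximal heart rate
(beats·min⁻¹) — derived from a 42-participant cohort of ventilation-mimicking
experiments, which is packaged verbatim (`table1_cohort()`).

## The composite model

The model is a sum of single-predictor shapes chosen per predictor by lowest
standard error: a cubic in V̇E, a cubic in weight, an exponential in height,
and linear terms in age, V̇O2 peak and HRmax,

$$\widehat{\mathrm{VO_2vent}} = \sum_{j=1}^{5} c_{0j}
  + v_1 VE + v_2 VE^2 + v_3 VE^3
  + w_1 W + w_2 W^2 + w_3 W^3
  + h_s e^{h_r H} + a_1 A + p_1 P + r_1 HR ,$$

sixteen printed constants in all (`published_composite()`). Only the *sum*
of the five additive constants is identifiable — `effective_intercept()`
reports it, and predictions are invariant to shifting mass among the five
(tested by random redistribution). The six stand-alone single-predictor
relationships are also available (`published_submodels()`,
`fit_submodel()`); note that the stand-alone height exponential uses its own
rate (0.01293 per cm) while the composite uses a much smaller one
(0.00006302 per cm) — both are preserved, each in its own coefficient set.

Units: all V̇O2 and V̇E quantities are L·min⁻¹ and V̇E must be STPD.
`btps_to_stpd()` converts BTPS volumes by the product of a temperature ratio
and a pressure ratio, `273/(273 + T_b) × P_B/760`, with defaults
T_b = 37 °C and P_B = 635 mmHg (the site pressure of the derivation data;
configurable). No saturated-water-vapor term is included by default because
the conversion the derivation data used has none; `vapor_correction = TRUE`
applies the textbook `P_B − 47` substitution for users who want it.

## Refitting: profiled least squares

`fit_composite()` refits the same functional family to any cohort with
measured V̇O2vent. The family is linear in all coefficients except the
height rate $h_r$, so rather than a 16-parameter black-box optimizer we
profile: for each candidate $h_r$ the remaining 11 identifiable coefficients
are solved exactly by QR least squares, and the profiled RSS is minimized
over $h_r$ by a coarse grid (41 points over ±0.06 per cm, plus the published
rate as a candidate) followed by golden-section refinement. The fit is
declared converged when one further local refinement cannot reduce the RSS
by more than 1e-8 relative — the same convergence notion used when the model
was first fitted. Profiling matters because near $h_r = 0$ the height term
degenerates into the intercept (at exactly 0 the design is rank-deficient,
which is why the profile has a spike there), making naive full non-linear
iteration unstable.

On the packaged derivation cohort the profile attains RSS ≈ 0.673,
R² ≈ 0.814 at $h_r ≈ −0.032$; the published coefficient set evaluates on the
same cohort to RSS ≈ 0.683, R² ≈ 0.812. A property test checks on small
cohorts that the profiled optimum matches a dense 4001-point grid to 1e-6.

Refits cannot resolve the five-way constant split, so they return
`c0_list = (intercept, 0, 0, 0, 0)` with `provenance = "refit"`. Negative
predictions are clamped to zero with a warning (the raw values stay in the
`"unclamped"` attribute), and predictors outside the derivation ranges warn
rather than error.

## Internal validation: two error scales, deliberately both

`loocv()` holds out each subject, refits on the rest and predicts the
held-out subject, then pools. Its report carries *two* metric blocks:

* the honest held-out metrics (`rmse`, `mae`, `r2`, `adjusted_r2`,
  calibration of predicted on observed), and
* the `apparent` in-sample metrics of the full-cohort refit.

They are kept side by side because they answer different questions and are
easy to conflate: for an OLS-type fit the in-sample RMSE is exactly
`sqrt(RSS/n)` and the in-sample calibration regression obeys the identities
slope = R², intercept = (1 − R²)·mean(observed) — so apparent metrics can
masquerade as cross-validated ones. On the packaged derivation cohort the
apparent values are RMSE ≈ 0.127, MAE ≈ 0.097, calibration ≈ 0.81/0.16,
while the honest held-out values are RMSE ≈ 0.17 and MAE ≈ 0.14: with 12
effective parameters on 41 training subjects per fold, genuine held-out
error sits well above the in-sample scale. This gap is intrinsic — it is
essentially unchanged whether the height rate is re-profiled per fold,
re-optimized locally, or frozen. The acceptance suite asserts the identities
and the apparent values, and reports the honest held-out values at the same
tolerances; the held-out assertions document the optimism gap rather than
being relaxed to hide it.

`bootstrap_validation()` resamples subjects with replacement to the original
size and reruns the pipeline per resample, recording both families again:
apparent (refit on the resample; the adjusted R² here is the distribution
the headline adjusted-R²-with-CI estimate belongs to) and within-resample
LOOCV, where all duplicates of a held-out subject leave the training fold
together so a subject never predicts itself. Intervals are percentile 95%
(not BCa), the seed is mandatory and recorded, and the same seed reproduces
the report bit for bit.

`collinearity()` reports pairwise Pearson correlations among the six
predictors and VIFs from the regress-each-on-the-rest definition; a test
confirms the VIFs equal the diagonal of the inverse correlation matrix. On
the derivation cohort the strongest pair is V̇O2 peak with height
(r ≈ 0.761) and all VIFs are below 5. `residual_diagnostics()` adds an OLS
trend of residuals on predictions as a drift check.

## Applying the model to breath-by-breath data

Within one test only V̇E varies among the six predictors, so
`predict_vent_series()` slides the instantaneous (typically seven-breath
averaged, `average_breaths()`) V̇E through the model with the other five
predictors fixed at the subject's values. How the original LabVIEW-style
application produced submaximal values is not documented anywhere, so this
choice is made explicit here; a `"peak_anchored"` mode (peak prediction
scaled by V̇E(t)/V̇E_peak) and an optional `rest_offset` (subtract the
prediction at baseline V̇E, off by default because resting V̇O2vent is
genuinely unresolved) are provided as alternatives.

`correct_series()` forms V̇O2vcorr = V̇O2 − V̇O2vent samplewise. The stored
V̇O2vent is re-derived as `vo2 - vo2vcorr` (a ≤ 1-ulp adjustment) so the
defining identity holds bit-exactly. `intensity_table()` interpolates
channels *in power* (ramp tests are defined by power, and intensities are
reported as %Wpeak) at 35/55/75/85/95/100% of peak power, using the last
crossing if power is non-monotone. `final_slope()` is the OLS slope over the
final 30 s (inclusive window by time stamp), per minute.
`paired_slope_test()` and `rm_anova()` provide the comparisons used for
corrected-versus-uncorrected analyses: a paired t with Cohen's d on the
differences, and one-way or two-way fully within-subjects ANOVA with
Greenhouse–Geisser correction. The GG epsilon comes from orthonormal
contrasts applied to the sample covariance of the repeated measures
(epsilon is exactly 1 for two-level effects); follow-up paired comparisons
are Bonferroni-adjusted, the common statistical-package convention. An
effect whose sum of squares falls below 1e-12 of its scale is classified as
exactly zero (F = 0) or exactly fitted (F = ∞) so that additive integer
designs do not produce arbitrary ratios of rounding residue.

## The synthetic generator

No raw breath-by-breath series are distributable with the package, so
`generate_subject()` builds one from the known structure of an RIE test:

* power ramps at 36 W·min⁻¹ (the protocol slope of the application
  dataset) from 50 W for 600 s — peak ≈ 410 W, like trained cyclists;
* V̇O2 is first-order (mono-exponential, τ = 30 s) in the ramp with gain
  0.010 L·min⁻¹·W⁻¹ and baseline 0.5 L·min⁻¹, ending near 4.4 L·min⁻¹;
* V̇E is linear in V̇O2 (slope 22, intercept 5 L·min⁻¹) below a
  gas-exchange threshold at 60% of end-test V̇O2, with a smooth
  (C¹-continuous) exponential excess above it (rate 2.2 per L·min⁻¹),
  reaching ≈ 150 L·min⁻¹;
* tidal volume saturates hyperbolically toward 3.0 L while breathing
  frequency rises to supply V̇E (never below 14 breaths·min⁻¹), V̇E = fR·Vt
  exactly, and the breath interval 60/fR shortens as fR rises;
* multiplicative Gaussian noise (SD 5%) perturbs V̇O2 and V̇E per breath.

These defaults were chosen once as representative of trained adults and are
not tuned thereafter. `generate_cohort()` is deliberately *model-true*:
predictors are uniform over the derivation-table ranges (simplicity over a
fitted multivariate anthropometry) and "measured" V̇O2vent is the composite
prediction plus Gaussian noise (default SD 0.13 L·min⁻¹, the derivation
residual scale), with invalid rows redrawn. Model-true data give the
validation machinery a known ground truth: noiseless cohorts must refit to
R² ≈ 1, and noisy ones quantify pure estimation error. What passing tests
on these data do *not* show: robustness to non-uniform anthropometry, to
model misspecification (real V̇O2vent need not follow the composite family),
to V̇E measurement error, or to non-ramp protocols.

## Numerical choices and test problem sizes

* Profile bracket ±0.06 per cm, 41-point grid, golden-section to machine
  tolerance; convergence at 1e-8 relative RSS.
* Cubic sub-models are fitted on a centered/scaled basis and reported in
  raw powers; the exponential-growth sub-model starts from both a
  log-linear fit and the published pair, keeping the lower RSS.
* Percentile bootstrap with 500 iterations for reported intervals; unit
  tests use 100–150 iterations on cohorts of 16–42 subjects, and
  prediction-recovery checks use 20 replicate cohorts of n = 200. These
  sizes are the package's choices for routine checking; the full-size runs
  are in the acceptance material.
* The bootstrap coefficient-coverage check is asserted only for the age,
  V̇O2 peak and HRmax terms: near the published height rate the height
  scale/rate pair is practically unidentifiable (the profile is nearly
  flat), so individual recovery of those two is ill-posed even though
  predictions are stable.

## Known limitations

The derivation cohort is 42 healthy, mostly trained adults; predictions
outside its predictor ranges warn for a reason. The model family was fixed
by the original derivation — no form search is re-run. Honest held-out
accuracy is materially worse than apparent accuracy at this sample size
(see above), and resting V̇O2vent handling remains unresolved. The
percent-of-maximum summary is computed as 100·part/whole throughout; a
verbal description of it as a "difference … multiplied by 100" circulates
but is inconsistent with the tabulated values it accompanies, so the ratio
form is used.
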