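---
title: "Methods: agreement analysis and calibration of paired thermometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement analysis and calibration of paired thermometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A method-comparison study asks whether a cheap test instrument (here a
smartphone-attached thermal camera reading skin temperature) can stand in for
a reference instrument (a non-contact infrared thermometer). The design is
repeated-measures: each participant is measured many times by both devices in
each of two environmental rounds — a stable round (R1) and a dynamic round
(R2) that mimics clinical repositioning. Two distinct questions follow:

1. **Agreement** — how precise is each device, how large and how variable is
   the between-device difference, and is the disagreement clinically
   acceptable?
2. **Calibration** — how much of the disagreement can a learned mapping
   `reference ≈ f(test)` remove, and how much is irreducible sensor noise?

`thermocal` implements both stages plus a synthetic study generator so that
the whole pipeline is testable without access to raw participant data.

## Data model and sign convention

All functions operate on a long measurement table (one row per reading:
participant, round, device, replicate index, temperature in °C) or on its
paired form, where replicate *i* of the test device is matched with replicate
*i* of the reference device within each `(participant, round)` cell. Pairing
by index is the only option the sequential measurement protocol admits.

The difference is always `diff = test − reference`. A test camera that reads
low therefore has a *negative* bias (about −1.4 °C in the stable round of the
kind of study emulated here). All downstream statistics inherit this
convention.

## The synthetic study generator

`generate_study()` simulates, for participant *p* and round *r*:

* a true skin temperature `μ_pr ~ N(pop_mean_r, pop_sd)`,
* a participant-specific device bias `b_p ~ N(0, participant_bias_sd)`,
* reference readings `μ_pr + ε_i`, `ε_i ~ N(0, ref_noise_sd_r)`,
* test readings
  `μ_pr + β0_r + β1 (μ_pr − pop_mean_r) + b_p + η_i`, `η_i ~ N(0, test_noise_sd_r)`,

with readings quantised to the devices' 0.1 °C display resolution. A negative
`β1` makes the camera over-read cool skin and under-read warm skin — the
"X-shaped" temperature-dependent bias typical of uncooled microbolometer
sensors. `implied_moments()` gives the closed-form replicate-level mean and
SD of the differences and the between-device correlation, and is the oracle
against which the generator is tested.

### Default parameters and how they were chosen

The default configuration reproduces the published summary statistics of a
40-participant, two-round, 15-replicate study (2400 readings): replicate
noise SDs 0.030/0.093 °C (reference) and 0.340/0.300 °C (test), mean biases
−1.42/−1.15 °C, and population means 35.50/34.08 °C — all taken directly as
study conditions.

Three parameters are not printed anywhere and were **moment-matched**: we
minimised the squared discrepancy between the closed-form moments of
`implied_moments()` and four targets — the difference SDs implied by the
published limits of agreement (6.03/3.92 = 1.541 °C and 6.28/3.92 = 1.602 °C)
and the between-device correlations (0.788/0.760). The difference SD far
exceeds the combined replicate noise (≈0.34 °C), which *forces*
between-participant bias heterogeneity into the model; this is why `b_p`
exists. The four moments do not identify `β1` (the unconstrained fit drifts
to `β1 = 0`, which would erase the temperature-dependent bias), so `β1` was
fixed at −0.25 — a moderate slope that produces a clearly negative trend of
difference against mean — and the remaining two parameters fitted:
`pop_sd = 2.372 °C`, `participant_bias_sd = 1.418 °C`. The resulting implied
moments are SD ≈ 1.57 °C and r ≈ 0.77 in both rounds, a compromise across the
four targets.

A between-participant SD of 2.4 °C is realistic for hand-dorsum skin
temperature, which varies far more across people than core temperature does.

### What the generator does and does not emulate

It reproduces the *statistical* structure: noise scales, bias level and its
temperature dependence, participant clustering, display quantisation, and
(optionally) the reference device's 32–42.9 °C measurement range via
`clamp_ref_range` (off by default for transparency). It does **not** model
physical radiometry — emissivity error, sensor drift within a session,
distance effects, or non-Gaussian outliers from mis-aimed spot meters. Tests
passing on generated data therefore validate the estimators and the
pipeline's bookkeeping, not the devices themselves; conclusions about real
hardware require real readings.

## Agreement statistics

* **Precision**: the sample SD (n−1) of the replicates per
  `(participant, device, round)`, averaged over participants per device and
  round.
* **Bland–Altman**: bias = mean difference, 95% limits of agreement
  `bias ± 1.96 × SD(diff)`. The multiplier is fixed at 1.96; the small-sample
  t-based variant and the repeated-measures variance-component correction are
  deliberately out of scope. The default analysis level is
  `participant_means` (one difference of per-device means per participant, 40
  units in the default design); `replicates` level is available because the
  level used for some published statistics is ambiguous in such studies.
* **ICC(2,1)**: two-way random-effects, absolute-agreement, single-measure
  form on the participants × devices matrix of per-participant means.
  Absolute agreement is the right form here because a constant offset between
  devices *is* disagreement.
* **Tests**: Shapiro–Wilk as a normality gate (α = 0.05), paired and
  one-sample t-tests (two-sided; they error on zero-variance differences
  rather than emitting an unusable statistic), Pearson correlation within
  rounds, the correlation of round-to-round changes between devices, and a
  one-way ANOVA of per-participant bias across participant groups.

## The calibration suite

Ten models map test readings to reference readings, spanning three families.
Defaults in parentheses.

**Robust statistical baselines**

* *Robust polynomial* (degree 2, ε = 1.35, ridge α = 0): polynomial basis on
  the standardised predictor under Huber loss via IRLS. The Huber scale is
  re-estimated each pass as 1.4826 × median |residual|; convergence when the
  largest coefficient change is below 1e−8, with a 200-iteration cap.
  When all residuals fall within ε × scale the fit is exactly least squares.
* *Deming regression*: closed-form errors-in-variables line. The error
  variance ratio δ is estimated from the data as the ratio of pooled
  within-participant replicate variances (reference over test), pooled as the
  mean of per-cell variances. Note that this estimator captures replicate
  noise only; systematic per-participant bias heterogeneity is not part of
  it, which matters when interpreting the slope on clustered data.

**Non-parametric smoothers**

* *Isotonic* : exact weighted pool-adjacent-violators, written here as the
  package's own primitive (`pava()`) and verified in tests against
  brute-force enumeration of all monotone block partitions. Ties in x are
  collapsed to weighted means first. Between knots the prediction
  interpolates linearly; outside the training range it extends the boundary
  values. The interpolation rule is a package choice — a pure step function
  would be equally defensible.
* *Huber spline* (6 quantile-spaced knots, ε = 1.35): natural cubic spline
  basis, Huber IRLS as above. "6 knots" means six knots in total, the outer
  two serving as boundary knots.
* *Local regression* (frac = 0.25, 1 robustness pass): degree-1 weighted
  least squares over the ⌈frac·n⌉ nearest neighbours with tricube weights,
  plus bisquare robustness reweighting (scale 6 × median |residual|). Implemented
  directly so the neighbourhood, weights, and iteration count are exactly as
  stated, and so prediction at arbitrary x is a local fit at that x.
* *Weighted spline* (6 knots, 10 equal-count bins): a pilot isotonic fit
  supplies residuals; per-bin residual variances (floored at 1e−6 °C² so a
  perfect pilot fit cannot produce infinite weights) give inverse-variance
  weights for a weighted natural-spline fit. Bins with fewer than two points
  trigger automatic bin reduction with a warning.

**Tree ensembles**

* *Quantile GBRT* (400 trees, learning rate 0.05, depth 3): one boosted model
  per quantile {0.025, 0.5, 0.975} under pinball loss; the median model is
  the point predictor and the outer pair the 95% interval. Quantile crossing
  is repaired by sorting the three outputs per point — the simplest
  order-restoring operator.
* *Monotone boosted median* (600 trees, learning rate 0.03, 31 leaves,
  leaf-wise growth): the median model carries a hard non-decreasing
  constraint. Because the built-in quantile objective of the boosting
  backend bypasses monotone leaf bounds, the constrained median is trained
  with an explicit pinball objective (gradient −τ/1−τ, unit curvature),
  which routes through the standard leaf machinery where the constraint is
  enforced; tests assert non-decreasing predictions on a dense sorted grid.
  The flanking 0.025/0.975 models are unconstrained.
* *Random forest / extra trees* (400 trees, leaf size 5; bootstrap on for the
  forest, off for extra trees): variance-reducing ensembles; their intervals
  come from the conformal route below.

All stochastic fits take an explicit integer seed and run single-threaded, so
the whole suite is bit-reproducible given (data seed, fold seed, model seed).

## Evaluation protocol

* **Grouped cross-validation**: participants are shuffled once (seeded) and
  dealt round-robin into k = 5 folds, so fold sizes differ by at most one
  participant and every row of a participant stays on one side of each
  split. The training/test participant disjointness is asserted inside
  `cross_validated_predictions()` on every fold of every run. The test suite
  also demonstrates *why* this matters: a 1-nearest-neighbour memoriser looks
  near-perfect on resubstitution and collapses out of fold on
  participant-clustered readings.
* **Metrics**: MAE, RMSE, R², bias (mean error) and Bland–Altman limits of
  the out-of-fold prediction errors, one row per model plus an uncalibrated
  `raw` row, all models sharing identical folds. Both rounds are pooled by
  default; per-round analysis is available by filtering the paired table.
* **Hyperparameter search**: exhaustive over the documented ranges, selected
  by out-of-fold MAE (ties: RMSE, then grid order), on the *same* outer
  folds. Flat selection slightly optimistically biases the selected model's
  metrics; we keep one CV layer because the evaluation protocol being
  reproduced uses one. Nested CV would be the defensible alternative if the
  metrics were to be published as unbiased estimates.
* **Intervals**: quantile-capable models supply their own 95% intervals;
  point estimators get split-conformal intervals, `point ± q`, where q is the
  ⌈(m+1)(1−α)⌉-th smallest out-of-fold absolute residual (infinite when the
  index exceeds m — the honest answer for tiny calibration sets). Coverage is
  marginal, not participant-conditional.
* **Deployment**: `fit_deployment()` refits the chosen model on all rows and
  wires the appropriate interval machinery.

## Problem sizes in the test suite

The statistical tests run at sizes chosen to keep Monte-Carlo error well
below the asserted tolerances while staying quick: moment-recovery at 4,000
participants, parameter recovery for Bland–Altman and Deming at 1,000
participants, conformal coverage averaged over 200 replicate simulations of
600 points, quantile coverage on 10,000 held-out points, and the full suite
at the default 40-participant design. The suite verifies qualitatively that
every calibrator removes the raw bias while no model's RMSE drops below the
reference device's own replicate noise — calibration fixes accuracy, not
precision.

## Known limitations

* Univariate calibration only: ambient temperature, distance and emissivity
  are not features.
* The simple Bland–Altman formula is used even though replicates are
  available; the repeated-measures LoA correction is out of scope.
* Fitted boosted/forest models live in memory; persistence of fitted model
  objects to disk is not provided (the specs and seeds in the run manifest
  are sufficient to refit exactly).
* The generator's clamp reproduces range truncation but no other
  device-specific censoring.
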