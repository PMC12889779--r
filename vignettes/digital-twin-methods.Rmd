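---
title: "Digital-twin modelling of naming recovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin modelling of naming recovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphasiatwin)
```

## The problem

Chronic post-stroke aphasia responds to naming therapy, but individuals
differ widely in how much they gain, and part of that variation plausibly
traces to modifiable health factors — diabetes, hypertension, body-mass
index — alongside fixed factors such as age, lesion anatomy and white-matter
integrity. A *digital twin* in this setting is a per-person predictive model
of the Philadelphia Naming Test (PNT) score that (i) updates as each new
observation streams in across the treatment timeline, and (ii) supports
counterfactual queries: what would this person's predicted final score have
been, had a health factor been different, with everything else — including
the fitted model — held fixed?

`aphasiatwin` implements that analysis end to end. Because individual-level
clinical trial data of this kind cannot be shared openly, the package ships
a synthetic-cohort generator as a first-class, tested component: it emulates
the published marginal structure of a 106-participant chronic-aphasia
treatment cohort, and drives trajectories with a *known* linear
ground-truth process, so that every downstream stage — preprocessing,
streaming estimation, counterfactual accounting — can be validated by
parameter recovery against a known answer.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions; `generate_cohort()` draws them.

* **Continuous demographics** (age, education, BMI, baseline PNT) come from
  truncated normals over eligibility-style ranges (age 21–80 y, education
  8–25 y, BMI 15–55, PNT 0–100). Truncation shifts a normal's mean, so the
  location parameter is *calibrated* (by root-finding on the truncated-mean
  identity) such that the truncated mean equals the published target — e.g.
  sample mean age converges to 60.64 y, not to 60.64 minus a truncation
  bias. The spread parameter is left at the published SD; the realized SD is
  therefore slightly below it, a deliberate trade: calibrating both moments
  would require widening tails the eligibility criteria forbid.
* **Chronicity** (days post-stroke) is right-skewed: a lognormal with the
  target mean and SD of the shifted part, shifted by the 365-day chronicity
  floor.
* **Vascular comorbidity.** Diabetes (24/106), hypertension (52/106) and
  BMI share a latent standard-normal vascular factor with loading 0.4
  (Gaussian copula): marginals stay exactly on target while the three are
  positively correlated, matching the clinical observation that these risk
  factors co-occur. The published table prints both a 59.06% prevalence and
  a 52/106 count for hypertension; the generator follows the count, since
  counts are primary data.
* **Imaging features.** Per-ROI lesion load (nine left-hemisphere language
  ROIs from a JHU-style parcellation) is Beta(0.7, 2); FA is Beta(5, 5)
  rescaled into [0.2, 0.7] per hemisphere, with left-hemisphere FA reduced
  by `0.3 * lesion_load` relative — lesioned tissue has degraded
  microstructure. Connectivity values are standard normal. These shapes and
  couplings are realism knobs, not claims about the source data; all are
  `cohort_spec()` arguments.
* **Missingness.** A configurable fraction (default 2%) of continuous cells
  is masked completely at random; binary and categorical fields stay
  complete.

### Trajectories and their calibration

`generate_trajectories()` draws a baseline score and rolls the
`ground_truth()` recurrence forward for `n_timepoints - 1` steps (default
4 timepoints: baseline, post-treatment-phase-1, post-rest, final — the
two-treatment-blocks-plus-rest design; the exact number of administrations
in the source design is not published, so it is configurable). Scores are
clamped to [0, 100], treating the PNT as percent correct. The default
feature weights follow the expected sign pattern (previous score and FA
positive; age, lesion load, diabetes, hypertension, BMI negative) with
magnitudes chosen to be clinically modest (fractions of a point per step
per unit).

Two ground-truth defaults are calibration constants by construction:
`gain_intercept = 5.136` and `noise_sd = 10.1` were fixed once by a
fixed-point iteration at n = 100,000 so that the clamped treatment-gain
distribution (final minus baseline) has mean ≈ 7.92 and SD ≈ 16.11 points,
the published operating point. Clamping makes these differ from the
back-of-envelope values (7.92/3 per step, and the variance identity
`3·sigma² + 9·Var(signal)`), which is why they were calibrated numerically
rather than derived.

Masked feature cells enter the recurrence at the cohort mean of observed
values: the generative process is treated as acting on a latent complete
record whose masked coordinates sit at the population centre. This keeps
`generate_trajectories()` a pure, reproducible function of its inputs and
mirrors the mean imputation applied downstream.

Trajectory randomness is seeded at `spec$seed + 1`, so one spec determines
cohort and trajectories jointly while the two streams stay distinct.

### What the generator does *not* emulate

Marginals and a simple comorbidity copula are matched; the full joint
distribution of a real cohort (lesion-anatomy covariance across ROIs,
site effects, floor/ceiling-compressed measurement error, informative
missingness, dropout) is not. Passing recovery tests on this synthetic
cohort therefore demonstrates correctness of the *pipeline* — that the
estimator recovers a known process through the real preprocessing chain —
not that comparable accuracy would be achieved on clinical data.

## Preprocessing

`fit_preprocessor()` fits, per continuous feature, on the baseline rows
only: the imputation mean (over observed values), 1st–99th percentile
winsorization bounds, log1p membership, and standardization parameters.
The transform order is fixed: **impute → winsorize → log1p → standardize**,
with standardization parameters computed after the preceding stages so
transformed fit rows have mean 0 and SD 1 exactly.

Numerical choices worth pinning:

* Percentiles use linear interpolation (R `quantile` type 7); on the values
  1..100 the bounds are 1.99 and 99.01. Winsorization bounds depend on the
  interpolation rule, so it is part of the contract.
* A feature joins the log roster iff its adjusted Fisher–Pearson skewness
  on observed values exceeds 1.0 (configurable) *and* its minimum is
  non-negative. The criterion is one-sided by design: log1p corrects right
  skew and is only defined (and monotone-sensible) on non-negative values.
* Standardization uses the sample SD (n − 1). Scalers in some ML libraries
  use the population SD; the distinction rescales weights by
  `sqrt(n/(n-1))` and is absorbed by the linear model.
* Zero-variance features are dropped with a warning; binary features bypass
  the chain as 0/1 indicators; categoricals are one-hot encoded with the
  first (alphabetical) level dropped, so sex contributes one column. An
  unseen level at transform time is an error, never a silent new column.
* The state is frozen after fitting: streamed rows and counterfactual
  edits are transformed with baseline-fit parameters, never refit. This
  keeps counterfactual deltas well defined (edited and original rows pass
  through the identical map) and mirrors pretraining on baseline data.

Drop-first binary encoding has a consequence for counterfactuals: under a
frozen linear model, flipping a single-indicator binary moves every
eligible individual's prediction by exactly ± the weight, so the two flip
directions are exactly antisymmetric. Published analyses of this design
report *asymmetric* direction-specific averages; a frozen linear model with
single-indicator encoding cannot produce that, and the package implements
(and tests) the symmetric semantics while surfacing both directions in the
report.

## The twin model

The twin is a linear model on the post-encoding schema — all static
features plus one `pnt_prev` feature holding the most recent prior score
(a single previous-score column, consistent with reporting previous naming
performance as one weighted factor; baseline could be added as a second
lag by extending the schema). Training is per-observation Adam on the loss
`0.5·(y − ŷ)² + 0.5·λ‖w‖²` with λ = 1e-3 by default and the intercept
unregularized: first/second moment decays 0.9/0.999, bias correction,
ε = 1e-8. The stationary point of the streamed objective is ridge
regression with penalty `n·λ`, which is exactly how the test suite checks
convergence against the closed-form normal-equations solution.

The operating learning rate is 1e-4 — deliberately cautious for an online
clinical model, where each update should nudge rather than rewrite the
twin. At that rate an Adam step has magnitude ≈ 1e-4, so the intercept
could never travel to the outcome scale (~60 points) in a realistic number
of updates; `run_pipeline()` therefore initializes the intercept at the
mean pretraining target and lets updates concentrate on the weights.
Recovery experiments in the tests use a staged schedule (0.05 to travel,
then 0.005 to settle) — a property of those experiments, not of the
operating configuration.

The streaming protocol is **prequential**: within each timepoint
(chronological), participants are visited in a seeded random order; the
model predicts `pnt[t]` from static features plus `pnt[t-1]`, the
prediction is recorded, and only then is one Adam step taken on that
observation. Every recorded prediction is thus out-of-sample for its own
observation. Performance is `evaluate_r2()` at the final timepoint (a
pooled-timepoints mode and a frozen post-hoc mode via
`stream_update(update = FALSE)` are exposed; whether the published R² was
prequential is not stated, so both are available). Pretraining runs 100
epochs by default over shuffled (baseline features → first post-baseline
score) pairs — the same task as streaming, so pretrained weights are
aligned with the streamed ones.

`rank_weights()` orders features by absolute weight, ties broken
lexicographically, for the top-k report.

## Counterfactual engine

Scenarios edit *raw* features before the frozen transform chain:
`set_value` flips a binary (eligibility: only participants currently at
the opposite value), `scale` multiplies BMI by 1.1 or 0.9 (always
applicable). Editing raw values means a BMI edit propagates through
winsorization — if the scaled value crosses the 99th-percentile bound the
delta saturates, a documented and regression-tested interaction rather
than a bug: the model never sees values outside the range it was trained
on.

`summarize_factor()` reports the eligible-subgroup mean/max/min absolute
delta per scenario. `omnibus()` changes all three factors at once in a
given direction and reports (a) the *additive* summary — the sum of the
three per-factor subgroup means, the arithmetic behind a combined
headline figure — and (b) a *per-individual* summary in which each
participant receives every edit they are eligible for (a participant
already hypertensive and diabetic receives only the BMI edit in the
adverse direction, so their combined delta can be small or zero). For a
frozen linear model the per-individual omnibus delta equals the sum of the
single-edit deltas exactly whenever no winsorization bound binds; the test
suite asserts this to 1e-10.

`variance_explained()` divides each adverse-direction subgroup mean delta
by the cohort mean treatment gain (final − baseline, sample SD with n − 1)
and reports percentages; the total is *defined* as the sum of components.
This is an accounting convention — effect sizes scaled by the average
gain — not an ANOVA-style variance decomposition, and the package keeps
the published term for it. No causal claim attaches to any of it: the
engine answers "what would the frozen model predict", not "what would
happen".

## Orchestration and reproducibility

`run_config()` validates every knob up front (unknown keys are rejected,
sections mirror `cohort_spec()`, `ground_truth()`, the preprocessor and
the model) and reads YAML; `run_pipeline()` executes simulate → fit
preprocessor → pretrain → stream → evaluate → scenarios → variance
account, failing with the stage name on error; `emit_report()` writes JSON
or a text summary. A single seed drives cohort, trajectories, pretraining
shuffles and visit order, so a config reproduces its report exactly
(provenance carries a config hash, the seed and the package version; the
timestamp is the one report field excluded from determinism checks).

## Problem sizes used in validation

The test suite validates calibration at n = 100,000 (cohort means and the
treatment-gain distribution), optimizer-vs-ridge agreement on a 50 × 10
design, noiseless parameter recovery at n = 400 (final-timepoint R² above
0.99 and correct health-factor signs), and noisy recovery at n = 1,500
(prequential final R² within ±0.05 of the generative oracle R²). These
sizes were chosen so each experiment's Monte-Carlo error is comfortably
inside the tolerance it is checked against.

## Known limitations

* The ground-truth process is first-order linear with homoscedastic noise;
  it cannot probe robustness to nonlinear recovery dynamics or
  heteroscedastic measurement error.
* Published headline results on the real cohort (R² = 0.5848, specific
  weight values, per-factor deltas such as −0.16/−0.38/−1.48) depend on
  unreleased clinical data and are reference points for the report format
  and calibration targets here, not quantities this package can reproduce.
* Single-indicator binary encoding forces symmetric flip effects (above).
* The counterfactual engine edits features independently; it does not model
  physiological coupling (e.g. a BMI reduction changing hypertension
  status).
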