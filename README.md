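# aphasiatwin

Digital-twin modelling of naming recovery in chronic post-stroke aphasia.

People with chronic aphasia improve with naming therapy, but gains vary
widely, and some of that variation may trace to modifiable health factors.
`aphasiatwin` is for researchers who want to study that question with a
*digital twin*: a per-participant predictive model of the Philadelphia
Naming Test (PNT) score that updates online as each new observation arrives
across the treatment timeline, and that supports counterfactual queries —
re-predicting a participant's final score after editing diabetes status,
hypertension status or BMI while freezing everything else.

Because participant-level clinical data of this kind cannot be shared, the
package also ships a seeded synthetic-cohort generator as a first-class,
tested component. It emulates the published marginal structure of a
106-participant chronic-aphasia treatment cohort (age 60.64 ± 10.87 y,
diabetes 24/106, hypertension 52/106, BMI 27.21 ± 4.97, baseline PNT
59.69 ± 22.85, mean treatment gain ≈ 7.92 ± 16.11 points over a
baseline / 3-week treatment / 4-week rest / 3-week treatment timeline) and
drives trajectories with a *known* linear ground truth, so the whole
pipeline is validated by parameter recovery.

## The model

Naming scores follow a regularized linear model over demographics, health
factors, per-ROI lesion load, fractional anisotropy, connectivity, and the
previous score:

    ŷ_it = b + w · x_it,   x_it = (static features_i, PNT_{i,t-1})

trained by per-observation **Adam** updates (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8, learning rate 1e-4, L2 penalty λ = 1e-3 on the weights only),
pretrained on baseline data, then streamed **prequentially**: at each
timepoint the model predicts before it updates, so every recorded
prediction is out-of-sample. Performance is R² at the final timepoint.

Counterfactual scenarios edit raw features (binary flips with
direction-specific eligibility; BMI × 1.1 / × 0.9) ahead of the frozen
preprocessing chain (mean imputation → 1st–99th percentile winsorization →
log1p of right-skewed predictors → standardization → one-hot encoding) and
re-predict with the frozen model. Each factor's adverse-direction subgroup
mean delta, divided by the cohort mean treatment gain, gives its
percentage in the variance-of-treatment-gains account; the total is the
sum of the per-factor percentages.

## Worked example

```r
library(aphasiatwin)

cfg <- run_config(list(
  seed   = 42,
  cohort = list(n_participants = 1000),
  # a faster learning rate than the 1e-4 online default, appropriate for a
  # one-shot batch analysis of a synthetic cohort
  model  = list(learning_rate = 0.01, pretrain_epochs = 300)
))
report <- run_pipeline(cfg)

report
#> <run_report> R2(final) = 0.8618; 6 scenarios; seed 42

head(report$top_weights, 5)
#>        feature     weight
#> 1     pnt_prev 20.2696345
#> 2 hypertension -0.8863930
#> 3          bmi -0.7629166
#> 4 lesion_load_STG_pole  0.6684864
#> 5     diabetes -0.6160999

report$counterfactual_summaries$diabetes_0to1$subgroup_mean_delta
#> [1] -0.616      # predicted PNT change if a non-diabetic became diabetic

report$variance_account
#> <variance_account> mean gain 8.04 points
#>   diabetes_0to1              7.66%
#>   hypertension_0to1         11.02%
#>   bmi_up10                   5.16%
#>   total                     23.85%

report$omnibus_adverse$additive    # all three factors worsened
#> [1] -1.917
report$omnibus_favorable$additive  # all three improved
#> [1] 1.927
```

Reading the output: the previous naming score dominates (its weight is on
the standardized scale, ≈ the baseline SD, i.e. carryover ≈ 1), health
factors carry the expected negative signs, and the three factors together
account for ~24% of the mean treatment gain of ~8 points. The observed
gain mean/SD (8.04 / 16.07 here) match the generator's calibration
targets. `emit_report(report, "report.json")` writes the machine-readable
version; `write_cohort()` / `read_cohort()` round-trip cohorts through
CSV, and the preprocessor and model serialize to JSON.

See the vignette (`vignettes/digital-twin-methods.Rmd`) for the generative
model, preprocessing contracts, optimizer details, counterfactual
semantics and known limitations.

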