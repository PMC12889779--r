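# A trained fixture shared across counterfactual tests: moderate training is
# enough, since the laws under test hold for any frozen linear model.
fx <- test_fixture(n = 40, seed = 33)
fit <- train_twin(fx, stages = list(c(0.05, 60)))
rows <- cf_rows_of(fx)

test_that("apply_scenario edits only the named fields", {
  s <- standard_scenarios()
  row <- rows[which(rows$diabetes == 0)[1], ]
  edited <- apply_scenario(row, s$diabetes_0to1)
  expect_equal(edited$diabetes, 1)
  expect_identical(edited[setdiff(names(edited), "diabetes")],
                   row[setdiff(names(row), "diabetes")])

  row$bmi <- 30
  expect_equal(apply_scenario(row, s$bmi_up10)$bmi, 33)

  already <- rows[which(rows$diabetes == 1)[1], ]
  expect_error(apply_scenario(already, s$diabetes_0to1), "not eligible")
  expect_error(cf_scenario("bad", list(list(feature = "bmi", kind = "scale",
                                            operand = -1))), "operand")
})

test_that("a zero-weight model yields zero deltas for any scenario", {
  null_model <- twin_model(fx$state$output_names, intercept = 50)
  for (s in standard_scenarios()) {
    elig <- which(vapply(seq_len(nrow(rows)),
                         function(i) isTRUE(s$eligibility(rows[i, ])),
                         logical(1)))[1]
    expect_equal(predict_pair(null_model, fx$state, rows[elig, ], s), 0)
  }
})

test_that("a binary flip moves the prediction by exactly the model weight", {
  s <- standard_scenarios()
  row <- rows[which(rows$diabetes == 0)[1], ]
  d <- predict_pair(fit$model, fx$state, row, s$diabetes_0to1)
  expect_equal(d, unname(fit$model$weights["diabetes"]), tolerance = 1e-12)
})

test_that("a BMI scale propagates through the frozen chain as w * 0.1 * bmi / sd", {
  s <- standard_scenarios()
  st <- fx$state
  expect_false("bmi" %in% st$log_roster)  # near-normal BMI is not rostered
  i <- which(rows$bmi * 1.1 < st$clip_high$bmi &
               rows$bmi > st$clip_low$bmi)[1]
  d <- predict_pair(fit$model, st, rows[i, ], s$bmi_up10)
  expected <- unname(fit$model$weights["bmi"]) * 0.1 * rows$bmi[i] /
    st$standardize_sd$bmi
  expect_equal(d, expected, tolerance = 1e-10)
})

test_that("binary flips are antisymmetric per individual", {
  s <- standard_scenarios()
  for (i in which(rows$hypertension == 0)[1:5]) {
    d_up <- predict_pair(fit$model, fx$state, rows[i, ], s$hypertension_0to1)
    flipped <- apply_scenario(rows[i, ], s$hypertension_0to1)
    d_down <- predict_pair(fit$model, fx$state, flipped, s$hypertension_1to0)
    expect_equal(d_down, -d_up, tolerance = 1e-10)
  }
})

test_that("subgroup summaries cover only eligible participants", {
  s <- standard_scenarios()
  out <- summarize_factor(fit$model, fx$state, rows, s$diabetes_0to1)
  expect_s3_class(out, "cf_outcome")
  expect_equal(out$subgroup_size, sum(rows$diabetes == 0))
  expect_true(all(names(out$per_participant_delta) %in%
                    rows$participant_id[rows$diabetes == 0]))
  expect_equal(out$subgroup_mean_delta, mean(out$per_participant_delta))
  expect_equal(out$max_abs_delta, max(abs(out$per_participant_delta)))

  everyone_has_it <- rows
  everyone_has_it$diabetes <- 1
  expect_error(summarize_factor(fit$model, fx$state, everyone_has_it,
                                s$diabetes_0to1), "no eligible")
})

test_that("counterfactual deltas recover the ground-truth sign pattern", {
  # noiseless cohort, well-converged model: adverse flips must predict harm
  fxn <- test_fixture(n = 200, seed = 34, clamp = FALSE,
                      truth = ground_truth(noise_sd = 0))
  fitn <- train_twin(fxn, stages = list(c(0.05, 200), c(0.005, 100)))
  rn <- cf_rows_of(fxn)
  s <- standard_scenarios()
  expect_lt(summarize_factor(fitn$model, fxn$state, rn,
                             s$diabetes_0to1)$subgroup_mean_delta, 0)
  expect_gt(summarize_factor(fitn$model, fxn$state, rn,
                             s$diabetes_1to0)$subgroup_mean_delta, 0)
  expect_lt(summarize_factor(fitn$model, fxn$state, rn,
                             s$bmi_up10)$subgroup_mean_delta, 0)
})

test_that("omnibus is additive in means and linear per individual", {
  omni <- omnibus(fit$model, fx$state, rows, "adverse")
  expect_equal(omni$additive, sum(omni$per_factor_means), tolerance = 1e-12)
  expect_equal(omnibus_additive(c(-0.16, -0.38, -1.48)), -2.02)

  # per-individual combined delta equals the sum of single-edit deltas
  s <- standard_scenarios()
  adverse <- s[c("diabetes_0to1", "hypertension_0to1", "bmi_up10")]
  for (i in seq_len(nrow(rows))[1:10]) {
    row <- rows[i, ]
    if (row$bmi * 1.1 > fx$state$clip_high$bmi) next  # clip must not bind
    singles <- 0
    for (sc in adverse) {
      if (isTRUE(sc$eligibility(row))) {
        singles <- singles + predict_pair(fit$model, fx$state, row, sc)
      }
    }
    expect_equal(omni$per_individual$delta[[row$participant_id]], singles,
                 tolerance = 1e-10)
  }
  # a participant with both conditions gets only the BMI edit
  both <- which(rows$diabetes == 1 & rows$hypertension == 1)
  if (length(both)) {
    i <- both[1]
    expect_equal(omni$per_individual$delta[[rows$participant_id[i]]],
                 predict_pair(fit$model, fx$state, rows[i, ], s$bmi_up10),
                 tolerance = 1e-12)
  }
})

test_that("counterfactuals leave model and preprocessor bit-identical", {
  model_before <- fit$model
  state_before <- fx$state
  invisible(omnibus(fit$model, fx$state, rows, "adverse"))
  invisible(summarize_factor(fit$model, fx$state, rows,
                             standard_scenarios()$bmi_down10))
  expect_identical(fit$model, model_before)
  expect_identical(fx$state, state_before)
})

test_that("a BMI edit saturates once the winsorization bound binds", {
  s <- standard_scenarios()
  row <- rows[1, ]
  row$bmi <- fx$state$clip_high$bmi + 1   # already beyond the bound
  expect_equal(predict_pair(fit$model, fx$state, row, s$bmi_up10), 0)
})

test_that("treatment gain reduces trajectories to mean and sample sd", {
  traj0 <- data.frame(participant_id = rep(c("a", "b", "c"), each = 2),
                      timepoint = rep(0:1, 3), pnt = rep(50, 6))
  expect_equal(treatment_gain(traj0)[c("mean_gain", "sd_gain")],
               list(mean_gain = 0, sd_gain = 0))
  traj <- data.frame(participant_id = rep(c("a", "b"), each = 2),
                     timepoint = rep(0:1, 2),
                     pnt = c(10, 14, 20, 32))   # gains 4 and 12
  tg <- treatment_gain(traj)
  expect_equal(tg$mean_gain, 8)
  expect_equal(tg$sd_gain, sqrt(32))   # 5.657 by hand
  expect_error(treatment_gain(traj[c(1, 3), ]), ">= 2 timepoints")
})

test_that("variance accounting scales deltas by the mean gain", {
  va <- variance_explained(c(diabetes = 0.16), mean_gain = 7.92)
  expect_equal(round(unname(va$per_factor_percent)), 2)
  va3 <- variance_explained(c(d = 0.1584, h = 0.3762, b = 1.4652),
                            mean_gain = 7.92)
  expect_equal(unname(va3$per_factor_percent), c(2, 4.75, 18.5),
               tolerance = 1e-9)
  expect_equal(va3$total_percent, sum(va3$per_factor_percent))
  expect_equal(unname(variance_explained(c(x = 0), 7.92)$per_factor_percent),
               0)
  expect_error(variance_explained(c(x = 1), 0), "mean gain is zero")
})
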