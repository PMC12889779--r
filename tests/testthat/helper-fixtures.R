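# Shared fixtures: everything is generated in code at test time.

# Small, fully observed cohort spec for fast tests.
test_spec <- function(n = 30, seed = 101, ...) {
  cohort_spec(n_participants = n, seed = seed, missing_rate = 0, ...)
}

# Cohort + trajectories + fitted preprocessor + baseline design matrix.
test_fixture <- function(n = 30, seed = 101, truth = ground_truth(),
                         clamp = TRUE, spec = test_spec(n, seed)) {
  cohort <- generate_cohort(spec)
  trajectories <- generate_trajectories(cohort, truth, spec, clamp = clamp)
  pnt <- matrix(trajectories$pnt, nrow = spec$n_participants, byrow = TRUE)
  baseline <- cohort
  baseline$pnt_prev <- pnt[, 1]
  state <- fit_preprocessor(baseline, feature_schema(cohort))
  list(spec = spec, cohort = cohort, trajectories = trajectories,
       pnt = pnt, baseline = baseline, state = state,
       X0 = transform_cohort(baseline, state))
}

# Pretrain with a staged learning-rate schedule (high rate to travel, low
# rate to settle), then stream. Built entirely from exported functions.
train_twin <- function(fx, stages = list(c(0.05, 300), c(0.005, 200)),
                       l2_lambda = 1e-3, stream_lr = NULL, seed = 1) {
  model <- twin_model(fx$state$output_names, learning_rate = stages[[1]][1],
                      l2_lambda = l2_lambda, intercept = mean(fx$pnt[, 2]))
  for (s in stages) {
    model$adam$learning_rate <- s[1]
    model <- pretrain(model, fx$X0, fx$pnt[, 2], n_epochs = s[2], seed = seed)
  }
  if (!is.null(stream_lr)) model$adam$learning_rate <- stream_lr
  out <- stream_update(model, fx$cohort, fx$trajectories, fx$state,
                       seed = seed)
  c(out, list(state = fx$state))
}

# Raw rows at the final-prediction context (pnt_prev = last pre-final score).
cf_rows_of <- function(fx) {
  rows <- fx$cohort
  rows$pnt_prev <- fx$pnt[, ncol(fx$pnt) - 1L]
  rows
}
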