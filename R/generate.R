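#' Generate a synthetic cohort of participant records
#'
#' Draws one row per participant: demographics, vascular health factors,
#' per-ROI lesion-load proportions (left hemisphere), per-ROI fractional
#' anisotropy (both hemispheres, with left-hemisphere values reduced in
#' proportion to that ROI's lesion load) and per-ROI connectivity z-values.
#' Sampling is fully determined by `spec$seed`: the same spec produces an
#' identical cohort on every run.
#'
#' Diabetes, hypertension and BMI are coupled through a shared latent
#' vascular factor (Gaussian copula): each marginal stays at its target
#' prevalence or mean while the three are positively correlated. A
#' `missing_rate` fraction of continuous cells is masked (`NA`) at random;
#' binary and categorical fields are always complete.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` with one participant per row. Columns:
#'   `participant_id`, `age`, `sex` (`"F"`/`"M"`), `education`,
#'   `days_poststroke`, `diabetes`, `hypertension`, `bmi`, then
#'   `lesion_load_<roi>`, `fa_left_<roi>`, `fa_right_<roi>`,
#'   `conn_left_<roi>`, `conn_right_<roi>` for each ROI in `spec$roi_names`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_participants
  set.seed(spec$seed)

  # Shared latent vascular factor couples diabetes, hypertension and BMI.
  lam <- spec$latent_loading
  z_vasc <- stats::rnorm(n)
  mix <- function() lam * z_vasc + sqrt(1 - lam^2) * stats::rnorm(n)
  diabetes <- as.integer(mix() > stats::qnorm(1 - spec$prop_diabetes))
  hypertension <- as.integer(mix() > stats::qnorm(1 - spec$prop_hypertension))
  bmi <- rtruncnorm_calibrated(n, spec$bmi_mean, spec$bmi_sd, 15, 55,
                               p = stats::pnorm(mix()))

  age <- rtruncnorm_calibrated(n, spec$age_mean, spec$age_sd, 21, 80)
  sex <- ifelse(stats::runif(n) < spec$prop_female, "F", "M")
  education <- rtruncnorm_calibrated(n, spec$education_mean,
                                     spec$education_sd, 8, 25)

  # Chronicity: >= 365 days, right-skewed (shifted lognormal with the
  # target mean and sd of the shifted part).
  shift <- 365
  m <- spec$days_poststroke_mean - shift
  check_that(m > 0, "days_poststroke_mean", "must exceed 365 days")
  cv <- spec$days_poststroke_sd / m
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  days_poststroke <- shift + stats::rlnorm(n, meanlog, sdlog)

  cohort <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = age, sex = sex, education = education,
    days_poststroke = days_poststroke,
    diabetes = diabetes, hypertension = hypertension, bmi = bmi,
    stringsAsFactors = FALSE
  )

  rois <- spec$roi_names
  for (r in rois) {
    cohort[[paste0("lesion_load_", r)]] <-
      stats::rbeta(n, spec$lesion_shape1, spec$lesion_shape2)
  }
  fa_lo <- spec$fa_range[1]
  fa_span <- spec$fa_range[2] - spec$fa_range[1]
  for (r in rois) {
    base_l <- fa_lo + fa_span * stats::rbeta(n, spec$fa_shape1, spec$fa_shape2)
    base_r <- fa_lo + fa_span * stats::rbeta(n, spec$fa_shape1, spec$fa_shape2)
    cohort[[paste0("fa_left_", r)]] <-
      base_l * (1 - spec$fa_lesion_coupling * cohort[[paste0("lesion_load_", r)]])
    cohort[[paste0("fa_right_", r)]] <- base_r
  }
  for (r in rois) {
    cohort[[paste0("conn_left_", r)]] <- stats::rnorm(n)
    cohort[[paste0("conn_right_", r)]] <- stats::rnorm(n)
  }

  if (spec$missing_rate > 0) {
    for (col in continuous_feature_columns(cohort)) {
      mask <- stats::runif(n) < spec$missing_rate
      cohort[[col]][mask] <- NA_real_
    }
  }
  cohort
}

# Continuous participant-level feature columns (missingness-eligible).
continuous_feature_columns <- function(cohort) {
  setdiff(names(cohort)[vapply(cohort, is.double, logical(1))],
          c("diabetes", "hypertension"))
}

#' Generate naming-score trajectories from a ground-truth process
#'
#' Draws a baseline Philadelphia Naming Test score per participant at the
#' spec's baseline mean/SD (truncated to `[0, 100]`), then rolls the
#' [ground_truth()] recurrence forward for `spec$n_timepoints - 1` steps.
#' Masked (`NA`) feature cells enter the recurrence at the cohort mean of the
#' observed values for that feature — the latent process acts as if at the
#' population centre, which mirrors the downstream mean imputation.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param truth a [ground_truth()]; every weight name must be a numeric
#'   cohort column.
#' @param spec the [cohort_spec()] used for the cohort.
#' @param clamp clamp scores into `[0, 100]` after each step (default). Set
#'   `FALSE` for parameter-recovery experiments where trajectories must stay
#'   an exact linear function of features.
#' @param seed RNG seed for baseline draws and step noise; defaults to
#'   `spec$seed + 1` so cohort and trajectory streams are distinct but both
#'   reproducible from the spec.
#' @return long `data.frame` with columns `participant_id`, `timepoint`
#'   (0-based; 0 = baseline) and `pnt`.
#' @export
generate_trajectories <- function(cohort, truth, spec, clamp = TRUE,
                                  seed = spec$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  unknown <- setdiff(names(truth$weights), names(cohort))
  if (length(unknown)) {
    stop("ground truth references unknown feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  T_ <- spec$n_timepoints
  set.seed(seed)

  X <- as.matrix(cohort[names(truth$weights)])
  for (j in seq_len(ncol(X))) {   # latent completion of masked cells
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[!nas, j])
  }
  signal <- drop(X %*% truth$weights)

  pnt <- matrix(NA_real_, n, T_)
  pnt[, 1] <- rtruncnorm_calibrated(n, spec$pnt_baseline_mean,
                                    spec$pnt_baseline_sd, 0, 100)
  for (t in 2:T_) {
    step <- truth$carryover_weight * pnt[, t - 1] + truth$intercept +
      truth$gain_intercept + signal +
      stats::rnorm(n, 0, truth$noise_sd)
    pnt[, t] <- if (clamp) clamp(step, 0, 100) else step
  }

  data.frame(
    participant_id = rep(cohort$participant_id, each = T_),
    timepoint = rep.int(seq_len(T_) - 1L, n),
    pnt = as.vector(t(pnt)),
    stringsAsFactors = FALSE
  )
}
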