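#' Define a counterfactual scenario
#'
#' A scenario is a list of edits applied to raw feature rows before the
#' frozen preprocessing chain: `set_value` replaces a field, `scale`
#' multiplies it (e.g. BMI x 1.1). Eligibility selects the applicable
#' subgroup: by default a `set_value` edit on a binary excludes participants
#' already at the target value (a 0-to-1 flip applies only to current 0s),
#' while `scale` edits apply to everyone.
#'
#' @param name scenario identifier.
#' @param edits list of edits, each `list(feature =, kind = "set_value" or
#'   "scale", operand =)`. Scale operands must be positive.
#' @param eligibility optional predicate `function(row)` returning `TRUE`
#'   for eligible raw rows; default derives from the edits as above.
#' @return an object of class `cf_scenario`.
#' @export
cf_scenario <- function(name, edits, eligibility = NULL) {
  stopifnot(is.character(name), length(name) == 1L, length(edits) >= 1L)
  for (e in edits) {
    stopifnot(all(c("feature", "kind", "operand") %in% names(e)))
    if (!e$kind %in% c("set_value", "scale")) {
      stop("unknown edit kind: ", e$kind, call. = FALSE)
    }
    if (e$kind == "scale" && e$operand <= 0) {
      stop("scale operand must be > 0 for `", e$feature, "`", call. = FALSE)
    }
  }
  if (is.null(eligibility)) {
    eligibility <- function(row) {
      for (e in edits) {
        if (e$kind == "set_value" && row[[e$feature]] == e$operand) {
          return(FALSE)
        }
      }
      TRUE
    }
  }
  structure(list(name = name, edits = edits, eligibility = eligibility),
            class = "cf_scenario")
}

#' The study's standard health-factor scenarios
#'
#' Diabetes and hypertension flips in both directions plus BMI scaled by
#' +/-10%. Adverse scenarios (flip to 1, BMI up) carry `direction =
#' "adverse"`, the reverse `"favorable"`.
#'
#' @return named list of [cf_scenario()] objects with a `direction`
#'   attribute each.
#' @export
standard_scenarios <- function() {
  mk <- function(name, feature, kind, operand, direction) {
    s <- cf_scenario(name, list(list(feature = feature, kind = kind,
                                     operand = operand)))
    attr(s, "direction") <- direction
    s
  }
  list(
    diabetes_0to1 = mk("diabetes_0to1", "diabetes", "set_value", 1, "adverse"),
    diabetes_1to0 = mk("diabetes_1to0", "diabetes", "set_value", 0, "favorable"),
    hypertension_0to1 = mk("hypertension_0to1", "hypertension", "set_value", 1,
                           "adverse"),
    hypertension_1to0 = mk("hypertension_1to0", "hypertension", "set_value", 0,
                           "favorable"),
    bmi_up10 = mk("bmi_up10", "bmi", "scale", 1.1, "adverse"),
    bmi_down10 = mk("bmi_down10", "bmi", "scale", 0.9, "favorable")
  )
}

#' Apply a scenario's edits to one raw row
#'
#' Only the edited fields change; everything else is returned untouched.
#'
#' @param row single raw row (1-row data.frame or named list).
#' @param scenario a [cf_scenario()].
#' @return the edited row.
#' @export
apply_scenario <- function(row, scenario) {
  stopifnot(inherits(scenario, "cf_scenario"))
  if (!isTRUE(scenario$eligibility(row))) {
    stop("row not eligible for scenario `", scenario$name, "`",
         call. = FALSE)
  }
  for (e in scenario$edits) {
    if (!e$feature %in% names(row)) {
      stop("scenario edits unknown feature `", e$feature, "`", call. = FALSE)
    }
    row[[e$feature]] <- switch(e$kind,
                               set_value = e$operand,
                               scale = row[[e$feature]] * e$operand)
  }
  row
}

#' Predicted-score delta for one participant under a scenario
#'
#' Both the original and the edited raw row pass through the *frozen*
#' preprocessing chain and the *frozen* model (no refit, no Adam step);
#' the delta is counterfactual minus original prediction.
#'
#' @param model frozen [twin_model()].
#' @param state frozen [fit_preprocessor()] state.
#' @param row raw row including the previous-score feature set to the
#'   prediction context (for final-score counterfactuals, the last observed
#'   pre-final score).
#' @param scenario a [cf_scenario()].
#' @return delta in PNT points.
#' @export
predict_pair <- function(model, state, row, scenario) {
  edited <- apply_scenario(row, scenario)
  predict(model, transform_record(edited, state)) -
    predict(model, transform_record(row, state))
}

#' Summarize a scenario over its eligible subgroup
#'
#' @param model,state frozen model and preprocessor.
#' @param rows raw rows for the whole cohort (including the previous-score
#'   feature).
#' @param scenario a [cf_scenario()].
#' @return object of class `cf_outcome`: scenario name, per-participant
#'   deltas (named), subgroup mean delta, subgroup size, max/min absolute
#'   delta.
#' @export
summarize_factor <- function(model, state, rows, scenario) {
  elig <- vapply(seq_len(nrow(rows)),
                 function(i) isTRUE(scenario$eligibility(rows[i, ])),
                 logical(1))
  if (!any(elig)) {
    stop("no eligible participants for scenario `", scenario$name, "`",
         call. = FALSE)
  }
  idx <- which(elig)
  deltas <- vapply(idx, function(i) {
    predict_pair(model, state, rows[i, ], scenario)
  }, numeric(1))
  names(deltas) <- rows$participant_id[idx]
  structure(list(
    scenario_name = scenario$name,
    per_participant_delta = deltas,
    subgroup_mean_delta = mean(deltas),
    subgroup_size = length(deltas),
    max_abs_delta = max(abs(deltas)),
    min_abs_delta = min(abs(deltas))
  ), class = "cf_outcome")
}

#' @export
print.cf_outcome <- function(x, ...) {
  cat(sprintf("<cf_outcome> %s: n=%d, mean delta %+0.3f (|max| %0.3f)\n",
              x$scenario_name, x$subgroup_size, x$subgroup_mean_delta,
              x$max_abs_delta))
  invisible(x)
}

#' Additive omnibus summary from per-factor outcomes
#'
#' The sum of the per-factor subgroup mean deltas — the arithmetic behind a
#' combined "all three risk factors change" headline figure.
#'
#' @param per_factor_means numeric vector of subgroup mean deltas.
#' @return their sum (PNT points).
#' @export
omnibus_additive <- function(per_factor_means) {
  sum(per_factor_means)
}

#' Omnibus counterfactual: change all three health factors at once
#'
#' Two summaries are produced. The *additive* summary sums the three
#' per-factor subgroup mean deltas for the requested direction. The
#' *per-individual* summary applies, to each participant, every edit for
#' which they are eligible — binaries flip only when currently at the
#' opposite value, BMI is always scaled — and reports the distribution of
#' the combined deltas (participants with no applicable binary flip still
#' receive the BMI edit).
#'
#' @param model,state frozen model and preprocessor.
#' @param rows raw cohort rows (including the previous-score feature).
#' @param direction `"adverse"` (diabetes/hypertension to 1, BMI +10%) or
#'   `"favorable"` (to 0, BMI -10%).
#' @return list with `direction`, `additive` (sum of per-factor means),
#'   `per_factor_means`, and `per_individual` (named deltas plus mean,
#'   max_abs, min_abs).
#' @export
omnibus <- function(model, state, rows, direction = c("adverse", "favorable")) {
  direction <- match.arg(direction)
  scen <- standard_scenarios()
  scen <- scen[vapply(scen, function(s) attr(s, "direction") == direction,
                      logical(1))]
  per_factor <- vapply(scen, function(s) {
    summarize_factor(model, state, rows, s)$subgroup_mean_delta
  }, numeric(1))

  n <- nrow(rows)
  deltas <- numeric(n)
  for (i in seq_len(n)) {
    row <- rows[i, ]
    d <- 0
    for (s in scen) {
      if (isTRUE(s$eligibility(row))) {
        d <- d + predict_pair(model, state, row, s)
      }
    }
    deltas[i] <- d
  }
  names(deltas) <- rows$participant_id
  list(direction = direction,
       additive = omnibus_additive(per_factor),
       per_factor_means = per_factor,
       per_individual = list(delta = deltas, mean = mean(deltas),
                             max_abs = max(abs(deltas)),
                             min_abs = min(abs(deltas))))
}

#' Observed treatment gain of a cohort
#'
#' Per-participant gain is the final minus the baseline naming score;
#' returns the cohort mean and sample SD (n - 1 denominator).
#'
#' @param trajectories long trajectory table.
#' @return `list(mean_gain, sd_gain, gains)` with `gains` named by
#'   participant.
#' @export
treatment_gain <- function(trajectories) {
  sp <- split(trajectories, trajectories$participant_id)
  gains <- vapply(sp, function(d) {
    if (nrow(d) < 2L) stop("every trajectory needs >= 2 timepoints",
                           call. = FALSE)
    d <- d[order(d$timepoint), ]
    d$pnt[nrow(d)] - d$pnt[1]
  }, numeric(1))
  list(mean_gain = mean(gains),
       sd_gain = stats::sd(gains),
       gains = gains)
}

#' Variance-of-treatment-gain accounting
#'
#' Expresses each factor's adverse-direction subgroup mean delta as a
#' percentage of the cohort mean treatment gain; the total is defined as
#' the sum of the per-factor percentages.
#'
#' @param adverse_deltas named numeric vector of adverse-direction subgroup
#'   mean deltas (PNT points); signs are ignored.
#' @param mean_gain cohort mean treatment gain (must be nonzero).
#' @param sd_gain optional cohort gain SD, carried into the account.
#' @return object of class `variance_account` with `per_factor_percent`,
#'   `total_percent`, `mean_gain`, `sd_gain`.
#' @export
variance_explained <- function(adverse_deltas, mean_gain, sd_gain = NA_real_) {
  if (mean_gain == 0) {
    stop("variance account undefined: mean gain is zero", call. = FALSE)
  }
  pct <- 100 * abs(adverse_deltas) / abs(mean_gain)
  structure(list(per_factor_percent = pct,
                 total_percent = sum(pct),
                 mean_gain = mean_gain, sd_gain = sd_gain),
            class = "variance_account")
}

#' @export
print.variance_account <- function(x, ...) {
  cat("<variance_account> mean gain", round(x$mean_gain, 2), "points\n")
  for (f in names(x$per_factor_percent)) {
    cat(sprintf("  %-24s %6.2f%%\n", f, x$per_factor_percent[[f]]))
  }
  cat(sprintf("  %-24s %6.2f%%\n", "total", x$total_percent))
  invisible(x)
}
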