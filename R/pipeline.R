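#' Build and validate a full run configuration
#'
#' Collects every knob of the end-to-end analysis — cohort spec, ground
#' truth, preprocessing, model, scenarios, seed — applying defaults for
#' anything unspecified. Unknown keys are rejected before any computation.
#'
#' @param config named list of overrides; sections `cohort` (see
#'   [cohort_spec()]), `truth` (see [ground_truth()]), `preprocessing`
#'   (`skew_threshold`, `clip_probs`), `model` (`learning_rate`,
#'   `l2_lambda`, `beta1`, `beta2`, `epsilon`, `pretrain_epochs`),
#'   `scenarios` (`"standard"`, `"none"`, or a list of scenario
#'   definitions), `paths` (`input_dir` to read CSVs instead of
#'   simulating), and `seed`.
#' @param path optional YAML file; its contents are used as `config`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list(), path = NULL) {
  if (!is.null(path)) config <- yaml::read_yaml(path)
  config <- config %||% list()
  allowed <- c("cohort", "truth", "preprocessing", "model", "scenarios",
               "paths", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_section <- function(section, allowed_keys) {
    bad <- setdiff(names(config[[section]]), allowed_keys)
    if (length(bad)) {
      stop("unknown `", section, "` key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_section("cohort", names(formals(cohort_spec)))
  check_section("truth", names(formals(ground_truth)))
  check_section("preprocessing", c("skew_threshold", "clip_probs"))
  check_section("model", c("learning_rate", "l2_lambda", "beta1", "beta2",
                           "epsilon", "pretrain_epochs"))
  check_section("paths", c("input_dir", "out_dir"))

  seed <- as.integer(config$seed %||% 1L)
  cohort_args <- config$cohort %||% list()
  if (is.null(cohort_args$seed)) cohort_args$seed <- seed
  truth_args <- config$truth %||% list()
  if (!is.null(truth_args$weights)) {
    truth_args$weights <- unlist(truth_args$weights)
  }

  cfg <- list(
    seed = seed,
    cohort = do.call(cohort_spec, cohort_args),
    truth = do.call(ground_truth, truth_args),
    preprocessing = list(
      skew_threshold = config$preprocessing$skew_threshold %||% 1.0,
      clip_probs = config$preprocessing$clip_probs %||% c(0.01, 0.99)
    ),
    model = list(
      learning_rate = config$model$learning_rate %||% 1e-4,
      l2_lambda = config$model$l2_lambda %||% 1e-3,
      beta1 = config$model$beta1 %||% 0.9,
      beta2 = config$model$beta2 %||% 0.999,
      epsilon = config$model$epsilon %||% 1e-8,
      pretrain_epochs = config$model$pretrain_epochs %||% 100L
    ),
    scenarios = parse_scenarios(config$scenarios),
    paths = config$paths %||% list()
  )
  class(cfg) <- "run_config"
  cfg
}

parse_scenarios <- function(x) {
  if (is.null(x) || identical(x, "standard")) return(standard_scenarios())
  if (identical(x, "none")) return(list())
  scen <- lapply(x, function(s) {
    cf_scenario(s$name, lapply(s$edits, function(e) {
      list(feature = e$feature, kind = e$kind, operand = e$operand)
    }))
  })
  stats::setNames(scen, vapply(scen, `[[`, character(1), "name"))
}

#' Run the full digital-twin analysis
#'
#' Executes, in order: cohort simulation (or CSV input), trajectory
#' generation, preprocessor fitting on baseline rows, pretraining on
#' (baseline features -> first post-baseline score) pairs, prequential
#' streaming over the remaining timepoints, final-timepoint R-squared,
#' weight ranking, the configured counterfactual scenarios with omnibus
#' summaries in both directions, and variance-of-treatment-gain
#' accounting.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: `r2_final`, `top_weights`,
#'   `counterfactual_summaries`, `omnibus_adverse`/`omnibus_favorable`,
#'   `variance_account`, `gain`, `model`, `state`, `predictions`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  tryCatch({
    if (!is.null(config$paths$input_dir)) {
      dat <- read_cohort(config$paths$input_dir)
      cohort <- dat$cohort
      trajectories <- dat$trajectories
    } else {
      cohort <- generate_cohort(config$cohort)
      trajectories <- generate_trajectories(cohort, config$truth,
                                            config$cohort)
    }
    pnt <- trajectories_matrix(cohort, trajectories)

    stage <- "fit_preprocessor"
    schema <- feature_schema(cohort)
    baseline_rows <- cohort
    baseline_rows$pnt_prev <- pnt[, 1]
    state <- fit_preprocessor(baseline_rows, schema,
                              skew_threshold = config$preprocessing$skew_threshold,
                              clip_probs = config$preprocessing$clip_probs)

    stage <- "pretrain"
    model <- twin_model(state$output_names,
                        learning_rate = config$model$learning_rate,
                        beta1 = config$model$beta1,
                        beta2 = config$model$beta2,
                        epsilon = config$model$epsilon,
                        l2_lambda = config$model$l2_lambda,
                        intercept = mean(pnt[, 2]))
    X0 <- transform_cohort(baseline_rows, state)
    model <- pretrain(model, X0, pnt[, 2],
                      n_epochs = config$model$pretrain_epochs,
                      seed = config$seed)

    stage <- "stream_update"
    streamed <- stream_update(model, cohort, trajectories, state,
                              seed = config$seed)
    model <- streamed$model

    stage <- "evaluate"
    r2 <- evaluate_r2(streamed$predictions, final_timepoint_only = TRUE)
    top <- rank_weights(model, top_k = 10L)

    stage <- "counterfactual"
    T_ <- ncol(pnt)
    cf_rows <- cohort
    cf_rows$pnt_prev <- pnt[, T_ - 1L]
    summaries <- lapply(config$scenarios, function(s) {
      summarize_factor(model, state, cf_rows, s)
    })
    omni_adv <- omni_fav <- NULL
    account <- NULL
    gain <- treatment_gain(trajectories)
    if (length(config$scenarios)) {
      omni_adv <- omnibus(model, state, cf_rows, "adverse")
      omni_fav <- omnibus(model, state, cf_rows, "favorable")
      account <- variance_explained(omni_adv$per_factor_means,
                                    gain$mean_gain, gain$sd_gain)
    }

    structure(list(
      r2_final = r2, top_weights = top,
      counterfactual_summaries = summaries,
      omnibus_adverse = omni_adv, omnibus_favorable = omni_fav,
      variance_account = account, gain = gain[c("mean_gain", "sd_gain")],
      model = model, state = state, predictions = streamed$predictions,
      provenance = list(
        config_hash = rlang::hash(config_fingerprint(config)),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("aphasiatwin")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ), class = "run_report")
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Hashable view of a config (drops closures, which hash unstably).
config_fingerprint <- function(config) {
  list(seed = config$seed, cohort = unclass(config$cohort),
       truth = unclass(config$truth),
       preprocessing = config$preprocessing, model = config$model,
       scenarios = lapply(config$scenarios, function(s) {
         list(name = s$name, edits = s$edits)
       }),
       paths = config$paths)
}

#' Emit a run report to disk
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output file.
#' @param format `"json"` (machine-readable; excludes the fitted model and
#'   preprocessor objects, which have their own serializers) or `"text"`
#'   (human-readable summary: R-squared, top-10 weights with signs,
#'   per-scenario mean deltas, variance account).
#' @return invisibly, `path`.
#' @export
emit_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "run_report"))
  if (format == "json") {
    x <- list(
      r2_final = report$r2_final,
      top_weights = report$top_weights,
      counterfactual = lapply(report$counterfactual_summaries, function(s) {
        list(scenario = s$scenario_name,
             subgroup_mean_delta = s$subgroup_mean_delta,
             subgroup_size = s$subgroup_size,
             max_abs_delta = s$max_abs_delta,
             min_abs_delta = s$min_abs_delta)
      }),
      omnibus = list(
        adverse_additive = report$omnibus_adverse$additive %||% NULL,
        favorable_additive = report$omnibus_favorable$additive %||% NULL
      ),
      variance_account = if (!is.null(report$variance_account)) list(
        per_factor_percent = as.list(report$variance_account$per_factor_percent),
        total_percent = report$variance_account$total_percent,
        mean_gain = report$variance_account$mean_gain,
        sd_gain = report$variance_account$sd_gain
      ),
      gain = report$gain,
      provenance = report$provenance
    )
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) cat(..., "\n", sep = "", file = con)
    w(sprintf("Final-timepoint R2: %.4f", report$r2_final))
    w("")
    w("Top-weighted predictors:")
    for (i in seq_len(nrow(report$top_weights))) {
      w(sprintf("  %2d. %-28s %+0.4f", i, report$top_weights$feature[i],
                report$top_weights$weight[i]))
    }
    if (length(report$counterfactual_summaries)) {
      w("")
      w("Counterfactual scenarios (subgroup mean delta, PNT points):")
      for (s in report$counterfactual_summaries) {
        w(sprintf("  %-20s %+0.3f  (n = %d)", s$scenario_name,
                  s$subgroup_mean_delta, s$subgroup_size))
      }
      w("")
      w(sprintf("Omnibus additive: adverse %+0.3f, favorable %+0.3f",
                report$omnibus_adverse$additive,
                report$omnibus_favorable$additive))
      w("")
      va <- report$variance_account
      w(sprintf("Treatment gain: mean %.2f (SD %.2f) points",
                va$mean_gain, va$sd_gain))
      w("Variance in treatment gains attributed to health factors:")
      for (f in names(va$per_factor_percent)) {
        w(sprintf("  %-20s %6.2f%%", f, va$per_factor_percent[[f]]))
      }
      w(sprintf("  %-20s %6.2f%%", "total", va$total_percent))
    }
  }
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> R2(final) = %.4f; %d scenarios; seed %d\n",
              x$r2_final, length(x$counterfactual_summaries),
              x$provenance$seed))
  invisible(x)
}
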