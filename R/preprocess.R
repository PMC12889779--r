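#' Declare the feature schema for modelling
#'
#' Maps every model input to a kind: `continuous` features pass through the
#' impute / winsorize / log1p / standardize chain, `binary` features pass
#' through untouched as 0/1 indicators, `categorical` features are one-hot
#' encoded with the first (alphabetical) level dropped. The previous naming
#' score enters the model as an ordinary continuous feature named by
#' `prev_feature`.
#'
#' @param cohort a participant table; used only for its column names.
#' @param prev_feature name of the lagged-outcome feature (default
#'   `"pnt_prev"`).
#' @return an object of class `feature_schema` with elements
#'   `feature_names` (ordered), `kinds` (named character) and `outcome_name`.
#' @export
feature_schema <- function(cohort, prev_feature = "pnt_prev") {
  feats <- setdiff(names(cohort), "participant_id")
  kinds <- stats::setNames(rep("continuous", length(feats)), feats)
  kinds[names(kinds) == "sex"] <- "categorical"
  kinds[names(kinds) %in% c("diabetes", "hypertension")] <- "binary"
  if (!prev_feature %in% feats) feats <- c(feats, prev_feature)
  kinds[prev_feature] <- "continuous"
  if (anyDuplicated(feats)) {
    stop("duplicate feature names in schema", call. = FALSE)
  }
  structure(list(feature_names = feats, kinds = kinds,
                 outcome_name = "pnt", prev_feature = prev_feature),
            class = "feature_schema")
}

## ---- elementary stages ----------------------------------------------------

#' Elementary preprocessing stages
#'
#' The fitted pipeline is the composition impute -> winsorize -> log1p (for
#' rostered skewed features) -> standardize, applied with parameters frozen
#' at fit time. Each stage is exposed on its own; all are pure.
#'
#' @param x numeric vector.
#' @param center imputation or centering value.
#' @param low,high winsorization bounds (`low <= high`).
#' @param feature feature name to look up in `roster`.
#' @param roster character vector of features receiving `log1p`.
#' @param scale positive standard deviation used for scaling.
#' @return transformed numeric vector of the same length.
#' @name preprocessing-stages
NULL

#' @rdname preprocessing-stages
#' @export
impute <- function(x, center) {
  x[is.na(x)] <- center
  x
}

#' @rdname preprocessing-stages
#' @export
winsorize <- function(x, low, high) {
  stopifnot(low <= high)
  pmin(pmax(x, low), high)
}

#' @rdname preprocessing-stages
#' @export
log1p_selected <- function(x, feature, roster) {
  if (feature %in% roster) log1p(x) else x
}

#' @rdname preprocessing-stages
#' @export
standardize <- function(x, center, scale) {
  stopifnot(scale > 0)
  (x - center) / scale
}

## ---- fitting --------------------------------------------------------------

#' Fit the preprocessing pipeline on a set of raw rows
#'
#' Computes, per continuous feature, the imputation mean (over observed
#' values), 1st/99th-percentile winsorization bounds (linear-interpolation
#' quantiles), log1p membership and post-chain standardization parameters.
#' A continuous feature joins the log roster iff its adjusted Fisher-Pearson
#' skewness on observed values exceeds `skew_threshold` and its minimum is
#' non-negative. Standardization mean/SD are computed after imputation,
#' winsorization and any log transform, in that order, so that transformed
#' fit rows have mean 0 and (sample) SD 1. Zero-variance features are dropped
#' with a warning. The fitted state is frozen: transforming new rows (or
#' counterfactual edits of them) never refits anything.
#'
#' @param fit_rows data.frame of raw feature rows (the pretraining/baseline
#'   set), containing every schema feature as a column.
#' @param schema a [feature_schema()].
#' @param skew_threshold skewness above which a non-negative continuous
#'   feature is log1p-transformed (default 1.0).
#' @param clip_probs two probabilities for the winsorization quantiles
#'   (default `c(0.01, 0.99)`).
#' @return an object of class `preprocessor_state`.
#' @export
fit_preprocessor <- function(fit_rows, schema, skew_threshold = 1.0,
                             clip_probs = c(0.01, 0.99)) {
  stopifnot(inherits(schema, "feature_schema"))
  if (nrow(fit_rows) < 2L) stop("need at least 2 fit rows", call. = FALSE)
  missing_cols <- setdiff(schema$feature_names, names(fit_rows))
  if (length(missing_cols)) {
    stop("fit rows lack feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  cont <- schema$feature_names[schema$kinds[schema$feature_names] == "continuous"]
  bin <- schema$feature_names[schema$kinds[schema$feature_names] == "binary"]
  cat_ <- schema$feature_names[schema$kinds[schema$feature_names] == "categorical"]

  impute_mean <- clip_low <- clip_high <- std_mean <- std_sd <-
    stats::setNames(numeric(length(cont)), cont)
  skewness <- stats::setNames(numeric(length(cont)), cont)
  log_roster <- character(0)
  dropped <- character(0)

  for (f in cont) {
    obs <- fit_rows[[f]][!is.na(fit_rows[[f]])]
    if (length(obs) == 0L) {
      stop("feature `", f, "` has no observed values", call. = FALSE)
    }
    if (length(obs) < 2L) {
      stop("feature `", f, "` has fewer than 2 observed values",
           call. = FALSE)
    }
    impute_mean[f] <- mean(obs)
    q <- stats::quantile(obs, clip_probs, type = 7, names = FALSE)
    clip_low[f] <- q[1]
    clip_high[f] <- q[2]
    sk <- sample_skewness(obs)
    skewness[f] <- if (is.na(sk)) 0 else sk
    if (!is.na(sk) && sk > skew_threshold && min(obs) >= 0) {
      log_roster <- c(log_roster, f)
    }
  }
  for (f in cont) {
    v <- impute(fit_rows[[f]], impute_mean[f])
    v <- winsorize(v, clip_low[f], clip_high[f])
    v <- log1p_selected(v, f, log_roster)
    std_mean[f] <- mean(v)
    std_sd[f] <- stats::sd(v)
    if (std_sd[f] == 0) dropped <- c(dropped, f)
  }
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    cont <- setdiff(cont, dropped)
  }

  for (b in bin) {
    v <- fit_rows[[b]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      stop("binary feature `", b, "` must be complete 0/1", call. = FALSE)
    }
  }

  encoding_map <- list()
  for (f in cat_) {
    v <- fit_rows[[f]]
    if (anyNA(v)) stop("categorical feature `", f, "` has missing values",
                       call. = FALSE)
    lev <- sort(unique(as.character(v)))
    encoding_map[[f]] <- list(
      levels = lev,
      baseline = lev[1],
      columns = if (length(lev) > 1L) paste(f, lev[-1], sep = "_")
                else character(0)
    )
  }

  output_names <- character(0)
  for (f in schema$feature_names) {
    if (f %in% dropped) next
    output_names <- c(output_names, switch(
      schema$kinds[[f]],
      continuous = f,
      binary = f,
      categorical = encoding_map[[f]]$columns
    ))
  }

  structure(list(
    schema = schema, continuous = cont, binary = bin, categorical = cat_,
    impute_mean = as.list(impute_mean[cont]),
    clip_low = as.list(clip_low[cont]), clip_high = as.list(clip_high[cont]),
    log_roster = log_roster, skewness = as.list(skewness),
    standardize_mean = as.list(std_mean[cont]),
    standardize_sd = as.list(std_sd[cont]),
    encoding_map = encoding_map, dropped = dropped,
    output_names = output_names,
    skew_threshold = skew_threshold, clip_probs = clip_probs
  ), class = "preprocessor_state")
}

#' @export
print.preprocessor_state <- function(x, ...) {
  cat("<preprocessor_state>", length(x$continuous), "continuous,",
      length(x$binary), "binary,", length(x$categorical),
      "categorical features;", length(x$log_roster), "log1p-rostered;",
      length(x$dropped), "dropped\n")
  invisible(x)
}

## ---- transforming ---------------------------------------------------------

#' Transform raw rows with a frozen preprocessor
#'
#' Applies, per continuous feature, impute -> winsorize -> log1p (if
#' rostered) -> standardize with the fit-time parameters; passes binaries
#' through; one-hot encodes categoricals. An unseen categorical level is an
#' error (no silent new column).
#'
#' @param rows data.frame of raw rows containing every retained feature.
#' @param state a fitted [fit_preprocessor()] state.
#' @return numeric matrix, one row per input row, columns
#'   `state$output_names`.
#' @export
transform_cohort <- function(rows, state) {
  stopifnot(inherits(state, "preprocessor_state"))
  n <- nrow(rows)
  out <- matrix(0, n, length(state$output_names),
                dimnames = list(NULL, state$output_names))
  for (f in state$continuous) {
    v <- impute(rows[[f]], state$impute_mean[[f]])
    v <- winsorize(v, state$clip_low[[f]], state$clip_high[[f]])
    v <- log1p_selected(v, f, state$log_roster)
    out[, f] <- standardize(v, state$standardize_mean[[f]],
                            state$standardize_sd[[f]])
  }
  for (b in state$binary) {
    v <- rows[[b]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      stop("binary feature `", b, "` must be complete 0/1", call. = FALSE)
    }
    out[, b] <- as.numeric(v)
  }
  for (f in state$categorical) {
    enc <- state$encoding_map[[f]]
    v <- as.character(rows[[f]])
    bad <- setdiff(unique(v), enc$levels)
    if (length(bad)) {
      stop("unknown level `", bad[1], "` for categorical feature `", f, "`",
           call. = FALSE)
    }
    for (i in seq_along(enc$columns)) {
      out[, enc$columns[i]] <- as.numeric(v == enc$levels[-1][i])
    }
  }
  out
}

#' @rdname transform_cohort
#' @param row a single raw row (1-row data.frame or named list).
#' @return `transform_record()`: a named numeric vector.
#' @export
transform_record <- function(row, state) {
  drop(transform_cohort(as.data.frame(row, stringsAsFactors = FALSE,
                                      check.names = FALSE), state))
}

## ---- serialization --------------------------------------------------------

#' Serialize and restore a fitted preprocessor
#'
#' State is stored as JSON at full numeric precision, so a restored state
#' produces bit-identical transforms.
#'
#' @param state a `preprocessor_state`.
#' @param path file path.
#' @return `read_preprocessor()` returns a `preprocessor_state`.
#' @export
write_preprocessor <- function(state, path) {
  stopifnot(inherits(state, "preprocessor_state"))
  x <- unclass(state)
  x$schema <- list(feature_names = state$schema$feature_names,
                   kinds = as.list(state$schema$kinds),
                   outcome_name = state$schema$outcome_name,
                   prev_feature = state$schema$prev_feature)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- structure(list(
    feature_names = as.character(x$schema$feature_names),
    kinds = unlist(x$schema$kinds),
    outcome_name = x$schema$outcome_name,
    prev_feature = x$schema$prev_feature
  ), class = "feature_schema")
  structure(list(
    schema = schema,
    continuous = as.character(x$continuous),
    binary = as.character(x$binary),
    categorical = as.character(x$categorical),
    impute_mean = as.list(x$impute_mean),
    clip_low = as.list(x$clip_low), clip_high = as.list(x$clip_high),
    log_roster = as.character(x$log_roster),
    skewness = as.list(x$skewness),
    standardize_mean = as.list(x$standardize_mean),
    standardize_sd = as.list(x$standardize_sd),
    encoding_map = lapply(x$encoding_map, function(e) list(
      levels = as.character(e$levels), baseline = e$baseline,
      columns = as.character(e$columns)
    )),
    dropped = as.character(x$dropped),
    output_names = as.character(x$output_names),
    skew_threshold = x$skew_threshold,
    clip_probs = as.numeric(x$clip_probs)
  ), class = "preprocessor_state")
}
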