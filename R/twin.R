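#' Construct a digital-twin linear model
#'
#' A linear model over the post-encoding feature schema (including a
#' previous-naming-score feature), trained by per-observation Adam updates on
#' the squared-error loss with an L2 penalty on the weights (intercept
#' exempt). With learning rate 1e-4 the model adjusts weights gradually as
#' observations stream in, the intended online regime; tests and recovery
#' experiments may raise the rate.
#'
#' @param feature_names ordered post-encoding feature names (e.g.
#'   `state$output_names` from [fit_preprocessor()]).
#' @param learning_rate Adam step size (default 1e-4).
#' @param beta1,beta2 Adam moment decays (defaults 0.9 / 0.999).
#' @param epsilon Adam stabilizer (default 1e-8).
#' @param l2_lambda L2 penalty strength per observation (default 1e-3).
#' @param intercept initial intercept. For outcomes far from zero,
#'   initializing at the mean training target lets the low-rate online
#'   updates concentrate on the feature weights.
#' @return an object of class `twin_model`.
#' @export
twin_model <- function(feature_names, learning_rate = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       l2_lambda = 1e-3, intercept = 0) {
  stopifnot(length(feature_names) >= 1L, !anyDuplicated(feature_names),
            learning_rate > 0, l2_lambda >= 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1, epsilon > 0)
  p <- length(feature_names)
  zero <- stats::setNames(numeric(p), feature_names)
  structure(list(
    weights = zero, intercept = intercept,
    adam = list(m = zero, v = zero, m_b = 0, v_b = 0, step_count = 0L,
                beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                learning_rate = learning_rate),
    l2_lambda = l2_lambda,
    feature_names = feature_names
  ), class = "twin_model")
}

#' @export
print.twin_model <- function(x, ...) {
  cat("<twin_model>", length(x$weights), "features;",
      x$adam$step_count, "Adam steps; lr", x$adam$learning_rate,
      "; lambda", x$l2_lambda, "\n")
  invisible(x)
}

#' Predict naming scores from feature vectors
#'
#' `intercept + x %*% weights`; pure, no state change.
#'
#' @param object a [twin_model()].
#' @param x named numeric vector or matrix with columns matching
#'   `object$feature_names`.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.twin_model <- function(object, x, ...) {
  if (is.matrix(x)) {
    drop(object$intercept + x[, object$feature_names, drop = FALSE] %*%
           object$weights)
  } else {
    object$intercept + sum(object$weights * x[object$feature_names])
  }
}

#' One Adam update on a single observation
#'
#' Takes the gradient of `0.5 * (y - yhat)^2 + 0.5 * lambda * ||w||^2`
#' with respect to the weights and (unregularized) intercept, updates the
#' first and second moment estimates with decay `beta1` / `beta2`, applies
#' the standard bias corrections, and moves the parameters by
#' `lr * m_hat / (sqrt(v_hat) + eps)`.
#'
#' @param model a [twin_model()].
#' @param x named numeric feature vector aligned to the model schema.
#' @param y observed naming score.
#' @return the updated `twin_model`.
#' @export
adam_step <- function(model, x, y) {
  x <- x[model$feature_names]
  yhat <- model$intercept + sum(model$weights * x)
  r <- y - yhat
  g_w <- -r * x + model$l2_lambda * model$weights
  g_b <- -r
  if (!all(is.finite(g_w)) || !is.finite(g_b)) {
    stop("non-finite gradient in adam_step", call. = FALSE)
  }
  a <- model$adam
  t <- a$step_count + 1L
  a$m <- a$beta1 * a$m + (1 - a$beta1) * g_w
  a$v <- a$beta2 * a$v + (1 - a$beta2) * g_w^2
  a$m_b <- a$beta1 * a$m_b + (1 - a$beta1) * g_b
  a$v_b <- a$beta2 * a$v_b + (1 - a$beta2) * g_b^2
  bc1 <- 1 - a$beta1^t
  bc2 <- 1 - a$beta2^t
  lr <- a$learning_rate
  model$weights <- model$weights -
    lr * (a$m / bc1) / (sqrt(a$v / bc2) + a$epsilon)
  model$intercept <- model$intercept -
    lr * (a$m_b / bc1) / (sqrt(a$v_b / bc2) + a$epsilon)
  a$step_count <- t
  model$adam <- a
  model
}

#' Pretrain the twin on baseline pairs
#'
#' Runs `n_epochs` passes of [adam_step()] over the baseline
#' (feature vector, first post-baseline score) pairs, in a freshly shuffled
#' (seeded) order each epoch. Pretraining stabilizes the online model before
#' streaming updates begin.
#'
#' @param model a [twin_model()].
#' @param X numeric matrix of transformed baseline feature vectors.
#' @param y numeric targets, one per row of `X`.
#' @param n_epochs passes over the data (default 100); 0 is a no-op.
#' @param seed shuffle seed (default 1).
#' @return the updated `twin_model`.
#' @export
pretrain <- function(model, X, y, n_epochs = 100L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 1L)
  if (n_epochs == 0L) return(model)
  set.seed(seed)
  n <- nrow(X)
  for (epoch in seq_len(n_epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      model <- adam_step(model, X[i, ], y[i])
    }
  }
  model
}

#' Stream the twin over post-baseline timepoints (prequential)
#'
#' For each timepoint `t = 1 .. T-1` in chronological order and each
#' participant in a seeded random order within the timepoint: build the raw
#' row from the participant's static features plus the previous naming score
#' (`pnt_prev = pnt[t-1]`), transform it with the frozen preprocessor,
#' record the model's prediction of `pnt[t]` *before* updating, then apply
#' one [adam_step()] on the observation. This predict-then-update ordering
#' (prequential evaluation) means every recorded prediction is out-of-sample
#' with respect to that observation.
#'
#' @param model a pretrained [twin_model()].
#' @param cohort participant table of raw static features.
#' @param trajectories long trajectory table (`participant_id`, `timepoint`,
#'   `pnt`).
#' @param state frozen [fit_preprocessor()] state.
#' @param seed seed for the within-timepoint participant order.
#' @param update apply Adam updates (default). `FALSE` freezes the model, so
#'   predictions at every timepoint come from the pretrained weights
#'   (post-hoc rather than prequential scoring).
#' @return `list(model, predictions)`; `predictions` is a data.frame with
#'   `participant_id`, `timepoint`, `y_true`, `y_pred`, `residual`.
#' @export
stream_update <- function(model, cohort, trajectories, state, seed = 1L,
                          update = TRUE) {
  pnt <- trajectories_matrix(cohort, trajectories)
  T_ <- ncol(pnt)
  if (T_ < 2L) stop("every trajectory needs >= 2 timepoints", call. = FALSE)
  n <- nrow(cohort)
  set.seed(seed)
  preds <- vector("list", T_ - 1L)
  prev_feature <- state$schema$prev_feature
  for (t in 2:T_) {
    rows <- cohort
    rows[[prev_feature]] <- pnt[, t - 1L]
    Xt <- transform_cohort(rows, state)
    ord <- sample.int(n)
    y_pred <- numeric(n)
    for (i in ord) {
      y_pred[i] <- predict(model, Xt[i, ])
      if (update) model <- adam_step(model, Xt[i, ], pnt[i, t])
    }
    preds[[t - 1L]] <- data.frame(
      participant_id = cohort$participant_id,
      timepoint = t - 1L, y_true = pnt[, t], y_pred = y_pred,
      residual = pnt[, t] - y_pred, stringsAsFactors = FALSE
    )
  }
  list(model = model, predictions = do.call(rbind, preds))
}

# Wide matrix of scores (participants x timepoints) aligned to cohort order.
trajectories_matrix <- function(cohort, trajectories) {
  tps <- sort(unique(trajectories$timepoint))
  if (!identical(tps, seq_along(tps) - 1L)) {
    stop("timepoints must be contiguous 0..T-1", call. = FALSE)
  }
  pnt <- matrix(NA_real_, nrow(cohort), length(tps))
  idx <- match(trajectories$participant_id, cohort$participant_id)
  if (anyNA(idx)) {
    stop("trajectory references unknown participant", call. = FALSE)
  }
  pnt[cbind(idx, trajectories$timepoint + 1L)] <- trajectories$pnt
  if (anyNA(pnt)) {
    stop("every participant needs a score at every timepoint", call. = FALSE)
  }
  pnt
}

#' Coefficient of determination over prediction records
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` over the selected records.
#'
#' @param records prediction data.frame from [stream_update()].
#' @param final_timepoint_only restrict to the last timepoint (default), the
#'   study's headline evaluation; `FALSE` pools all streamed predictions.
#' @return R-squared.
#' @export
evaluate_r2 <- function(records, final_timepoint_only = TRUE) {
  if (final_timepoint_only) {
    records <- records[records$timepoint == max(records$timepoint), ]
  }
  y <- records$y_true
  if (length(y) < 2L) stop("need >= 2 records for R2", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R2 undefined: constant y_true", call. = FALSE)
  1 - sum((y - records$y_pred)^2) / ss_tot
}

#' Rank model weights by absolute magnitude
#'
#' @param model a fitted [twin_model()].
#' @param top_k number of features to return (default 10).
#' @return data.frame `feature`, `weight`, sorted by `|weight|` descending;
#'   ties broken by feature name.
#' @export
rank_weights <- function(model, top_k = 10L) {
  w <- model$weights
  ord <- order(-abs(w), names(w))
  k <- min(top_k, length(w))
  data.frame(feature = names(w)[ord][seq_len(k)],
             weight = unname(w[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Serialize and restore a twin model
#'
#' Weights, intercept, Adam moments and configuration stored as JSON at full
#' precision.
#'
#' @param model a `twin_model`.
#' @param path file path.
#' @return `read_twin_model()` returns a `twin_model`.
#' @export
write_twin_model <- function(model, path) {
  stopifnot(inherits(model, "twin_model"))
  x <- list(
    feature_names = model$feature_names,
    weights = unname(model$weights), intercept = model$intercept,
    l2_lambda = model$l2_lambda,
    adam = list(m = unname(model$adam$m), v = unname(model$adam$v),
                m_b = model$adam$m_b, v_b = model$adam$v_b,
                step_count = model$adam$step_count,
                beta1 = model$adam$beta1, beta2 = model$adam$beta2,
                epsilon = model$adam$epsilon,
                learning_rate = model$adam$learning_rate)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_twin_model
#' @export
read_twin_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fn <- as.character(x$feature_names)
  structure(list(
    weights = stats::setNames(as.numeric(x$weights), fn),
    intercept = x$intercept,
    adam = list(m = stats::setNames(as.numeric(x$adam$m), fn),
                v = stats::setNames(as.numeric(x$adam$v), fn),
                m_b = x$adam$m_b, v_b = x$adam$v_b,
                step_count = as.integer(x$adam$step_count),
                beta1 = x$adam$beta1, beta2 = x$adam$beta2,
                epsilon = x$adam$epsilon,
                learning_rate = x$adam$learning_rate),
    l2_lambda = x$l2_lambda, feature_names = fn
  ), class = "twin_model")
}
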