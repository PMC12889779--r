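test_that("prediction is the intercept plus the dot product", {
  m <- twin_model(c("a", "b"))
  m$intercept <- 50
  expect_equal(predict(m, c(a = 3, b = -7)), 50)

  m$intercept <- 0
  m$weights[] <- c(2, -1)
  expect_equal(predict(m, c(a = 3, b = 4)), 2)

  set.seed(11)
  p <- 10
  m10 <- twin_model(paste0("f", 1:p))
  m10$weights[] <- rnorm(p)
  m10$intercept <- rnorm(1)
  x <- rnorm(p); names(x) <- paste0("f", 1:p)
  acc <- m10$intercept
  for (f in names(x)) acc <- acc + m10$weights[[f]] * x[[f]]
  expect_equal(predict(m10, x), acc, tolerance = 1e-12)
  # name alignment, not position
  expect_equal(predict(m10, rev(x)), acc, tolerance = 1e-12)
})

test_that("adam_step is stationary at zero residual without regularization", {
  m <- twin_model("a", l2_lambda = 0)
  m$weights[] <- 2; m$intercept <- 1
  m2 <- adam_step(m, c(a = 3), y = 7)   # yhat = 1 + 6 = 7
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$adam$step_count, 1L)
})

test_that("the first Adam step has magnitude about the learning rate", {
  m <- twin_model("a", learning_rate = 1e-4, l2_lambda = 0)
  m2 <- adam_step(m, c(a = 1), y = 30)  # gradient -30, well above epsilon
  expect_equal(abs(m2$weights[["a"]]), 1e-4, tolerance = 1e-6)
  expect_equal(sign(m2$weights[["a"]]), 1)  # moves toward the target
})

test_that("two consecutive steps match a hand-rolled Adam trace", {
  lr <- 0.01; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lam <- 1e-3
  m <- twin_model("a", learning_rate = lr, beta1 = b1, beta2 = b2,
                  epsilon = eps, l2_lambda = lam)
  x <- 2; y <- 5
  # independent scalar trace of the same recurrences
  w <- 0; b <- 0; mw <- vw <- mb <- vb <- 0
  for (t in 1:2) {
    r <- y - (b + w * x)
    gw <- -r * x + lam * w
    gb <- -r
    mw <- b1 * mw + (1 - b1) * gw; vw <- b2 * vw + (1 - b2) * gw^2
    mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
    w <- w - lr * (mw / (1 - b1^t)) / (sqrt(vw / (1 - b2^t)) + eps)
    b <- b - lr * (mb / (1 - b1^t)) / (sqrt(vb / (1 - b2^t)) + eps)
  }
  m <- adam_step(m, c(a = x), y)
  m <- adam_step(m, c(a = x), y)
  expect_equal(m$weights[["a"]], w, tolerance = 1e-14)
  expect_equal(m$intercept, b, tolerance = 1e-14)
  expect_identical(m$adam$step_count, 2L)
})

test_that("non-finite gradients abort instead of propagating", {
  m <- twin_model("a")
  expect_error(adam_step(m, c(a = Inf), y = 1), "non-finite")
})

test_that("pretraining with zero epochs is a no-op", {
  m <- twin_model(c("a", "b"))
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(pretrain(m, X, rnorm(5), n_epochs = 0), m)
})

test_that("long pretraining converges to the closed-form ridge solution", {
  set.seed(21)
  n <- 40; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(1.5, -2, 0.5, 0, 1)
  y <- 3 + drop(X %*% beta) + rnorm(n, 0, 0.3)
  lam <- 1e-3
  # normal-equations oracle: intercept unpenalized, penalty n * lambda
  A <- cbind(1, X)
  P <- diag(c(0, rep(n * lam, p)))
  ref <- drop(solve(crossprod(A) + P, crossprod(A, y)))

  m <- twin_model(colnames(X), learning_rate = 0.05, l2_lambda = lam)
  m <- pretrain(m, X, y, n_epochs = 400, seed = 1)
  m$adam$learning_rate <- 0.002
  m <- pretrain(m, X, y, n_epochs = 400, seed = 2)
  expect_lt(max(abs(c(m$intercept, m$weights) - ref)), 1e-2)
})

test_that("streaming is prequential: one prediction per participant per step", {
  fx <- test_fixture(n = 15, seed = 22,
                     spec = test_spec(15, 22, n_timepoints = 2))
  m <- twin_model(fx$state$output_names, intercept = mean(fx$pnt[, 2]))
  out <- stream_update(m, fx$cohort, fx$trajectories, fx$state)
  expect_equal(nrow(out$predictions), 15)
  expect_equal(unique(out$predictions$timepoint), 1L)
  expect_equal(out$predictions$residual,
               out$predictions$y_true - out$predictions$y_pred)
})

test_that("a frozen model predicts from pretrained weights, order-invariantly", {
  fx <- test_fixture(n = 20, seed = 23)
  m <- twin_model(fx$state$output_names, intercept = mean(fx$pnt[, 2]))
  m <- pretrain(m, fx$X0, fx$pnt[, 2], n_epochs = 20, seed = 1)
  frozen1 <- stream_update(m, fx$cohort, fx$trajectories, fx$state,
                           seed = 1, update = FALSE)
  frozen2 <- stream_update(m, fx$cohort, fx$trajectories, fx$state,
                           seed = 999, update = FALSE)
  expect_identical(frozen1$predictions, frozen2$predictions)
  expect_identical(frozen1$model$weights, m$weights)
  # and the predictions equal direct pretrained-model predictions
  for (t in 2:ncol(fx$pnt)) {
    rows <- fx$cohort
    rows$pnt_prev <- fx$pnt[, t - 1]
    direct <- predict(m, transform_cohort(rows, fx$state))
    got <- frozen1$predictions$y_pred[frozen1$predictions$timepoint == t - 1]
    expect_equal(got, unname(direct), tolerance = 1e-12)
  }
})

test_that("R2 matches hand arithmetic and rejects degenerate inputs", {
  rec <- function(y, yhat) data.frame(participant_id = seq_along(y),
                                      timepoint = 1L, y_true = y,
                                      y_pred = yhat,
                                      residual = y - yhat)
  expect_equal(evaluate_r2(rec(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(evaluate_r2(rec(c(1, 2, 3), rep(2, 3))), 0)
  expect_equal(evaluate_r2(rec(c(1, 2, 3), c(1, 2, 4))), 0.5)
  expect_error(evaluate_r2(rec(c(2, 2, 2), c(1, 2, 3))), "constant")
  expect_error(evaluate_r2(rec(1, 1)), ">= 2")

  # invariant to ordering and to records at the mean with zero residual
  r <- rec(c(1, 2, 3, 6), c(1.2, 1.9, 3.3, 5.1))
  expect_equal(evaluate_r2(r[sample(4), ]), evaluate_r2(r))
  padded <- rbind(r, rec(mean(r$y_true), mean(r$y_true)))
  expect_equal(evaluate_r2(padded), evaluate_r2(r))
})

test_that("weight ranking sorts by magnitude with lexicographic ties", {
  m <- twin_model(c("a", "b", "c", "d"))
  m$weights[] <- c(0.1, -0.2, 0.2, 0.05)
  rk <- rank_weights(m, top_k = 4)
  expect_equal(rk$feature, c("b", "c", "a", "d"))
  expect_equal(rk$weight[1], -0.2)
  expect_equal(nrow(rank_weights(m, top_k = 2)), 2)
})

test_that("model state survives JSON serialization bit-identically", {
  fx <- test_fixture(n = 10, seed = 24)
  m <- twin_model(fx$state$output_names, learning_rate = 0.01)
  m <- pretrain(m, fx$X0, fx$pnt[, 2], n_epochs = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_twin_model(m, path)
  m2 <- read_twin_model(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$adam$m, m$adam$m)
  expect_identical(m2$adam$v, m$adam$v)
  expect_identical(m2$adam$step_count, m$adam$step_count)
  expect_equal(predict(m2, fx$X0[1, ]), predict(m, fx$X0[1, ]))
})
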