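#' Clamp values to an interval
#'
#' @param x numeric vector.
#' @param lower,upper interval bounds.
#' @return `x` with values outside `[lower, upper]` replaced by the bound.
#' @export
clamp <- function(x, lower = 0, upper = 100) {
  pmin(pmax(x, lower), upper)
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' The bias-adjusted standardized third moment,
#' `g1 * sqrt(n * (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`.
#' Used to decide which predictors receive a log1p transform.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return skewness estimate; `NA` if fewer than 3 observations or zero variance.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean(d^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Mean of a normal(mu, sd) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter mu such that the [lower, upper]-truncated normal with
# scale `sd` has mean exactly `target`. Keeps the generator's sample means on
# the published cohort targets despite eligibility truncation.
calibrate_truncnorm_mu <- function(target, sd, lower, upper) {
  stopifnot(target > lower, target < upper, sd > 0)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  stats::uniroot(f, lower = target - 6 * sd, upper = target + 6 * sd,
                 tol = 1e-10)$root
}

# Inverse CDF of the truncated normal: maps p in (0, 1) to [lower, upper].
qtruncnorm <- function(p, mu, sd, lower, upper) {
  pa <- stats::pnorm(lower, mu, sd)
  pb <- stats::pnorm(upper, mu, sd)
  stats::qnorm(pa + p * (pb - pa), mu, sd)
}

# Draw from a truncated normal whose *truncated* mean equals `target`.
# `p` supplies uniforms (for copula coupling); otherwise runif is used.
rtruncnorm_calibrated <- function(n, target, sd, lower, upper, p = NULL) {
  mu <- calibrate_truncnorm_mu(target, sd, lower, upper)
  if (is.null(p)) p <- stats::runif(n)
  qtruncnorm(p, mu, sd, lower, upper)
}

# Validation helper: stop with the offending field named.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
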