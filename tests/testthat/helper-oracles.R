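# Independent oracles kept deliberately separate from the package internals.

# Normal-equations least squares for the two-factor quadratic: builds the
# design matrix by hand and solves X'X b = X'y directly.
oracle_quad_fit <- function(data, response, terms = c("x1", "x2", "x1sq", "x2sq", "x1x2")) {
  cols <- list(
    intercept = rep(1, nrow(data)),
    x1 = data$x1, x2 = data$x2,
    x1sq = data$x1^2, x2sq = data$x2^2, x1x2 = data$x1 * data$x2
  )
  X <- do.call(cbind, cols[c("intercept", terms)])
  y <- data[[response]]
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Closed-form stationary point of b0 + b1 x1 + b2 x2 + b11 x1^2 + b22 x2^2
# + b12 x1 x2 (gradient solve, independent of optimize_surface()).
oracle_stationary_point <- function(b) {
  H <- matrix(c(2 * b[["x1sq"]], b[["x1x2"]], b[["x1x2"]], 2 * b[["x2sq"]]), 2)
  drop(solve(H, -c(b[["x1"]], b[["x2"]])))
}

# Constant predictor pinned to the overall experimental mean (the Q2 = 0
# baseline by definition).
overall_mean_factory <- function(response, full_data) {
  m <- mean(full_data[[response]])
  function(train) function(newdata) rep(m, nrow(newdata))
}

# Oracle predictor: returns the held-out truth (Q2 = 1 by definition).
oracle_factory <- function(response) {
  function(train) function(newdata) newdata[[response]]
}

# absolute-tolerance assertion (printed-value comparisons are absolute)
expect_within <- function(actual, target, tol = 0.01) {
  testthat::expect_lt(max(abs(actual - target)), tol)
}
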