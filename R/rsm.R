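# Canonical term set of the two-factor quadratic, in coded units:
# y = b0 + b1*x1 + b2*x2 + b11*x1^2 + b22*x2^2 + b12*x1*x2
rsm_all_terms <- c("x1", "x2", "x1sq", "x2sq", "x1x2")

rsm_term_label <- c(
  x1 = "x1", x2 = "x2", x1sq = "I(x1^2)", x2sq = "I(x2^2)", x1x2 = "x1:x2"
)

rsm_formula <- function(response, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(rsm_term_label[terms], collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

# lm() reports the interaction as "x1:x2" (or "x2:x1" when the x1 main
# effect is absent) and quadratics as "I(x1^2)"; map back to canonical names.
rsm_canonical_name <- function(lm_names) {
  lut <- c(
    "(Intercept)" = "intercept",
    "x2:x1" = "x1x2",
    setNames(names(rsm_term_label), unname(rsm_term_label))
  )
  unname(lut[lm_names])
}

#' Fit the two-factor quadratic response surface
#'
#' Ordinary least squares of a response on the coded factors, their squares
#' and their interaction, fitted over all individual samples (replicates
#' included, n = 29 for the packaged experiment table). Because least squares
#' only sees the per-condition sums, storing condition means with their
#' replicate multiplicity yields the same coefficients as the raw replicates
#' would.
#'
#' @param data An `fcd_df` tibble with a column named in `response`.
#' @param response Response column name, e.g. `"flux"` or `"fouling_index"`.
#' @param terms Character vector of model terms to include, a subset of
#'   `c("x1", "x2", "x1sq", "x2sq", "x1x2")`. The intercept is always
#'   included. Defaults to the full quadratic.
#' @return An object of class `rsm_fit`: the coefficient vector over the
#'   canonical term set (excluded terms carry exactly 0), the included-term
#'   mask, the underlying `lm` fit, residual variance and sample count.
#' @examples
#' fit <- fit_quadratic(coconut_design(), "flux")
#' coef(fit)
#' @export
fit_quadratic <- function(data, response, terms = rsm_all_terms) {
  stopifnot(response %in% names(data))
  if (length(terms) > 0) {
    terms <- match.arg(terms, rsm_all_terms, several.ok = TRUE)
  }
  if (nrow(data) < length(terms) + 1L) {
    abort("fewer samples than model terms", class = "cocoflux_singular_fit")
  }
  fit <- lm(rsm_formula(response, terms), data = data)
  if (anyNA(coef(fit))) {
    abort(
      "design is rank-deficient for the requested terms",
      class = "cocoflux_singular_fit"
    )
  }
  beta <- setNames(numeric(6), c("intercept", rsm_all_terms))
  est <- coef(fit)
  beta[rsm_canonical_name(names(est))] <- est
  structure(
    list(
      response = response,
      coefficients = beta,
      included_terms = c("intercept", terms),
      dropped_terms = setdiff(rsm_all_terms, terms),
      lm = fit,
      covariance = suppressWarnings(vcov(fit)),
      # perfect fits (noise-free synthetic data) are legitimate here
      sigma2 = suppressWarnings(summary(fit)$sigma^2),
      n = nrow(data),
      factors = attr(data, "factors"),
      alpha = NA_real_
    ),
    class = "rsm_fit"
  )
}

#' Prune non-significant terms and refit
#'
#' Fits the full quadratic, drops every non-intercept term whose t-test
#' p-value exceeds `alpha` (ties at `alpha` are retained), and refits the
#' reduced model. This fit-prune-refit recipe is the package's reference
#' pipeline for the microfiltration design: it removes the pressure linear
#' term for permeate flux and the temperature linear plus pressure quadratic
#' terms for the fouling index.
#'
#' @inheritParams fit_quadratic
#' @param alpha Significance level for term retention (default 0.05).
#' @return An `rsm_fit` of the reduced model.
#' @examples
#' fit <- fit_rsm(coconut_design(), "flux")
#' fit$dropped_terms  # "x1"
#' @export
fit_rsm <- function(data, response, alpha = 0.05) {
  full <- fit_quadratic(data, response)
  p <- suppressWarnings(summary(full$lm))$coefficients[, "Pr(>|t|)"]
  names(p) <- rsm_canonical_name(names(p))
  drop <- names(p)[p > alpha & names(p) != "intercept"]
  keep <- setdiff(rsm_all_terms, drop)
  if (length(keep) == 0) {
    warn("all non-intercept terms non-significant; returning intercept-only model")
  }
  out <- fit_quadratic(data, response, terms = keep)
  out$alpha <- alpha
  out$full_fit <- full
  out
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Quadratic response surface for `", x$response, "` (coded factors)\n", sep = "")
  cat("  included terms:", paste(x$included_terms, collapse = ", "), "\n")
  if (length(x$dropped_terms) > 0) {
    cat("  dropped terms: ", paste(x$dropped_terms, collapse = ", "),
        " (alpha = ", x$alpha, ")\n", sep = "")
  }
  print(round(x$coefficients, 4))
  invisible(x)
}

rsm_newdata <- function(object, newdata = NULL, pressure = NULL,
                        temperature = NULL, coded = NULL) {
  if (!is.null(coded)) {
    coded <- matrix(coded, ncol = 2)
    return(tibble::tibble(x1 = coded[, 1], x2 = coded[, 2]))
  }
  if (!is.null(pressure)) {
    p <- factor_row(object$factors, "pressure")
    t <- factor_row(object$factors, "temperature")
    return(tibble::tibble(
      x1 = code_level(pressure, p),
      x2 = code_level(temperature, t)
    ))
  }
  if (is.null(newdata)) abort("supply `newdata`, `coded` or actual levels")
  if (!all(c("x1", "x2") %in% names(newdata))) {
    p <- factor_row(object$factors, "pressure")
    t <- factor_row(object$factors, "temperature")
    newdata$x1 <- code_level(newdata$pressure, p)
    newdata$x2 <- code_level(newdata$temperature, t)
  }
  newdata
}

#' Predict from a fitted response surface
#'
#' Evaluates the included-term polynomial; the standard error comes from the
#' reduced-model coefficient covariance. Points outside the coded unit box
#' are extrapolations and flagged as such.
#'
#' @param object An `rsm_fit`.
#' @param newdata Optional tibble with columns `x1`/`x2` (coded) or
#'   `pressure`/`temperature` (actual units).
#' @param pressure,temperature Optional actual-unit levels (vectorized).
#' @param coded Optional 2-column matrix (or length-2 vector) of coded levels.
#' @param ... Unused.
#' @return A tibble with columns `x1`, `x2`, `.pred`, `.se` and
#'   `extrapolated`.
#' @examples
#' fit <- fit_rsm(coconut_design(), "flux")
#' predict(fit, pressure = 75, temperature = 30)  # 611.48 +/- 13.93
#' @export
predict.rsm_fit <- function(object, newdata = NULL, pressure = NULL,
                            temperature = NULL, coded = NULL, ...) {
  nd <- rsm_newdata(object, newdata, pressure, temperature, coded)
  pr <- suppressWarnings(predict(object$lm, newdata = nd, se.fit = TRUE))
  out <- tibble::tibble(
    x1 = nd$x1, x2 = nd$x2,
    .pred = unname(pr$fit), .se = unname(pr$se.fit),
    extrapolated = abs(nd$x1) > 1 + 1e-9 | abs(nd$x2) > 1 + 1e-9
  )
  if (any(out$extrapolated)) {
    warn("some prediction points lie outside the coded design box")
  }
  out
}

#' @method tidy rsm_fit
#' @export
tidy.rsm_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$lm))$coefficients
  tibble::tibble(
    term = rsm_canonical_name(rownames(s)),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @method glance rsm_fit
#' @export
glance.rsm_fit <- function(x, ...) {
  a <- anova_rsm(x)
  tibble::tibble(
    r.squared = a$r_squared,
    sigma = sqrt(x$sigma2),
    f.calculated = a$f_cal,
    f.tabulated = a$f_tab,
    p.value = a$p_value,
    df.regression = a$table$df[a$table$source == "regression"],
    df.residual = a$table$df[a$table$source == "residual"],
    nobs = x$n
  )
}

#' ANOVA decomposition of a fitted response surface
#'
#' Splits the total sum of squares into regression and residual parts and,
#' when the design is replicated, splits the residual into lack-of-fit and
#' pure error. `F_cal` is the regression mean square over the residual mean
#' square and is compared with the tabulated F at level `alpha`.
#'
#' @param object An `rsm_fit`.
#' @param alpha Level for the tabulated F quantile.
#' @return A list with the decomposition `table` (source, df, sum_sq,
#'   mean_sq), `r_squared`, `f_cal`, `f_tab`, `p_value`, `f_lof` (lack-of-fit
#'   F against pure error, `NA` when pure error is not estimable) and
#'   `pure_error_available`.
#' @export
anova_rsm <- function(object, alpha = 0.05) {
  mf <- model.frame(object$lm)
  y <- mf[[1]]
  x1 <- object$lm$model$x1
  x2 <- object$lm$model$x2
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(residuals(object$lm)^2)
  ss_reg <- ss_tot - ss_res
  df_reg <- length(object$included_terms) - 1L
  df_res <- n - df_reg - 1L

  cond <- interaction(x1, x2, drop = TRUE)
  reps <- table(cond)
  pure_ok <- any(reps > 1)
  if (pure_ok) {
    ss_pe <- sum(tapply(y, cond, function(v) sum((v - mean(v))^2)))
    df_pe <- n - length(reps)
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
  } else {
    ss_pe <- NA_real_; df_pe <- NA_integer_
    ss_lof <- NA_real_; df_lof <- NA_integer_
  }

  ms_reg <- ss_reg / df_reg
  ms_res <- ss_res / df_res
  f_cal <- ms_reg / ms_res
  f_tab <- qf(1 - alpha, df_reg, df_res)
  f_lof <- if (pure_ok && df_lof > 0 && df_pe > 0 && ss_pe > 0) {
    (ss_lof / df_lof) / (ss_pe / df_pe)
  } else {
    NA_real_
  }
  tbl <- tibble::tibble(
    source = c("regression", "residual", "lack_of_fit", "pure_error", "total"),
    df = c(df_reg, df_res, df_lof, df_pe, n - 1L),
    sum_sq = c(ss_reg, ss_res, ss_lof, ss_pe, ss_tot)
  )
  tbl$mean_sq <- tbl$sum_sq / tbl$df
  list(
    table = tbl,
    r_squared = ss_reg / ss_tot,
    f_cal = f_cal,
    f_tab = f_tab,
    p_value = pf(f_cal, df_reg, df_res, lower.tail = FALSE),
    f_lof = f_lof,
    pure_error_available = pure_ok
  )
}

rsm_eval <- function(beta, x1, x2) {
  beta[["intercept"]] + beta[["x1"]] * x1 + beta[["x2"]] * x2 +
    beta[["x1sq"]] * x1^2 + beta[["x2sq"]] * x2^2 + beta[["x1x2"]] * x1 * x2
}

# 1-D quadratic a*t^2 + b*t + c optimum over [lo, hi] (interior vertex +
# endpoints), returning the candidate t values to evaluate.
quad_1d_candidates <- function(a, b, lo, hi) {
  cand <- c(lo, hi)
  if (abs(a) > 1e-12) {
    v <- -b / (2 * a)
    if (v > lo && v < hi) cand <- c(cand, v)
  }
  cand
}

#' Locate the optimum of a response surface over the coded box
#'
#' Deterministic global optimization of the two-variable quadratic over
#' \[-1, 1\]^2: the analytic stationary point (solution of the zero-gradient
#' system) is checked against the four edges (each a one-variable quadratic
#' with a closed-form vertex) and the corners, and the best feasible
#' candidate wins.
#'
#' @param object An `rsm_fit`.
#' @param direction `"max"` or `"min"`.
#' @param bounds Length-4 numeric `c(x1_lo, x1_hi, x2_lo, x2_hi)` in coded
#'   units.
#' @return A one-row tibble: coded and actual location, predicted response,
#'   its standard error, and flags `boundary` (optimum on the box edge) and
#'   `flat` (surface has no curvature or slope).
#' @examples
#' fit <- fit_rsm(coconut_design(), "flux")
#' optimize_surface(fit)  # interior maximum near 126.9 kPa, 32.8 degC
#' @export
optimize_surface <- function(object, direction = c("max", "min"),
                             bounds = c(-1, 1, -1, 1)) {
  direction <- match.arg(direction)
  b <- object$coefficients
  sign <- if (direction == "max") 1 else -1

  cand <- expand.grid(
    x1 = c(bounds[1], bounds[2]),
    x2 = c(bounds[3], bounds[4])
  )
  # interior stationary point: solve H %*% x = -g0 with H the Hessian
  H <- matrix(c(2 * b[["x1sq"]], b[["x1x2"]], b[["x1x2"]], 2 * b[["x2sq"]]), 2)
  g0 <- c(b[["x1"]], b[["x2"]])
  flat <- all(abs(c(H, g0)) < 1e-12)
  if (abs(det(H)) > 1e-12) {
    sp <- solve(H, -g0)
    if (sp[1] >= bounds[1] && sp[1] <= bounds[2] &&
        sp[2] >= bounds[3] && sp[2] <= bounds[4]) {
      cand <- rbind(cand, sp)
    }
  }
  # edges: x1 fixed at lo/hi -> quadratic in x2, and vice versa
  for (x1f in bounds[1:2]) {
    ts <- quad_1d_candidates(
      b[["x2sq"]], b[["x2"]] + b[["x1x2"]] * x1f, bounds[3], bounds[4]
    )
    cand <- rbind(cand, data.frame(x1 = x1f, x2 = ts))
  }
  for (x2f in bounds[3:4]) {
    ts <- quad_1d_candidates(
      b[["x1sq"]], b[["x1"]] + b[["x1x2"]] * x2f, bounds[1], bounds[2]
    )
    cand <- rbind(cand, data.frame(x1 = ts, x2 = x2f))
  }
  vals <- rsm_eval(b, cand$x1, cand$x2)
  best <- which.max(sign * vals)
  x1o <- cand$x1[best]; x2o <- cand$x2[best]
  pr <- predict(object, coded = c(x1o, x2o))
  p <- factor_row(object$factors, "pressure")
  t <- factor_row(object$factors, "temperature")
  on_edge <- any(abs(c(x1o - bounds[1:2], x2o - bounds[3:4])) < 1e-9)
  if (flat) warn("surface is flat; optimum location is arbitrary")
  tibble::tibble(
    x1 = x1o, x2 = x2o,
    pressure = decode_level(x1o, p),
    temperature = decode_level(x2o, t),
    value = pr$.pred, se = pr$.se,
    boundary = on_edge, flat = flat
  )
}
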