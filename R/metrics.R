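#' Fit-quality metric suite
#'
#' Computes the error metrics used to compare surrogate models against
#' experimental samples: mean absolute deviation (AAD), mean squared error
#' (MSE), MSE normalized by the experimental mean (NMSE), mean percentage
#' error (MPE, relative to the prediction), RMSE, RMSE normalized by the
#' experimental mean (NRMSE), and the coefficient of determination
#' `R2 = 1 - sum((pred - actual)^2) / sum((actual - mean(actual))^2)`.
#' `literal = TRUE` switches the R-squared denominator to the
#' prediction-centred form `sum((pred - mean(actual))^2)`.
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @param literal Use the prediction-centred R-squared denominator.
#' @return A one-row tibble with columns `aad`, `mse`, `nmse`, `mpe`,
#'   `rmse`, `nrmse`, `r_squared`, `n`. `mpe` is `NA` (with a warning) when
#'   any prediction is exactly zero.
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 1, 5))
#' @export
fit_metrics <- function(predicted, actual, literal = FALSE) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length",
          class = "cocoflux_metric_error")
  }
  n <- length(actual)
  if (n == 0) abort("empty input", class = "cocoflux_metric_error")
  xm <- mean(actual)
  err <- predicted - actual
  mse <- mean(err^2)
  mpe <- if (any(predicted == 0)) {
    warn("zero predictions: MPE undefined, returning NA")
    NA_real_
  } else {
    100 * mean(abs(err) / abs(predicted))
  }
  denom <- if (literal) sum((predicted - xm)^2) else sum((actual - xm)^2)
  tibble::tibble(
    aad = mean(abs(err)),
    mse = mse,
    nmse = mse / xm,
    mpe = mpe,
    rmse = sqrt(mse),
    nrmse = sqrt(mse) / xm,
    r_squared = 1 - sum(err^2) / denom,
    n = n
  )
}

#' Leave-one-condition-out cross-validation
#'
#' Grouped cross-validation over the design: in each fold every replicate of
#' one pressure-temperature condition is held out, the model is refitted on
#' the remaining samples, and the held-out samples are predicted. Pooled
#' over folds this yields
#' `Q2 = 1 - sum((actual - pred_cv)^2) / sum((actual - mean(actual))^2)` and
#' `RMSE_CV = sqrt(mean((actual - pred_cv)^2))`. By default the 9
#' geometrically unique conditions form the folds (no replicate leakage);
#' `folds = "run"` instead treats each of the 13 experiment rows as a fold,
#' so the center replicates are held out one at a time.
#'
#' @param data An `fcd_df` tibble.
#' @param response Response column name.
#' @param model_factory Function taking the training `fcd_df` and returning
#'   a prediction function `function(newdata) -> numeric` for `response`.
#' @param folds `"condition"` (default) or `"run"`.
#' @param literal Passed through to the Q-squared denominator convention
#'   (see [fit_metrics()]).
#' @return An object of class `cv_result`: the pooled `predictions` tibble
#'   (fold, row, actual, predicted), `q2`, `rmse_cv`, `n_folds` and any
#'   `failed_folds`.
#' @examples
#' rsm_factory <- function(train) {
#'   fit <- fit_rsm(train, "flux")
#'   function(newdata) predict(fit, newdata = newdata)$.pred
#' }
#' cv <- loco_cv(coconut_design(), "flux", rsm_factory)
#' cv$q2
#' @export
loco_cv <- function(data, response, model_factory,
                    folds = c("condition", "run"), literal = FALSE) {
  folds <- match.arg(folds)
  key <- if (folds == "condition") {
    interaction(data$x1, data$x2, drop = TRUE)
  } else {
    factor(data$run)
  }
  if (nlevels(key) < 3) {
    abort("need at least 3 unique conditions for grouped CV",
          class = "cocoflux_cv_error")
  }
  failed <- character(0)
  preds <- purrr::map_dfr(levels(key), function(lev) {
    hold <- key == lev
    train <- data[!hold, , drop = FALSE]
    attr(train, "factors") <- attr(data, "factors")
    pred_fun <- tryCatch(model_factory(train), error = function(e) NULL)
    if (is.null(pred_fun)) {
      failed <<- c(failed, lev)
      return(tibble::tibble())
    }
    tibble::tibble(
      fold = lev,
      row = which(hold),
      actual = data[[response]][hold],
      predicted = as.numeric(pred_fun(data[hold, , drop = FALSE]))
    )
  })
  xm <- mean(preds$actual)
  denom <- if (literal) {
    sum((preds$predicted - xm)^2)
  } else {
    sum((preds$actual - xm)^2)
  }
  press <- sum((preds$actual - preds$predicted)^2)
  structure(
    list(
      predictions = preds,
      q2 = 1 - press / denom,
      rmse_cv = sqrt(press / nrow(preds)),
      n_folds = nlevels(key),
      failed_folds = failed,
      response = response,
      folds = folds
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Grouped leave-one-condition-out CV for `", x$response, "`\n", sep = "")
  cat("  folds: ", x$n_folds, " (", x$folds, "); Q2 = ", signif(x$q2, 4),
      "; RMSE_CV = ", signif(x$rmse_cv, 4), "\n", sep = "")
  if (length(x$failed_folds) > 0) {
    cat("  failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    q2 = x$q2,
    rmse_cv = x$rmse_cv,
    n_folds = x$n_folds,
    n_failed = length(x$failed_folds)
  )
}

#' Model factories for cross-validation
#'
#' Convenience constructors producing the `model_factory` argument of
#' [loco_cv()]: `rsm_factory()` refits the pruned quadratic on each training
#' fold, `ann_factory()` retrains the neural surrogate (best of
#' `config$n_restarts` initializations).
#'
#' @param response Response column name.
#' @param alpha Pruning level for the quadratic.
#' @param config An [ann_config()] for the surrogate.
#' @return A function `function(train_data) -> function(newdata) -> numeric`.
#' @export
rsm_factory <- function(response, alpha = 0.05) {
  force(response); force(alpha)
  function(train) {
    fit <- fit_rsm(train, response, alpha = alpha)
    function(newdata) predict(fit, newdata = newdata)$.pred
  }
}

#' @rdname rsm_factory
#' @export
ann_factory <- function(response, config = ann_config(n_restarts = 3L)) {
  force(response); force(config)
  function(train) {
    fit <- select_best_mlp(train, config)
    function(newdata) predict(fit, newdata = newdata)[[response]]
  }
}
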