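#' Plot a fitted response surface
#'
#' Filled-contour map of the fitted quadratic over the coded design box, in
#' actual units, with the design points overlaid.
#'
#' @param object An `rsm_fit`.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsm_fit
#' @export
autoplot.rsm_fit <- function(object, n = 60, ...) {
  p <- factor_row(object$factors, "pressure")
  t <- factor_row(object$factors, "temperature")
  grid <- tidyr::expand_grid(
    x1 = seq(-1, 1, length.out = n),
    x2 = seq(-1, 1, length.out = n)
  )
  grid$.pred <- predict(object, newdata = grid)$.pred
  grid$pressure <- decode_level(grid$x1, p)
  grid$temperature <- decode_level(grid$x2, t)
  pts <- unique(model.frame(object$lm)[c("x1", "x2")])
  pts$pressure <- decode_level(pts$x1, p)
  pts$temperature <- decode_level(pts$x2, t)
  ggplot2::ggplot(grid, ggplot2::aes(.data$pressure, .data$temperature)) +
    ggplot2::geom_contour_filled(ggplot2::aes(z = .data$.pred)) +
    ggplot2::geom_point(data = pts, colour = "white", size = 2) +
    ggplot2::labs(
      x = paste0("pressure (", p$units, ")"),
      y = paste0("temperature (", t$units, ")"),
      fill = object$response,
      title = paste("Fitted response surface:", object$response)
    )
}

#' Plot a GA fitness trajectory
#'
#' Best and mean population fitness per generation.
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectory, c("best", "mean"),
                              names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = "fitness (minimized)",
                  colour = NULL, title = "GA convergence")
}

#' Plot blocking-law fits over a flux-decline series
#'
#' The observed series with the four fitted decay curves (back-transformed
#' from the linearized fits), ordered by fit quality in the legend.
#'
#' @param object A `hermia_ranking` from [select_mechanism()].
#' @param series The flux series the ranking was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hermia_ranking
#' @export
autoplot.hermia_ranking <- function(object, series, ...) {
  check_series(series)
  tt <- seq(min(series$time_h), max(series$time_h), length.out = 200)
  curves <- purrr::pmap_dfr(
    object[, c("law", "epsilon", "intercept")],
    function(law, epsilon, intercept) {
      z <- intercept + hermia_slope_sign(law) * epsilon * tt
      flux <- switch(law,
        complete = exp(z),
        standard = z^(-2),
        intermediate = 1 / z,
        cake = z^(-0.5)
      )
      tibble::tibble(law = law, time_h = tt, flux = flux)
    }
  )
  lab <- paste0(object$law, " (R2 = ", sprintf("%.3f", object$r_squared), ")")
  curves$law <- factor(curves$law, levels = object$law, labels = lab)
  ggplot2::ggplot(series, ggplot2::aes(.data$time_h, .data$flux)) +
    ggplot2::geom_point(size = 1, alpha = 0.6) +
    ggplot2::geom_line(data = curves, ggplot2::aes(colour = .data$law)) +
    ggplot2::labs(x = "time (h)", y = "permeate flux (L h-1 m-2)",
                  colour = "blocking law",
                  title = "Hermia blocking-law fits")
}

#' Plot the cumulative cash flow of a techno-economic result
#'
#' @param object A `tea_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tea_result
#' @export
autoplot.tea_result <- function(object, ...) {
  cf <- object$cashflows
  cf$cumulative <- cumsum(cf$net)
  ggplot2::ggplot(cf, ggplot2::aes(.data$year, .data$cumulative)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_col(ggplot2::aes(y = .data$net), alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "project year (0 = operations start)",
                  y = "US$ (nominal)",
                  title = "Net and cumulative cash flow")
}
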