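# Hermia constant-pressure blocking laws, indexed by the exponent n of the
# underlying d2t/dV2 = k (dt/dV)^n law. Each has a closed-form decay and a
# linearizing transform of the flux.
hermia_laws <- c("complete", "standard", "intermediate", "cake")

#' The four constant-pressure blocking laws
#'
#' @return A tibble with the law name, its characteristic exponent `n`, the
#'   linearizing transform applied to the flux, and the units of the rate
#'   constant epsilon (time in hours, flux in L h^-1 m^-2).
#' @export
blocking_laws <- function() {
  tibble::tibble(
    law = hermia_laws,
    n = c(2, 1.5, 1, 0),
    transform = c("log(J)", "J^(-1/2)", "J^(-1)", "J^(-2)"),
    epsilon_units = c("1/h", "(L h^-1 m^-2)^(-1/2) / h",
                      "(L h^-1 m^-2)^(-1) / h", "(L h^-1 m^-2)^(-2) / h")
  )
}

hermia_transform <- function(law, j) {
  switch(law,
    complete = log(j),
    standard = j^(-0.5),
    intermediate = 1 / j,
    cake = j^(-2),
    abort("unknown blocking law")
  )
}

# slope sign: the complete law is ln J = ln J0 - eps*t; the others are
# increasing transforms z = z0 + eps*t
hermia_slope_sign <- function(law) if (law == "complete") -1 else 1

#' Simulate constant-pressure flux decay under a blocking law
#'
#' Closed forms: complete `J = J0 exp(-eps t)`; standard
#' `J = (J0^(-1/2) + eps t)^(-2)`; intermediate `J = (J0^(-1) + eps t)^(-1)`;
#' cake `J = (J0^(-2) + eps t)^(-1/2)`.
#'
#' @param law One of `"complete"`, `"standard"`, `"intermediate"`, `"cake"`.
#' @param j0 Initial flux (L h^-1 m^-2), positive.
#' @param eps Rate constant in the law's units (see [blocking_laws()]),
#'   non-negative.
#' @param times Numeric vector of times (h).
#' @return A tibble with columns `time_h` and `flux`.
#' @examples
#' simulate_decay("intermediate", 600, 1 / 1200, c(0, 1, 2))  # 600, 400, 300
#' @export
simulate_decay <- function(law = hermia_laws, j0, eps, times) {
  law <- match.arg(law)
  stopifnot(j0 > 0, eps >= 0)
  flux <- switch(law,
    complete = j0 * exp(-eps * times),
    standard = (j0^(-0.5) + eps * times)^(-2),
    intermediate = (1 / j0 + eps * times)^(-1),
    cake = (j0^(-2) + eps * times)^(-0.5)
  )
  tibble::tibble(time_h = times, flux = flux)
}

check_series <- function(series) {
  stopifnot(all(c("time_h", "flux") %in% names(series)))
  if (nrow(series) < 2) abort("flux series needs at least 2 points")
  if (is.unsorted(series$time_h, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  bad <- which(series$flux <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive flux at index ", bad[1]),
          class = "cocoflux_series_error")
  }
  invisible(series)
}

#' Fit one blocking law to a flux-decline series
#'
#' Ordinary least squares of the law's linearizing transform of the flux
#' against time. The slope gives the rate constant (sign-adjusted for the
#' complete law) and the fit quality is the R-squared of the linearized
#' regression — the selection criterion used throughout.
#'
#' @param series Tibble with `time_h` and `flux` columns.
#' @param law Blocking law name.
#' @param burn_in Initial period (h) excluded from the fit; the first sharp
#'   decline is usually polarization, not blocking (default 0).
#' @return A one-row tibble: `law`, `epsilon`, `intercept`, `r_squared`,
#'   `n_points`, and flags `underdetermined` (exactly 2 points) and
#'   `degenerate` (constant series; epsilon 0, R-squared `NA`).
#' @export
fit_hermia <- function(series, law = hermia_laws, burn_in = 0) {
  law <- match.arg(law)
  check_series(series)
  use <- series[series$time_h >= series$time_h[1] + burn_in, , drop = FALSE]
  if (nrow(use) < 2) abort("burn-in leaves fewer than 2 points")
  z <- hermia_transform(law, use$flux)
  fit <- lm(z ~ use$time_h)
  slope <- coef(fit)[[2]]
  ss_tot <- sum((z - mean(z))^2)
  degenerate <- ss_tot < .Machine$double.eps * max(1, mean(z)^2) * length(z)
  r2 <- if (degenerate) NA_real_ else 1 - sum(residuals(fit)^2) / ss_tot
  tibble::tibble(
    law = law,
    epsilon = if (degenerate) 0 else hermia_slope_sign(law) * slope,
    intercept = coef(fit)[[1]],
    r_squared = r2,
    n_points = nrow(use),
    underdetermined = nrow(use) == 2,
    degenerate = degenerate
  )
}

#' Rank the blocking mechanisms for a flux-decline series
#'
#' Fits all four laws by linearized least squares and sorts them by
#' descending R-squared. When the top two R-squared values differ by less
#' than 0.01 the result is flagged as a mixed regime (the two mechanisms are
#' statistically indistinguishable over the run). A constant series is
#' degenerate: every law fits with rate 0 and the fixed law order is kept.
#'
#' @inheritParams fit_hermia
#' @return A tibble of class `hermia_ranking` with one row per law, ordered
#'   by fit quality, and attributes `mixed_regime` and `degenerate`.
#' @examples
#' s <- simulate_decay("intermediate", 600, 1 / 1200, seq(0, 2, by = 1 / 30))
#' select_mechanism(s)
#' @export
select_mechanism <- function(series, burn_in = 0) {
  fits <- purrr::map_dfr(hermia_laws, function(l) fit_hermia(series, l, burn_in))
  degenerate <- all(fits$degenerate)
  if (!degenerate) {
    fits <- fits[order(-fits$r_squared), ]
  }
  r2 <- fits$r_squared
  mixed <- !degenerate && length(r2) >= 2 && (r2[1] - r2[2]) < 0.01
  out <- tibble::new_tibble(fits, class = "hermia_ranking")
  attr(out, "mixed_regime") <- mixed
  attr(out, "degenerate") <- degenerate
  out
}
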