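# Default "true" coefficient sets for synthetic designs: the full-model
# least-squares coefficients of the packaged experiment table, so simulated
# magnitudes (flux ~300-680 L/h/m2, fouling ~78-95%) match the real process.
default_fcd_beta <- function() {
  list(
    flux = c(intercept = 660.59, x1 = -12.78, x2 = 79.86,
             x1sq = -110.48, x2sq = -141.86, x1x2 = 19.36),
    fouling_index = c(intercept = 85.43, x1 = 5.81, x2 = 0.09,
                      x1sq = -0.22, x2sq = 3.75, x1x2 = 0.75)
  )
}

#' Generate a synthetic face-centered-design dataset
#'
#' Draws replicate responses from known quadratic surfaces plus additive
#' Gaussian noise: `y = poly(beta, x1, x2) + N(0, sd)` independently per
#' sample. With `sd = 0` the generating coefficients are recovered exactly
#' by least squares. The default coefficients and noise levels mirror the
#' magnitudes of the real microfiltration experiment.
#'
#' @param beta Named list of length-6 coefficient vectors (elements
#'   `intercept`, `x1`, `x2`, `x1sq`, `x2sq`, `x1x2`), one per response.
#' @param sd Named numeric vector of noise standard deviations, one per
#'   response (response units).
#' @param factors Factor specification ([fcd_factors()]).
#' @param replicates Replication plan as in [build_fcd()].
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return An `fcd_df` tibble with one response column per element of
#'   `beta`; the generating coefficients are attached as
#'   `attr(, "true_beta")`.
#' @examples
#' d <- gen_fcd_dataset(sd = c(flux = 0, fouling_index = 0), seed = 1)
#' coef(fit_quadratic(d, "flux"))
#' @export
gen_fcd_dataset <- function(beta = default_fcd_beta(),
                            sd = c(flux = 15, fouling_index = 1),
                            factors = fcd_factors(),
                            replicates = c(non_center = 3L, center = 5L),
                            seed = 1L) {
  stopifnot(is.list(beta), all(names(beta) %in% names(sd) | length(sd) == 1))
  d <- build_fcd(factors, replicates)
  with_seed(seed, {
    for (resp in names(beta)) {
      b <- beta[[resp]]
      mu <- rsm_eval(as.list(b), d$x1, d$x2)
      s <- if (length(sd) == 1) sd else sd[[resp]]
      d[[resp]] <- mu + rnorm(nrow(d), 0, s)
    }
  })
  attr(d, "true_beta") <- beta
  d
}

#' Generate a synthetic flux-decline series
#'
#' Closed-form blocking-law decay multiplied by lognormal noise of the given
#' coefficient of variation (multiplicative noise keeps fluxes positive);
#' the first point is exactly `j0`. The default rate constant is chosen so
#' the flux halves over the run — the magnitude of in-run decline typical of
#' coconut-water microfiltration — and the default sampling is every 2
#' minutes for 2 hours.
#'
#' @param law Blocking law name (see [blocking_laws()]).
#' @param j0 Initial flux (L h^-1 m^-2).
#' @param eps Rate constant; `NULL` picks the value that halves the flux
#'   over `duration_h`.
#' @param duration_h Run length (h).
#' @param interval_min Sampling interval (min).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @return A tibble with `time_h` and `flux`; the generating parameters are
#'   in `attr(, "true_params")`.
#' @export
gen_flux_series <- function(law = hermia_laws, j0 = 600, eps = NULL,
                            duration_h = 2, interval_min = 2,
                            noise_cv = 0.02, seed = 1L) {
  law <- match.arg(law)
  stopifnot(j0 > 0, duration_h > 0, interval_min > 0, noise_cv >= 0)
  if (is.null(eps)) eps <- eps_for_halving(law, j0, duration_h)
  times <- seq(0, duration_h, by = interval_min / 60)
  clean <- simulate_decay(law, j0, eps, times)
  out <- clean
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_seed(seed, rlnorm(nrow(out), -sdlog^2 / 2, sdlog))
    noise[1] <- 1  # first point is J0 exactly
    out$flux <- out$flux * noise
  }
  attr(out, "true_params") <- list(law = law, j0 = j0, eps = eps,
                                   noise_cv = noise_cv, seed = seed)
  out
}

# rate constant giving J(duration) = J0/2 under each law
eps_for_halving <- function(law, j0, duration_h) {
  switch(law,
    complete = log(2) / duration_h,
    standard = (sqrt(2) - 1) * j0^(-0.5) / duration_h,
    intermediate = 1 / (j0 * duration_h),
    cake = 3 * j0^(-2) / duration_h
  )
}

#' Construct a permeance staircase with a requested resistance partition
#'
#' Inverts the resistance-in-series identities: given the clean-membrane
#' permeance `lp0` and the target shares of `R_M`, `R_C`, `R_R` and `R_I` in
#' the total resistance, builds `lp1`-`lp3` so that
#' [resistance_partition()] recovers the shares exactly. Shares may also be
#' given as three values (`R_M`, `R_C`, `R_F`), in which case `R_F` is split
#' evenly between its reversible and irreversible parts.
#'
#' @param shares Named numeric vector, positive for `r_m`, summing to 1:
#'   either `c(r_m=, r_c=, r_r=, r_i=)` or `c(r_m=, r_c=, r_f=)`.
#' @param lp0 Clean-membrane permeance (m Pa^-1 s^-1).
#' @param mu_w Water viscosity (Pa s).
#' @return A [permeance_set()].
#' @examples
#' p <- gen_permeances(c(r_m = 0.1, r_c = 0.7, r_f = 0.2))
#' dominant_resistance(resistance_partition(p))
#' @export
gen_permeances <- function(shares, lp0 = 1e-9, mu_w = 1.0e-3) {
  if (length(shares) == 3 && "r_f" %in% names(shares)) {
    shares <- c(shares[c("r_m", "r_c")],
                r_r = unname(shares[["r_f"]]) / 2,
                r_i = unname(shares[["r_f"]]) / 2)
  }
  req <- c("r_m", "r_c", "r_r", "r_i")
  if (!all(req %in% names(shares))) {
    abort("shares must name r_m, r_c and either r_f or both r_r and r_i",
          class = "cocoflux_tea_error")
  }
  shares <- shares[req]
  if (any(shares < 0) || shares[["r_m"]] <= 0 ||
      abs(sum(shares) - 1) > 1e-9) {
    abort("shares must be non-negative (r_m positive) and sum to 1",
          class = "cocoflux_infeasible_shares")
  }
  r_t <- (1 / (mu_w * lp0)) / shares[["r_m"]]
  inv1 <- mu_w * r_t                       # 1/lp1
  inv2 <- inv1 - mu_w * shares[["r_c"]] * r_t
  inv3 <- inv2 - mu_w * shares[["r_r"]] * r_t
  if (min(inv1, inv2, inv3) <= 0) {
    abort("infeasible shares: implied permeance not positive",
          class = "cocoflux_infeasible_shares")
  }
  suppressWarnings(
    permeance_set(lp0, 1 / inv1, 1 / inv2, 1 / inv3, mu_w = mu_w)
  )
}
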