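#' Basic crossflow-filtration bookkeeping
#'
#' `permeate_flux()` is permeate volume over membrane area and time,
#' `vrr()` the volumetric retention ratio (feed over retentate volume;
#' VRR = 1 is total-recycle operation), `transmission()` and `rejection()`
#' the percentage solute passage and retention, and `flux_decline_pct()` the
#' in-run relative flux decline `100 * (1 - J_end / J0)` (a different
#' quantity from the permeance-based fouling index of
#' [resistance_partition()]).
#'
#' @param volume_l Permeate volume (L).
#' @param time_h Collection interval (h).
#' @param area_m2 Membrane area (m^2).
#' @param feed_l,retentate_l Feed and retentate volumes (L).
#' @param c_p,c_a Permeate and feed solute concentrations (mg/L).
#' @param j0,j_end Initial and final permeate flux (same units).
#' @return Numeric: flux in L h^-1 m^-2, dimensionless VRR, or percentages.
#' @examples
#' permeate_flux(1, 0.5, 0.2)  # 10 L/h/m2
#' transmission(80, 100) + rejection(80, 100)  # 100
#' @export
permeate_flux <- function(volume_l, time_h, area_m2) {
  if (any(time_h <= 0) || any(area_m2 <= 0)) {
    abort("time and area must be positive", class = "cocoflux_unit_error")
  }
  volume_l / (time_h * area_m2)
}

#' @rdname permeate_flux
#' @export
vrr <- function(feed_l, retentate_l) {
  if (any(retentate_l <= 0)) {
    abort("retentate volume must be positive", class = "cocoflux_unit_error")
  }
  feed_l / retentate_l
}

#' @rdname permeate_flux
#' @export
transmission <- function(c_p, c_a) {
  if (any(c_a <= 0)) abort("feed concentration must be positive",
                           class = "cocoflux_unit_error")
  100 * c_p / c_a
}

#' @rdname permeate_flux
#' @export
rejection <- function(c_p, c_a) {
  100 - transmission(c_p, c_a)
}

#' @rdname permeate_flux
#' @export
flux_decline_pct <- function(j0, j_end) {
  if (any(j0 <= 0)) abort("initial flux must be positive",
                          class = "cocoflux_unit_error")
  100 * (1 - j_end / j0)
}

#' Hydraulic permeance from a clean-water flux measurement
#'
#' `Lp = J_w / dP` with the flux converted from L h^-1 m^-2 to m s^-1 and
#' the transmembrane pressure from kPa to Pa, so the permeance is in
#' m Pa^-1 s^-1.
#'
#' @param jw_lhm2 Clean-water flux (L h^-1 m^-2).
#' @param dp_kpa Transmembrane pressure (kPa).
#' @return Permeance (m Pa^-1 s^-1).
#' @export
permeance <- function(jw_lhm2, dp_kpa) {
  if (any(dp_kpa <= 0)) abort("transmembrane pressure must be positive",
                              class = "cocoflux_unit_error")
  (jw_lhm2 * LHM2_TO_MS) / (dp_kpa * 1000)
}

#' Assemble the four-stage permeance set of a filtration run
#'
#' The four clean-water permeances bracketing a run: `lp0` for the clean
#' membrane, `lp1` immediately after processing, `lp2` after physical
#' cleaning and `lp3` after chemical cleaning. Physically one expects
#' `lp0 >= lp3 >= lp2 >= lp1`; a violation is only a warning since mild
#' measurement noise can reorder nearly equal stages.
#'
#' @param lp0,lp1,lp2,lp3 Permeances (m Pa^-1 s^-1).
#' @param mu_w Water viscosity (Pa s), default 1.0e-3.
#' @return A list of class `permeance_set`.
#' @export
permeance_set <- function(lp0, lp1, lp2, lp3, mu_w = 1.0e-3) {
  vals <- c(lp0 = lp0, lp1 = lp1, lp2 = lp2, lp3 = lp3)
  if (any(vals <= 0) || mu_w <= 0) {
    abort("permeances and viscosity must be positive",
          class = "cocoflux_unit_error")
  }
  if (!(lp0 >= lp3 && lp3 >= lp2 && lp2 >= lp1)) {
    warn("permeance staircase violates the expected ordering lp0 >= lp3 >= lp2 >= lp1")
  }
  structure(list(lp0 = lp0, lp1 = lp1, lp2 = lp2, lp3 = lp3, mu_w = mu_w),
            class = "permeance_set")
}

#' Resistance-in-series partition of a permeance set
#'
#' Decomposes the total hydraulic resistance `R_T = 1 / (mu_w * Lp1)` into
#' the clean-membrane resistance `R_M = 1 / (mu_w * Lp0)`, concentration
#' polarization `R_C = (1/Lp1 - 1/Lp2) / mu_w`, reversible fouling
#' `R_R = (1/Lp2 - 1/Lp3) / mu_w` and irreversible fouling
#' `R_I = (1/Lp3 - 1/Lp0) / mu_w`, with `R_F = R_R + R_I` and the fouling
#' index `FI = 100 * (1 - Lp1/Lp0)`. The four components telescope exactly
#' to `R_T`.
#'
#' @param p A [permeance_set()].
#' @return A one-row tibble of class `resistance_partition` with columns
#'   `r_m`, `r_c`, `r_r`, `r_i`, `r_f`, `r_t` (m^-1), `fouling_index` (%)
#'   and `anomalous` (`TRUE` when FI < 0, the flux-enhancement case).
#' @examples
#' p <- permeance_set(1e-9, 2e-10, 4e-10, 8e-10)
#' resistance_partition(p)
#' @export
resistance_partition <- function(p) {
  stopifnot(inherits(p, "permeance_set"))
  mu <- p$mu_w
  r_m <- 1 / (mu * p$lp0)
  r_c <- (1 / p$lp1 - 1 / p$lp2) / mu
  r_r <- (1 / p$lp2 - 1 / p$lp3) / mu
  r_i <- (1 / p$lp3 - 1 / p$lp0) / mu
  r_f <- r_r + r_i
  fi <- 100 * (1 - p$lp1 / p$lp0)
  out <- tibble::new_tibble(
    tibble::tibble(
      r_m = r_m, r_c = r_c, r_r = r_r, r_i = r_i, r_f = r_f,
      r_t = r_m + r_c + r_f,
      fouling_index = fi,
      anomalous = fi < 0
    ),
    class = "resistance_partition"
  )
  if (out$anomalous) warn("negative fouling index: post-run permeance exceeds clean permeance")
  out
}

#' Rank the resistance components
#'
#' Orders the three components of the series identity
#' `R_T = R_M + R_C + R_F` by decreasing magnitude; exact ties keep the
#' fixed order R_C, R_F, R_M (polarization first, as the component that is
#' operationally reversible).
#'
#' @param partition A [resistance_partition()] row.
#' @return A tibble with columns `component`, `resistance` and `share` (of
#'   `R_T`), sorted descending.
#' @export
dominant_resistance <- function(partition) {
  stopifnot(inherits(partition, "resistance_partition"))
  tbl <- tibble::tibble(
    component = c("r_c", "r_f", "r_m"),
    resistance = c(partition$r_c, partition$r_f, partition$r_m)
  )
  tbl$share <- tbl$resistance / partition$r_t
  # stable sort: ties keep the r_c, r_f, r_m listing order
  tbl[order(-tbl$resistance), ]
}
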