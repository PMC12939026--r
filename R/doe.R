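#' Define the two process factors of a face-centered design
#'
#' A face-centered central composite design (FCD) studies each factor at three
#' levels: the low and high bounds of the operating window (coded -1 and +1)
#' and their midpoint (coded 0). The default window is the microfiltration
#' study domain: transmembrane pressure 50-200 kPa and feed temperature
#' 20-40 degrees Celsius.
#'
#' @param pressure Numeric length-2, low and high pressure in kPa.
#' @param temperature Numeric length-2, low and high temperature in degrees C.
#' @return A tibble with one row per factor: `name`, `units`, `low`, `high`,
#'   `center` and `half_range`.
#' @examples
#' fcd_factors()
#' @export
fcd_factors <- function(pressure = c(50, 200), temperature = c(20, 40)) {
  spec <- tibble::tibble(
    name = c("pressure", "temperature"),
    units = c("kPa", "degC"),
    low = c(pressure[1], temperature[1]),
    high = c(pressure[2], temperature[2])
  )
  if (any(!is.finite(spec$low)) || any(!is.finite(spec$high))) {
    abort("factor bounds must be finite", class = "cocoflux_invalid_factor")
  }
  if (any(spec$high <= spec$low)) {
    abort("factor `high` must exceed `low`", class = "cocoflux_invalid_factor")
  }
  spec$center <- (spec$low + spec$high) / 2
  spec$half_range <- (spec$high - spec$low) / 2
  spec
}

factor_row <- function(factors, name) {
  row <- factors[factors$name == name, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown factor `", name, "`"), class = "cocoflux_invalid_factor")
  }
  row
}

#' Convert between actual and coded factor levels
#'
#' Coded levels place the design window on \[-1, +1\]: the low bound maps to
#' -1, the center to 0 and the high bound to +1. `code_level()` and
#' `decode_level()` are exact inverses.
#'
#' @param value Numeric vector of levels (actual units for `code_level()`,
#'   coded units for `decode_level()`).
#' @param factor A single-row factor specification as returned by
#'   [fcd_factors()] (subset to one row).
#' @return Numeric vector of the same length as `value`.
#' @examples
#' f <- fcd_factors()
#' code_level(75, f[f$name == "pressure", ])    # -2/3, the validation setpoint
#' decode_level(-1, f[f$name == "pressure", ])  # 50 kPa
#' @export
code_level <- function(value, factor) {
  stopifnot(is.data.frame(factor), nrow(factor) == 1L)
  if (!is.finite(factor$half_range) || factor$half_range <= 0) {
    abort("factor half-range must be positive", class = "cocoflux_invalid_factor")
  }
  (value - factor$center) / factor$half_range
}

#' @rdname code_level
#' @export
decode_level <- function(value, factor) {
  stopifnot(is.data.frame(factor), nrow(factor) == 1L)
  if (!is.finite(factor$half_range) || factor$half_range <= 0) {
    abort("factor half-range must be positive", class = "cocoflux_invalid_factor")
  }
  factor$center + value * factor$half_range
}

# The 9 unique coded conditions of a 2-factor FCD: 4 corners, 4 face centers,
# 1 center, in run order matching the experiment table (corners, faces, center).
fcd_coded_points <- function() {
  tibble::tibble(
    x1 = c(-1, 1, -1, 1, -1, 1, 0, 0, 0),
    x2 = c(-1, -1, 1, 1, 0, 0, -1, 1, 0),
    is_center = c(rep(FALSE, 8), TRUE)
  )
}

new_fcd <- function(data, factors) {
  out <- tibble::new_tibble(data, class = "fcd_df")
  attr(out, "factors") <- factors
  out
}

#' Build the sample table of a two-factor face-centered design
#'
#' Lays out the 9 unique coded conditions (4 factorial corners, 4 face
#' midpoints, 1 center) and expands them into replicate sample rows following
#' the replication plan: triplicate non-center points and a quintuplicate
#' center, giving 13 runs / 29 samples under the default plan.
#'
#' @param factors Factor specification from [fcd_factors()].
#' @param replicates Named integer vector with elements `non_center` and
#'   `center` giving the number of replicate samples per condition.
#' @return An `fcd_df` tibble with columns `run`, `replicate`, coded levels
#'   `x1`, `x2`, actual levels named after the factors, and `is_center`.
#'   Center replicates are numbered as separate runs, as in the experiment
#'   table.
#' @examples
#' d <- build_fcd()
#' nrow(d)                 # 29 samples
#' dplyr::n_distinct(d$run)  # 13 runs
#' @export
build_fcd <- function(factors = fcd_factors(),
                      replicates = c(non_center = 3L, center = 5L)) {
  pts <- fcd_coded_points()
  n_nc <- as.integer(replicates[["non_center"]])
  n_c <- as.integer(replicates[["center"]])
  stopifnot(n_nc >= 1L, n_c >= 1L)

  nc <- pts[!pts$is_center, ]
  nc$run <- seq_len(nrow(nc))
  nc <- tidyr::uncount(nc, weights = n_nc, .id = "replicate")

  ctr <- pts[pts$is_center, ][rep(1L, n_c), ]
  ctr$run <- nrow(pts) - 1L + seq_len(n_c)
  ctr$replicate <- 1L

  out <- dplyr::bind_rows(nc, ctr)
  p <- factor_row(factors, "pressure")
  t <- factor_row(factors, "temperature")
  out$pressure <- decode_level(out$x1, p)
  out$temperature <- decode_level(out$x2, t)
  out <- dplyr::select(
    out, "run", "replicate", "pressure", "temperature",
    "x1", "x2", "is_center"
  )
  new_fcd(out, factors)
}

#' The microfiltration experiment table shipped with the package
#'
#' The packaged dataset behind every worked example: permeate flux
#' (L h^-1 m^-2) and fouling index (%) measured over the 50-200 kPa x
#' 20-40 degC face-centered design. The five center-point samples are
#' individual measurements; for the eight non-center conditions only the
#' condition mean and standard deviation were reported, so the mean is stored
#' with replicate multiplicity 3. This reproduces every condition sum exactly,
#' hence all least-squares coefficients; the reported standard deviations are
#' kept as metadata in `attr(, "response_sd")`.
#'
#' @return An `fcd_df` tibble with 29 sample rows and response columns
#'   `flux` and `fouling_index`.
#' @examples
#' d <- coconut_design()
#' mean(d$flux[d$is_center])  # 656.11
#' @export
coconut_design <- function() {
  d <- build_fcd()
  flux_means <- c(324.35, 302.26, 471.78, 527.11, 608.78, 498.88, 469.00, 575.90)
  fi_means <- c(84.55, 93.28, 82.92, 94.66, 78.21, 92.61, 88.98, 89.78)
  flux_center <- c(656.47, 678.96, 639.43, 645.50, 660.21)
  fi_center <- c(84.10, 86.42, 84.06, 85.56, 85.80)
  d$flux <- ifelse(d$is_center, flux_center[pmax(d$run - 8L, 1L)], flux_means[pmin(d$run, 8L)])
  d$fouling_index <- ifelse(d$is_center, fi_center[pmax(d$run - 8L, 1L)], fi_means[pmin(d$run, 8L)])
  attr(d, "response_sd") <- tibble::tibble(
    run = 1:9,
    flux = c(6.97, 9.45, 11.53, 14.07, 16.77, 3.98, 12.34, 3.09, 15.25),
    fouling_index = c(1.35, 0.86, 1.04, 1.21, 0.67, 0.66, 1.08, 0.80, 1.06)
  )
  d
}

fcd_response_names <- function(data) {
  setdiff(
    names(data),
    c("run", "replicate", "pressure", "temperature", "x1", "x2", "is_center")
  )
}

#' Read or write a design sample table as CSV
#'
#' The CSV dialect is comma-separated with `.` decimals, a header row and
#' UTF-8 encoding. Required columns: `run`, `replicate`, the factor columns
#' in actual units (`pressure`, `temperature`) and at least one response
#' column. Coded levels are recomputed from the factor specification on read,
#' so a save/load round trip is lossless.
#'
#' @param path File path.
#' @param factors Factor specification used to recode the actual levels.
#' @param data An `fcd_df` tibble (for writing).
#' @return `read_fcd_csv()` returns an `fcd_df` tibble; `write_fcd_csv()`
#'   returns `data` invisibly.
#' @export
read_fcd_csv <- function(path, factors = fcd_factors()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("run", "replicate", "pressure", "temperature")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("design CSV is missing column(s): ", paste(missing, collapse = ", ")),
      class = "cocoflux_parse_error"
    )
  }
  responses <- setdiff(names(raw), c(required, "x1", "x2", "is_center"))
  if (nrow(raw) == 0) {
    abort("design CSV contains no sample rows", class = "cocoflux_parse_error")
  }
  for (col in c(required, responses)) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))[1]
      abort(
        paste0("non-numeric value in column `", col, "` (row ", bad, ")"),
        class = "cocoflux_parse_error"
      )
    }
  }
  p <- factor_row(factors, "pressure")
  t <- factor_row(factors, "temperature")
  raw$x1 <- code_level(raw$pressure, p)
  raw$x2 <- code_level(raw$temperature, t)
  raw$is_center <- raw$x1 == 0 & raw$x2 == 0
  bad_runs <- raw |>
    dplyr::summarise(
      n_lev = dplyr::n_distinct(.data$pressure, .data$temperature),
      .by = "run"
    ) |>
    dplyr::filter(.data$n_lev > 1)
  if (nrow(bad_runs) > 0) {
    abort(
      paste0(
        "inconsistent factor levels within run(s): ",
        paste(bad_runs$run, collapse = ", ")
      ),
      class = "cocoflux_parse_error"
    )
  }
  out <- dplyr::select(
    raw, "run", "replicate", "pressure", "temperature",
    "x1", "x2", "is_center", dplyr::all_of(responses)
  )
  new_fcd(out, factors)
}

#' @rdname read_fcd_csv
#' @export
write_fcd_csv <- function(data, path) {
  cols <- c("run", "replicate", "pressure", "temperature", fcd_response_names(data))
  readr::write_csv(dplyr::select(as.data.frame(data), dplyr::all_of(cols)), path)
  invisible(data)
}

#' Serialize a design dataset to and from JSON
#'
#' @param data An `fcd_df` tibble.
#' @param path File path.
#' @param factors Factor specification used on read.
#' @return `write_fcd_json()` returns `data` invisibly; `read_fcd_json()`
#'   returns an `fcd_df` tibble.
#' @export
write_fcd_json <- function(data, path) {
  payload <- list(
    factors = attr(data, "factors"),
    samples = dplyr::select(
      as.data.frame(data),
      "run", "replicate", "pressure", "temperature",
      dplyr::all_of(fcd_response_names(data))
    )
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(data)
}

#' @rdname write_fcd_json
#' @export
read_fcd_json <- function(path, factors = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fac <- if (is.null(factors)) tibble::as_tibble(payload$factors) else factors
  samples <- tibble::as_tibble(payload$samples)
  p <- factor_row(fac, "pressure")
  t <- factor_row(fac, "temperature")
  samples$x1 <- code_level(samples$pressure, p)
  samples$x2 <- code_level(samples$temperature, t)
  samples$is_center <- samples$x1 == 0 & samples$x2 == 0
  new_fcd(samples, fac)
}

#' Validate a design sample table
#'
#' Checks the structural invariants a face-centered design table must satisfy
#' before model fitting: consistent coded/actual levels, the 9-condition FCD
#' geometry, positive replicate counts and finite, physically sensible
#' responses (fluxes non-negative, fouling index within 0-100).
#'
#' @param data An `fcd_df` tibble.
#' @return A tibble of diagnostics with columns `check`, `ok` and `detail`.
#' @export
validate_design <- function(data) {
  factors <- attr(data, "factors")
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, ok = ok, detail = detail
    )
  }
  p <- factor_row(factors, "pressure")
  t <- factor_row(factors, "temperature")
  coded_ok <- max(abs(code_level(data$pressure, p) - data$x1),
                  abs(code_level(data$temperature, t) - data$x2)) < 1e-10
  add("coded/actual consistency", coded_ok)
  n_cond <- dplyr::n_distinct(data$x1, data$x2)
  add("9 unique coded conditions", n_cond == 9L, paste0("found ", n_cond))
  add("replicate count >= 1", all(table(data$run) >= 1))
  for (resp in fcd_response_names(data)) {
    vals <- data[[resp]]
    finite <- all(is.finite(vals))
    add(paste0("finite `", resp, "`"), finite)
    if (resp == "fouling_index" && finite) {
      add("fouling index in [0, 100]", all(vals >= 0 & vals <= 100))
    }
    if (resp == "flux" && finite) {
      add("non-negative flux", all(vals >= 0))
    }
  }
  dplyr::bind_rows(checks)
}
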