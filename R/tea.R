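#' Equipment purchase cost by capacity scaling
#'
#' The six-tenths rule `EPC = C0 * (Q / Q0)^a`: the cost of a reference unit
#' of capacity `Q0` scaled to the target capacity `Q` with exponent `a`
#' (default 0.6).
#'
#' @param cost0 Reference cost (US$).
#' @param capacity Target capacity.
#' @param capacity0 Reference capacity (same units as `capacity`).
#' @param exponent Scale exponent in (0, 1].
#' @return Scaled cost (US$).
#' @examples
#' epc_scale(10000, 2, 1)  # 15157.17
#' @export
epc_scale <- function(cost0, capacity, capacity0, exponent = 0.6) {
  if (any(capacity <= 0) || any(capacity0 <= 0) || any(cost0 <= 0)) {
    abort("costs and capacities must be positive", class = "cocoflux_tea_error")
  }
  stopifnot(exponent > 0, exponent <= 1)
  cost0 * (capacity / capacity0)^exponent
}

#' Green-coconut mass composition
#'
#' Mass fractions of the whole fruit: husk 33.6%, shell 16.5%, albumen
#' (pulp) 30.4% and coconut water 19.5%.
#'
#' @param husk,shell,albumen,water Mass fractions, must be non-negative and
#'   sum to 1 within 1e-6.
#' @return A named numeric vector of fractions.
#' @export
coconut_composition <- function(husk = 0.336, shell = 0.165,
                                albumen = 0.304, water = 0.195) {
  comp <- c(husk = husk, shell = shell, albumen = albumen, water = water)
  if (any(comp < 0) || abs(sum(comp) - 1) > 1e-6) {
    abort("composition fractions must be non-negative and sum to 1",
          class = "cocoflux_tea_error")
  }
  comp
}

#' Plant operating basis
#'
#' Default basis: 1 t of green coconut per batch, 1346 batches over 300
#' operating days per year, and a conservative design permeate flux of
#' 300 L h^-1 m^-2 for membrane sizing.
#'
#' @param batch_mass_kg Coconut mass per batch (kg).
#' @param batches_per_year Annual batch count.
#' @param operating_days Operating days per year.
#' @param design_flux Design permeate flux (L h^-1 m^-2).
#' @return A list of class `plant_basis`.
#' @export
plant_basis <- function(batch_mass_kg = 1000, batches_per_year = 1346,
                        operating_days = 300, design_flux = 300) {
  stopifnot(batch_mass_kg > 0, batches_per_year > 0, operating_days > 0,
            design_flux > 0)
  structure(
    list(batch_mass_kg = batch_mass_kg,
         batches_per_year = as.integer(batches_per_year),
         operating_days = as.integer(operating_days),
         design_flux = design_flux),
    class = "plant_basis"
  )
}

#' Annual mass balance of the biorefinery feed
#'
#' Annual feed is batch mass times batches per year; each stream is the feed
#' times its composition fraction.
#'
#' @param basis A [plant_basis()].
#' @param composition A [coconut_composition()].
#' @return A tibble with `stream`, `fraction` and `mass_kg_yr`, including a
#'   `feed` row with fraction 1.
#' @examples
#' mass_balance()  # 1,346,000 kg/yr feed
#' @export
mass_balance <- function(basis = plant_basis(),
                         composition = coconut_composition()) {
  feed <- basis$batch_mass_kg * basis$batches_per_year
  tibble::tibble(
    stream = c("feed", names(composition)),
    fraction = c(1, unname(composition)),
    mass_kg_yr = c(feed, unname(feed * composition))
  )
}

#' Product and revenue model
#'
#' Baseline factory-gate prices: US$16.80 per case of microfiltered coconut
#' water (10 x 1 L) and US$11.20 per case of pulp (10 x 0.4 kg). Baseline
#' annual output is 25,742.1 cases of water and 103,226.25 cases of pulp.
#' (The water case count is reconstructed from the reported water revenue of
#' US$432,468 at US$16.80/case; the originally printed figure "2574.21" is a
#' decimal-point slip and is preserved in `attr(, "note")`.)
#'
#' @param water_cases,pulp_cases Annual case counts.
#' @param water_price,pulp_price Prices (US$/case).
#' @return A tibble with one row per product: `product`, `cases_per_year`,
#'   `price_per_case`.
#' @export
revenue_model <- function(water_cases = 25742.1, pulp_cases = 103226.25,
                          water_price = 16.80, pulp_price = 11.20) {
  stopifnot(water_cases >= 0, pulp_cases >= 0,
            water_price >= 0, pulp_price >= 0)
  out <- tibble::tibble(
    product = c("coconut_water", "pulp"),
    cases_per_year = c(water_cases, pulp_cases),
    price_per_case = c(water_price, pulp_price)
  )
  attr(out, "note") <-
    "water cases implied by revenue/price; source table printed 2574.21"
  out
}

#' Annual revenue per product
#'
#' @param model A [revenue_model()] tibble.
#' @return The input with a `revenue` column added; the total is in
#'   `attr(, "total")` and also available as `sum(out$revenue)`.
#' @examples
#' rev <- annual_revenue()
#' sum(rev$revenue)  # ~1,588,601
#' @export
annual_revenue <- function(model = revenue_model()) {
  model$revenue <- model$cases_per_year * model$price_per_case
  attr(model, "total") <- sum(model$revenue)
  model
}

#' Baseline capital and operating cost line items
#'
#' The screening-level cost breakdown of the biorefinery model, shipped as a
#' fixture: CAPEX US$959,000 and OPEX US$1,178,000 per year, itemized.
#' These line items originate from a proprietary flowsheet simulator and are
#' inputs to the cash-flow model, not quantities this package recomputes.
#'
#' @return A list with tibbles `capex` and `opex` (`component`, `cost`).
#' @export
baseline_costs <- function() {
  capex <- tibble::tibble(
    component = c(
      "Equipment Purchase Cost", "Installation", "Process Piping",
      "Instrumentation", "Insulation", "Electrical", "Buildings",
      "Yard Improvement", "Auxiliary Facilities", "Engineering",
      "Construction", "Contractor's Fee", "Contingency", "Working Capital",
      "Startup Cost"
    ),
    cost = c(135000, 57000, 47000, 54000, 4000, 14000, 61000, 20000, 54000,
             112000, 156000, 36000, 71000, 97000, 41000)
  )
  opex <- tibble::tibble(
    component = c(
      "Raw Materials", "Labor-Dependent", "Facility-Dependent", "Consumables",
      "Waste Treatment/Disposal", "Utilities", "Transportation"
    ),
    cost = c(664000, 245000, 155000, 1000, 57000, 1000, 55000)
  )
  list(capex = capex, opex = opex)
}

#' Assemble a biorefinery cash-flow scenario
#'
#' Bundles the plant basis, composition, revenue model, cost totals and
#' financial rates. Defaults are the baseline case: CAPEX US$959,000, OPEX
#' US$1,178,000/yr, 13% discount rate, 4% inflation, 20 project years, a
#' 30-month construction period and a 4-month start-up.
#'
#' @param basis A [plant_basis()].
#' @param composition A [coconut_composition()].
#' @param revenue A [revenue_model()] tibble.
#' @param capex_total,opex_annual Cost totals (US$); default the sums of
#'   [baseline_costs()].
#' @param discount_rate,inflation Annual rates in \[0, 1).
#' @param project_years Operating life (years).
#' @param construction_months,startup_months Pre-operation timing.
#' @return A list of class `biorefinery_scenario`.
#' @export
biorefinery_scenario <- function(basis = plant_basis(),
                                 composition = coconut_composition(),
                                 revenue = revenue_model(),
                                 capex_total = sum(baseline_costs()$capex$cost),
                                 opex_annual = sum(baseline_costs()$opex$cost),
                                 discount_rate = 0.13, inflation = 0.04,
                                 project_years = 20L,
                                 construction_months = 30,
                                 startup_months = 4) {
  stopifnot(discount_rate >= 0, discount_rate < 1,
            inflation >= 0, inflation < 1, project_years > 0)
  structure(
    list(
      basis = basis, composition = composition, revenue = revenue,
      capex_total = capex_total, opex_annual = opex_annual,
      discount_rate = discount_rate, inflation = inflation,
      project_years = as.integer(project_years),
      construction_months = construction_months,
      startup_months = startup_months
    ),
    class = "biorefinery_scenario"
  )
}

#' Yearly nominal net cash flows of a scenario
#'
#' CAPEX is spread over the construction years (12-month slices, the final
#' partial year pro-rated) ending at year 0; operations start after the
#' start-up period, so the first operating year carries
#' `(12 - startup_months) / 12` of a full year's revenue and operating cost.
#' Revenue and OPEX are inflated at the scenario's inflation rate from the
#' first operating year. Flows are nominal; discounting happens in [npv()].
#'
#' @param scenario A [biorefinery_scenario()].
#' @return A tibble with `year` (0 at operations start, negative during
#'   construction), `capex`, `revenue`, `opex` and `net`.
#' @export
build_cashflows <- function(scenario) {
  stopifnot(inherits(scenario, "biorefinery_scenario"))
  cm <- scenario$construction_months
  if (cm < 0 || scenario$startup_months < 0 ||
      scenario$startup_months > 12) {
    abort("inconsistent construction/start-up periods",
          class = "cocoflux_tea_error")
  }
  n_cy <- max(1L, ceiling(cm / 12))
  month_slices <- rep(12, n_cy)
  month_slices[n_cy] <- cm - 12 * (n_cy - 1)
  capex_years <- tibble::tibble(
    year = seq(-(n_cy - 1L), 0L),
    capex = scenario$capex_total * month_slices / cm,
    revenue = 0, opex = 0
  )
  rev0 <- sum(annual_revenue(scenario$revenue)$revenue)
  frac1 <- (12 - scenario$startup_months) / 12
  op_years <- tibble::tibble(
    year = seq_len(scenario$project_years),
    capex = 0,
    revenue = rev0 * (1 + scenario$inflation)^(seq_len(scenario$project_years) - 1),
    opex = scenario$opex_annual *
      (1 + scenario$inflation)^(seq_len(scenario$project_years) - 1)
  )
  op_years$revenue[1] <- op_years$revenue[1] * frac1
  op_years$opex[1] <- op_years$opex[1] * frac1
  flows <- dplyr::bind_rows(capex_years, op_years)
  flows$net <- flows$revenue - flows$opex - flows$capex
  flows
}

#' Discounted-cash-flow indicators
#'
#' `npv()` discounts each flow by `(1 + rate)^year`; `irr()` finds the rate
#' that zeroes the NPV by bracketed root-finding; `payback()` is the first
#' time the cumulative undiscounted flow reaches zero, interpolated linearly
#' within the year.
#'
#' @param flows Numeric vector of net flows, or the tibble from
#'   [build_cashflows()] (its `net` and `year` columns are used).
#' @param rate Discount rate (fraction).
#' @param years Optional numeric vector of flow times; defaults to
#'   `0, 1, 2, ...` for a bare numeric `flows`.
#' @return `npv()`: US$. `irr()`: the internal rate of return as a fraction
#'   (0.10 is 10%); errors when the flows have no sign change. `payback()`:
#'   years from the first flow, `Inf` if never recovered.
#' @examples
#' npv(c(-100, 110), 0.10)  # 0
#' irr(c(-100, 110))        # 0.10
#' payback(c(-100, 60, 60)) # 1.667
#' @export
npv <- function(flows, rate, years = NULL) {
  f <- flow_parts(flows, years)
  sum(f$net / (1 + rate)^f$year)
}

flow_parts <- function(flows, years = NULL) {
  if (is.data.frame(flows)) {
    list(net = flows$net, year = flows$year)
  } else {
    list(net = flows, year = years %||% (seq_along(flows) - 1))
  }
}

#' @rdname npv
#' @export
irr <- function(flows, years = NULL) {
  f <- flow_parts(flows, years)
  if (all(f$net >= 0) || all(f$net <= 0)) {
    abort("IRR undefined: cash flows never change sign",
          class = "cocoflux_tea_error")
  }
  g <- function(r) npv(f$net, r, years = f$year)
  uniroot(g, lower = -0.9999, upper = 10, tol = 1e-10)$root
}

#' @rdname npv
#' @export
payback <- function(flows, years = NULL) {
  f <- flow_parts(flows, years)
  cum <- cumsum(f$net)
  k <- which(cum >= 0)[1]
  if (is.na(k)) return(Inf)
  if (k == 1) return(f$year[1] - f$year[1])
  # linear interpolation inside year k
  prev <- cum[k - 1]
  frac <- -prev / f$net[k]
  (f$year[k - 1] + frac * (f$year[k] - f$year[k - 1])) - f$year[1]
}

#' Evaluate a scenario's techno-economic indicators
#'
#' Builds the cash flows and reports NPV at the scenario discount rate, IRR,
#' payback (measured from the start of construction) and the gross margin
#' `(revenue - opex) / revenue` on the un-inflated annual basis.
#'
#' @param scenario A [biorefinery_scenario()].
#' @return A list of class `tea_result` with the `cashflows` tibble and the
#'   scalar indicators.
#' @export
tea_run <- function(scenario = biorefinery_scenario()) {
  flows <- build_cashflows(scenario)
  rev0 <- sum(annual_revenue(scenario$revenue)$revenue)
  structure(
    list(
      scenario = scenario,
      cashflows = flows,
      npv = npv(flows, scenario$discount_rate),
      irr = tryCatch(irr(flows), error = function(e) NA_real_),
      payback_years = payback(flows),
      gross_margin = (rev0 - scenario$opex_annual) / rev0
    ),
    class = "tea_result"
  )
}

#' @export
print.tea_result <- function(x, ...) {
  cat("Techno-economic indicators (screening cash-flow model)\n")
  cat(sprintf("  NPV  : US$ %0.0f at %.0f%% discount\n", x$npv,
              100 * x$scenario$discount_rate))
  cat(sprintf("  IRR  : %.2f%%\n", 100 * x$irr))
  cat(sprintf("  payback : %.2f years (from construction start)\n",
              x$payback_years))
  cat(sprintf("  gross margin : %.2f%%\n", 100 * x$gross_margin))
  invisible(x)
}

#' @method glance tea_result
#' @export
glance.tea_result <- function(x, ...) {
  tibble::tibble(
    npv = x$npv,
    irr_pct = 100 * x$irr,
    payback_years = x$payback_years,
    gross_margin_pct = 100 * x$gross_margin
  )
}

#' Selling-price sensitivity analysis
#'
#' Scales both product prices by each multiplier, recomputes the cash flows
#' and reports the indicators per scenario. Revenue scales linearly with
#' price, so NPV and IRR are increasing in the multiplier and payback
#' decreasing.
#'
#' @param scenario Base [biorefinery_scenario()].
#' @param multipliers Price multipliers (default 0.8, 0.9, 1, 1.1, 1.2 — the
#'   +/-10% and +/-20% scenarios).
#' @return A tibble with one row per multiplier: the scaled prices, annual
#'   revenue, `npv`, `irr_pct` and `payback_years`.
#' @export
price_sensitivity <- function(scenario = biorefinery_scenario(),
                              multipliers = c(0.8, 0.9, 1.0, 1.1, 1.2)) {
  purrr::map_dfr(multipliers, function(m) {
    sc <- scenario
    sc$revenue$price_per_case <- scenario$revenue$price_per_case * m
    res <- tea_run(sc)
    tibble::tibble(
      multiplier = m,
      water_price = sc$revenue$price_per_case[sc$revenue$product == "coconut_water"],
      pulp_price = sc$revenue$price_per_case[sc$revenue$product == "pulp"],
      revenue = sum(annual_revenue(sc$revenue)$revenue),
      npv = res$npv,
      irr_pct = 100 * res$irr,
      payback_years = res$payback_years
    )
  })
}
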