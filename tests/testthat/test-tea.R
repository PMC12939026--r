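test_that("cost scaling follows the six-tenths rule", {
  expect_equal(epc_scale(5000, 7, 7), 5000)              # identity at Q = Q0
  expect_equal(epc_scale(10000, 2, 1), 15157.17, tolerance = 1e-6)
  expect_equal(epc_scale(10000, 3, 1, exponent = 1), 30000)  # linear at a = 1
  expect_error(epc_scale(10000, -1, 1), class = "cocoflux_tea_error")
})

test_that("the coconut composition closes its mass balance", {
  comp <- coconut_composition()
  expect_equal(sum(comp), 1)
  expect_error(coconut_composition(husk = 0.5), class = "cocoflux_tea_error")
})

test_that("the annual mass balance reproduces the plant demand figures", {
  mb <- mass_balance()
  expect_equal(mb$mass_kg_yr[mb$stream == "feed"], 1346000)
  expect_equal(mb$mass_kg_yr[mb$stream == "water"], 262470)
  expect_equal(sum(mb$mass_kg_yr[mb$stream != "feed"]),
               mb$mass_kg_yr[mb$stream == "feed"])
  zero <- mass_balance(plant_basis(batches_per_year = 1))
  expect_equal(zero$mass_kg_yr[zero$stream == "feed"], 1000)
})

test_that("annual revenue reproduces the reported product and total figures", {
  rev <- annual_revenue()
  pulp <- rev$revenue[rev$product == "pulp"]
  water <- rev$revenue[rev$product == "coconut_water"]
  expect_equal(pulp, 1156134)               # 103,226.25 cases at 11.20
  expect_equal(water, 432468, tolerance = 1)
  expect_equal(sum(rev$revenue), 1588602, tolerance = 1)
  none <- annual_revenue(revenue_model(water_cases = 0, pulp_cases = 0))
  expect_equal(sum(none$revenue), 0)
})

test_that("NPV, IRR and payback satisfy their closed-form identities", {
  expect_equal(npv(c(-100, 110), 0.10), 0, tolerance = 1e-12)
  expect_equal(irr(c(-100, 110)), 0.10, tolerance = 1e-9)
  expect_equal(payback(c(-100, 60, 60)), 5 / 3, tolerance = 1e-9)
  expect_equal(payback(c(-100, 100)), 1)
  expect_equal(payback(c(-100, 10)), Inf)
  expect_error(irr(c(-10, -20)), class = "cocoflux_tea_error")
  # root consistency on the baseline scenario
  res <- tea_run()
  expect_equal(npv(res$cashflows, res$irr), 0, tolerance = 1e-6 * abs(res$npv))
  # NPV strictly decreasing in the rate for conventional flows
  rates <- seq(0.02, 0.40, by = 0.02)
  npvs <- sapply(rates, function(r) npv(res$cashflows, r))
  expect_true(all(diff(npvs) < 0))
})

test_that("cash-flow timing spreads CAPEX and pro-rates the start-up year", {
  sc <- biorefinery_scenario()
  cf <- build_cashflows(sc)
  expect_equal(sum(cf$capex), sc$capex_total)
  expect_equal(cf$year[cf$capex > 0], c(-2, -1, 0))
  expect_equal(cf$capex[cf$year == 0] / sc$capex_total, 6 / 30)
  rev0 <- sum(annual_revenue(sc$revenue)$revenue)
  expect_equal(cf$revenue[cf$year == 1], rev0 * 8 / 12)
  expect_equal(cf$revenue[cf$year == 2], rev0 * 1.04)
  expect_error(
    build_cashflows(biorefinery_scenario(startup_months = 18)),
    class = "cocoflux_tea_error"
  )
})

test_that("degenerate scenarios pin the NPV sign", {
  # no revenue: strictly negative NPV
  sc0 <- biorefinery_scenario(revenue = revenue_model(water_cases = 0,
                                                      pulp_cases = 0))
  expect_lt(tea_run(sc0)$npv, 0)
  # revenue equal to opex and no capex: NPV exactly 0
  flows <- rep(0, 10)
  expect_equal(npv(flows, 0.13), 0)
  # the baseline is profitable
  expect_gt(tea_run()$npv, 0)
})

test_that("the baseline gross margin matches the recomputed cost structure", {
  res <- tea_run()
  expect_equal(res$gross_margin, (1588601.28 - 1178000) / 1588601.28,
               tolerance = 1e-6)
  expect_equal(100 * res$gross_margin, 25.85, tolerance = 0.01)
  costs <- baseline_costs()
  expect_equal(sum(costs$capex$cost), 959000)
  expect_equal(sum(costs$opex$cost), 1178000)
})

test_that("price sensitivity reproduces the scenario prices and orderings", {
  sens <- price_sensitivity()
  expect_equal(sens$water_price, c(13.44, 15.12, 16.80, 18.48, 20.16))
  expect_equal(sens$pulp_price, c(8.96, 10.08, 11.20, 12.32, 13.44))
  # monotone: higher multiplier raises NPV and IRR, lowers payback
  expect_true(all(diff(sens$npv) > 0))
  expect_true(all(diff(sens$irr_pct) > 0))
  expect_true(all(diff(sens$payback_years) < 0))
  # the -20% scenario loses money
  expect_lt(sens$npv[sens$multiplier == 0.8], 0)
  # multiplier 1 leaves the base case untouched
  base <- tea_run()
  expect_equal(sens$npv[sens$multiplier == 1], base$npv)
  expect_equal(sens$irr_pct[sens$multiplier == 1], 100 * base$irr)
})
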