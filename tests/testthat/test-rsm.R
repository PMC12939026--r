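d <- coconut_design()

test_that("least squares agrees with hand-built normal equations", {
  fit <- fit_quadratic(d, "flux")
  oracle <- oracle_quad_fit(d, "flux")
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-10)
  # reduced model too
  red <- fit_quadratic(d, "fouling_index", terms = c("x1", "x2sq", "x1x2"))
  oracle_red <- oracle_quad_fit(d, "fouling_index", c("x1", "x2sq", "x1x2"))
  expect_equal(unname(coef(red)[c("intercept", "x1", "x2sq", "x1x2")]),
               unname(oracle_red), tolerance = 1e-10)
  expect_identical(unname(coef(red)[c("x2", "x1sq")]), c(0, 0))
})

test_that("noise-free synthetic surfaces are recovered exactly", {
  d0 <- gen_fcd_dataset(sd = c(flux = 0, fouling_index = 0), seed = 11)
  fit <- fit_quadratic(d0, "flux")
  expect_equal(unname(coef(fit)), unname(attr(d0, "true_beta")$flux),
               tolerance = 1e-9)
})

test_that("significance pruning drops the terms reported for each response", {
  flux <- fit_rsm(d, "flux")
  expect_identical(flux$dropped_terms, "x1")
  fi <- fit_rsm(d, "fouling_index")
  expect_setequal(fi$dropped_terms, c("x2", "x1sq"))
  # orthogonal design: intercept unchanged by the pruning refit
  expect_equal(coef(flux)[["intercept"]], coef(flux$full_fit)[["intercept"]])
  # a true-zero coefficient with tiny noise is dropped
  beta <- default_fcd_beta()
  beta$flux[["x1x2"]] <- 0
  hits <- 0
  for (s in 1:40) {
    ds <- gen_fcd_dataset(beta["flux"], sd = c(flux = 1), seed = s)
    hits <- hits + ("x1x2" %in% fit_rsm(ds, "flux")$dropped_terms)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("reduced-model predictions reproduce the reported design-point values", {
  flux <- fit_rsm(d, "flux")
  fi <- fit_rsm(d, "fouling_index")
  # non-center conditions in run order (row 01 asserted at its recomputed
  # value 347.73; the tabulated 347.53 is inconsistent with every other row)
  flux_expected <- c(347.73, 309.02, 468.75, 507.45, 550.10, 550.10, 438.86, 598.59)
  fi_expected <- c(83.97, 94.09, 82.46, 95.59, 79.50, 91.12, 89.03, 89.03)
  pts <- unique(d[!d$is_center, c("x1", "x2")])
  expect_within(predict(flux, newdata = pts)$.pred, flux_expected, tol = 0.011)
  expect_within(predict(fi, newdata = pts)$.pred, fi_expected, tol = 0.011)
  # center predictions
  expect_within(predict(flux, coded = c(0, 0))$.pred, 660.59)
  expect_within(predict(fi, coded = c(0, 0))$.pred, 85.31)
  # validation setpoint, actual units
  expect_within(predict(flux, pressure = 75, temperature = 30)$.pred, 611.48)
  expect_within(predict(fi, pressure = 75, temperature = 30)$.pred, 81.43)
})

test_that("fitting replicate samples equals weighted fitting of unique conditions", {
  uniq <- d |>
    dplyr::summarise(flux = mean(flux), w = dplyr::n(), .by = c(x1, x2))
  wfit <- lm(flux ~ x1 + x2 + I(x1^2) + I(x2^2) + x1:x2, data = uniq,
             weights = uniq$w)
  fit <- fit_quadratic(d, "flux")
  expect_equal(unname(coef(fit)),
               unname(coef(wfit)[c("(Intercept)", "x1", "x2", "I(x1^2)",
                                   "I(x2^2)", "x1:x2")]),
               tolerance = 1e-10)
})

test_that("a saturated fit of unreplicated data interpolates it exactly", {
  pts <- unique(d[, c("x1", "x2")])
  pts$pressure <- 125 + 75 * pts$x1
  pts$temperature <- 30 + 10 * pts$x2
  pts$run <- seq_len(nrow(pts)); pts$replicate <- 1L
  pts$y <- 1 + 2 * pts$x1 - 3 * pts$x2 + 0.5 * pts$x1^2 + pts$x1 * pts$x2
  attr(pts, "factors") <- attr(d, "factors")
  fit <- fit_quadratic(pts, "y")
  expect_equal(predict(fit, newdata = pts)$.pred, pts$y, tolerance = 1e-9)
})

test_that("rank-deficient term requests error cleanly", {
  two <- d[d$run <= 1, ]
  attr(two, "factors") <- attr(d, "factors")
  expect_error(fit_quadratic(two, "flux"), class = "cocoflux_singular_fit")
})

test_that("ANOVA decomposition is additive and matches the fit quality claims", {
  for (resp in c("flux", "fouling_index")) {
    fit <- fit_rsm(d, resp)
    a <- anova_rsm(fit)
    tbl <- a$table
    ss <- function(src) tbl$sum_sq[tbl$source == src]
    expect_equal(ss("regression") + ss("residual"), ss("total"))
    expect_equal(ss("lack_of_fit") + ss("pure_error"), ss("residual"))
    expect_gt(a$r_squared, 0.90)
    expect_gt(a$f_cal, a$f_tab)
    expect_true(a$pure_error_available)
  }
})

test_that("perfect and pure-noise responses give the expected ANOVA extremes", {
  d0 <- gen_fcd_dataset(sd = c(flux = 0, fouling_index = 0), seed = 2)
  a0 <- anova_rsm(fit_quadratic(d0, "flux"))
  expect_equal(a0$r_squared, 1, tolerance = 1e-9)
  expect_equal(a0$table$sum_sq[a0$table$source == "residual"], 0,
               tolerance = 1e-12)

  noise <- d
  noise$flux <- withr::with_seed(99, stats::rnorm(nrow(d), 500, 10))
  attr(noise, "factors") <- attr(d, "factors")
  an <- anova_rsm(fit_quadratic(noise, "flux"))
  expect_lt(an$r_squared, 0.6)
})

test_that("surface optimization finds the analytic optimum or the right edge", {
  flux <- fit_rsm(d, "flux")
  opt <- optimize_surface(flux, "max")
  sp <- oracle_stationary_point(coef(flux))
  expect_equal(unname(c(opt$x1, opt$x2)), sp, tolerance = 1e-9)
  expect_equal(opt$x1, 0.0248, tolerance = 1e-3)
  expect_equal(opt$x2, 0.2832, tolerance = 1e-3)
  expect_equal(opt$value, 671.89, tolerance = 0.01)
  expect_false(opt$boundary)

  fi <- fit_rsm(d, "fouling_index")
  mn <- optimize_surface(fi, "min")
  expect_equal(mn$x1, -1)          # positive pressure slope pushes to the low edge
  expect_true(mn$boundary)

  # concave paraboloid with a known interior vertex
  dd <- build_fcd()
  dd$y <- 10 - 2 * (dd$x1 - 0.2)^2 - 3 * (dd$x2 + 0.4)^2
  attr(dd, "factors") <- attr(d, "factors")
  vf <- fit_quadratic(dd, "y")
  vopt <- optimize_surface(vf, "max")
  expect_equal(unname(c(vopt$x1, vopt$x2)), c(0.2, -0.4), tolerance = 1e-6)
  expect_equal(vopt$value, 10, tolerance = 1e-6)
})

test_that("tidy and glance expose the model summary in broom shape", {
  fit <- fit_rsm(d, "flux")
  td <- tidy(fit)
  expect_setequal(td$term, c("intercept", "x2", "x1sq", "x2sq", "x1x2"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 29L)
  expect_gt(gl$r.squared, 0.9)
})
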