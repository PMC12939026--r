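laws <- c("complete", "standard", "intermediate", "cake")

test_that("decay simulators honour their closed forms and boundary cases", {
  times <- seq(0, 2, by = 0.1)
  for (law in laws) {
    s <- simulate_decay(law, 600, 0.3, times)
    expect_equal(s$flux[1], 600)                      # t = 0 gives J0
    expect_true(all(diff(s$flux) <= 0))               # monotone decay
    s0 <- simulate_decay(law, 600, 0, times)
    expect_equal(s0$flux, rep(600, length(times)))    # eps = 0 constant
  }
  # intermediate closed form: 1/600 + 2/1200 = 1/300
  s <- simulate_decay("intermediate", 600, 1 / 1200, c(0, 2))
  expect_equal(s$flux[2], 300)
  # complete law is exponential
  sc <- simulate_decay("complete", 500, log(2), c(0, 1, 2))
  expect_equal(sc$flux, c(500, 250, 125))
})

test_that("simulate then fit round-trips (J0, eps) exactly for every law", {
  times <- seq(0, 2, by = 1 / 30)
  for (law in laws) {
    eps <- cocoflux:::eps_for_halving(law, 600, 2)
    s <- simulate_decay(law, 600, eps, times)
    f <- fit_hermia(s, law)
    expect_equal(f$epsilon, eps, tolerance = 1e-9)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
    # intercept back-transforms to J0
    j0_hat <- switch(law,
      complete = exp(f$intercept),
      standard = f$intercept^(-2),
      intermediate = 1 / f$intercept,
      cake = f$intercept^(-0.5)
    )
    expect_equal(j0_hat, 600, tolerance = 1e-6)
  }
})

test_that("a mismatched law cannot fit an exact series perfectly", {
  s <- simulate_decay("cake", 600, cocoflux:::eps_for_halving("cake", 600, 2),
                      seq(0, 2, by = 1 / 30))
  f <- fit_hermia(s, "complete")
  expect_lt(f$r_squared, 1 - 1e-6)
})

test_that("degenerate series are flagged rather than mis-ranked", {
  # two points: perfect but under-determined
  s2 <- simulate_decay("intermediate", 600, 0.1, c(0, 1))
  expect_true(fit_hermia(s2, "intermediate")$underdetermined)
  # constant series: every law degenerate, fixed law order retained
  sc <- tibble::tibble(time_h = 0:5, flux = rep(400, 6))
  rk <- select_mechanism(sc)
  expect_true(attr(rk, "degenerate"))
  expect_equal(rk$law, laws)
  expect_equal(rk$epsilon, rep(0, 4))
  # non-positive flux names the offending index
  bad <- tibble::tibble(time_h = 0:2, flux = c(10, -1, 5))
  expect_error(fit_hermia(bad, "cake"), "index 2",
               class = "cocoflux_series_error")
})

test_that("noiseless mechanism selection is exact; close fits flag a mixed regime", {
  for (law in laws) {
    s <- gen_flux_series(law, noise_cv = 0, seed = 1)
    rk <- select_mechanism(s)
    expect_equal(rk$law[1], law)
    expect_equal(rk$r_squared[1], 1, tolerance = 1e-9)
  }
  # two laws with nearly identical transforms over a short window
  s <- simulate_decay("intermediate", 600,
                      cocoflux:::eps_for_halving("intermediate", 600, 20),
                      seq(0, 0.5, by = 0.05))
  rk <- select_mechanism(s)
  expect_true(attr(rk, "mixed_regime"))
})

test_that("the complete-law rate is invariant to a time-origin shift", {
  times <- seq(0, 2, by = 0.1)
  s <- simulate_decay("complete", 600, 0.4, times)
  shifted <- s
  shifted$time_h <- shifted$time_h + 5
  f1 <- fit_hermia(s, "complete")
  f2 <- fit_hermia(shifted, "complete")
  expect_equal(f1$epsilon, f2$epsilon, tolerance = 1e-12)
})

test_that("burn-in excludes the initial polarization-dominated points", {
  s <- gen_flux_series("intermediate", noise_cv = 0, seed = 1)
  f <- fit_hermia(s, "intermediate", burn_in = 0.5)
  expect_equal(f$n_points, sum(s$time_h >= 0.5))
})

test_that("mechanism recovery under 2% multiplicative noise is reliable", {
  # light version of the full simulation study: one law, 40 seeds
  hits <- sum(sapply(1:40, function(s) {
    select_mechanism(gen_flux_series("complete", seed = s))$law[1] == "complete"
  }))
  expect_gte(hits / 40, 0.9)
})
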