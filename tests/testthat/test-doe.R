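test_that("factor coding maps the design window onto [-1, 1] exactly", {
  f <- fcd_factors()
  p <- f[f$name == "pressure", ]
  expect_identical(code_level(50, p), -1)
  expect_identical(code_level(125, p), 0)
  expect_identical(code_level(200, p), 1)
  expect_equal(code_level(75, p), -2 / 3)
})

test_that("code/decode are exact inverses over many finite levels", {
  f <- fcd_factors()
  for (nm in f$name) {
    row <- f[f$name == nm, ]
    vals <- seq(row$low - 3 * row$half_range, row$high + 3 * row$half_range,
                length.out = 101)
    expect_equal(decode_level(code_level(vals, row), row), vals)
    coded <- seq(-2, 2, length.out = 101)
    expect_equal(code_level(decode_level(coded, row), row), coded)
  }
})

test_that("degenerate factor windows are rejected", {
  expect_error(fcd_factors(pressure = c(100, 100)), class = "cocoflux_invalid_factor")
  expect_error(fcd_factors(temperature = c(40, 20)), class = "cocoflux_invalid_factor")
})

test_that("the default design plan lays out 13 runs / 29 samples on 9 conditions", {
  d <- build_fcd()
  expect_equal(nrow(d), 29L)
  expect_equal(dplyr::n_distinct(d$run), 13L)
  expect_equal(dplyr::n_distinct(d$x1, d$x2), 9L)
  corners <- unique(d[abs(d$x1) == 1 & abs(d$x2) == 1, c("x1", "x2")])
  expect_setequal(paste(corners$x1, corners$x2),
                  c("-1 -1", "1 -1", "-1 1", "1 1"))
  # replicate plan: 3 per non-center condition, 5 center samples
  expect_true(all(table(d$run[!d$is_center]) == 3))
  expect_equal(sum(d$is_center), 5L)
})

test_that("the packaged experiment table reproduces its printed summaries", {
  d <- coconut_design()
  expect_equal(nrow(d), 29L)
  expect_equal(mean(d$flux[d$is_center]), 656.11, tolerance = 1e-4)
  expect_equal(sd(d$flux[d$is_center]), 15.25, tolerance = 1e-3)
  expect_equal(mean(d$fouling_index[d$is_center]), 85.19, tolerance = 1e-3)
  # condition means match the printed table to 2 decimals
  means <- d |>
    dplyr::summarise(flux = mean(flux), fi = mean(fouling_index),
                     .by = c(x1, x2))
  at <- function(x1, x2, col) means[[col]][means$x1 == x1 & means$x2 == x2]
  expect_equal(at(-1, 0, "flux"), 608.78)
  expect_equal(at(1, 1, "fi"), 94.66)
  expect_true(all(validate_design(d)$ok))
})

test_that("CSV round trip is lossless and bad files are rejected with row context", {
  d <- coconut_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fcd_csv(d, path)
  d2 <- read_fcd_csv(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)

  # missing column
  broken <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(as.data.frame(d), -pressure), broken)
  expect_error(read_fcd_csv(broken), "pressure", class = "cocoflux_parse_error")

  # empty file
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("run,replicate,pressure,temperature,flux", empty)
  expect_error(read_fcd_csv(empty), class = "cocoflux_parse_error")

  # inconsistent levels within a run
  bad <- as.data.frame(d)
  bad$pressure[2] <- 60
  badpath <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad[, c("run", "replicate", "pressure", "temperature", "flux",
                           "fouling_index")], badpath)
  expect_error(read_fcd_csv(badpath), "run", class = "cocoflux_parse_error")
})

test_that("JSON round trip preserves the dataset", {
  d <- coconut_design()
  path <- withr::local_tempfile(fileext = ".json")
  write_fcd_json(d, path)
  d2 <- read_fcd_json(path)
  expect_equal(d2$flux, d$flux)
  expect_equal(d2$x1, d$x1)
  expect_equal(attr(d2, "factors")$half_range, attr(d, "factors")$half_range)
})

test_that("validate_design flags physically impossible responses", {
  d <- coconut_design()
  d$fouling_index[3] <- 140
  diag <- validate_design(d)
  expect_false(all(diag$ok))
  expect_false(diag$ok[diag$check == "fouling index in [0, 100]"])
})
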