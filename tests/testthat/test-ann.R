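d <- coconut_design()

test_that("transfer functions match their closed forms", {
  expect_identical(tansig(0), 0)
  expect_equal(tansig(1), 2 / (1 + exp(-2)) - 1)
  expect_equal(tansig(1), 0.76159, tolerance = 1e-5)
  n <- seq(-5, 5, by = 0.25)
  expect_equal(tansig(n), -tansig(-n))          # odd
  expect_true(all(abs(tansig(n * 10)) <= 1))    # bounded (saturates in fp)
  expect_true(all(abs(tansig(n)) < 1))
  expect_equal(tansig(n), tanh(n))              # equivalent form
  expect_identical(purelin(n), n)
})

test_that("splits follow largest-remainder sizes and are reproducible", {
  s29 <- split_samples(29, seed = 4)
  expect_equal(lengths(s29), c(train = 20L, validation = 4L, test = 5L),
               ignore_attr = TRUE)
  s10 <- split_samples(10, seed = 4)
  expect_equal(unname(lengths(s10)), c(7L, 1L, 2L))
  # disjoint and exhaustive
  expect_setequal(unlist(s29), 1:29)
  expect_equal(length(unlist(s29)), 29L)
  expect_identical(split_samples(29, seed = 7), split_samples(29, seed = 7))
  expect_error(split_samples(2), class = "cocoflux_split_error")
})

test_that("a noise-free network is recovered to near machine precision without penalty", {
  # fabricate data from a known 2-5-2 network on scaled inputs
  truth <- withr::with_seed(3, runif(27, -0.8, 0.8))
  grid <- as.matrix(expand.grid(p = seq(50, 200, length.out = 6),
                                t = seq(20, 40, length.out = 5)))
  sx <- list(min = c(50, 20), max = c(200, 40))
  Xs <- cocoflux:::scale_minmax(grid, sx)
  Ys <- cocoflux:::mlp_forward(truth, Xs, 5L, 2L)$Y
  dd <- tibble::tibble(
    run = seq_len(nrow(grid)), replicate = 1L,
    pressure = grid[, 1], temperature = grid[, 2],
    x1 = Xs[, 1], x2 = Xs[, 2], is_center = FALSE,
    flux = Ys[, 1] * 100 + 500, fouling_index = Ys[, 2] * 5 + 85
  )
  attr(dd, "factors") <- fcd_factors()
  cfg <- ann_config(reg_lambda = 0, n_restarts = 8, seed = 5,
                    max_epochs = 400, patience = 50)
  fit <- select_best_mlp(dd, cfg)
  tr <- fit$diagnostics$mse[fit$diagnostics$subset == "train"]
  expect_lt(tr, 1e-6)
})

test_that("with an unregularized linear target the network matches OLS on training points", {
  dd <- build_fcd()
  dd$flux <- 500 + 60 * dd$x1 - 30 * dd$x2
  dd$fouling_index <- 85 + 3 * dd$x1 + 1 * dd$x2
  attr(dd, "factors") <- fcd_factors()
  cfg <- ann_config(reg_lambda = 0, n_restarts = 5, seed = 2)
  fit <- select_best_mlp(dd, cfg)
  ols <- lm(flux ~ x1 + x2, dd)
  tr <- fit$split$train
  pred <- predict(fit, newdata = dd[tr, ])$flux
  expect_equal(pred, unname(predict(ols, dd[tr, ])), tolerance = 0.01)
})

test_that("training diagnostics behave: bounded hidden layer, monotone objective", {
  fit <- train_mlp(d, ann_config(seed = 9))
  Xs <- cocoflux:::scale_minmax(as.matrix(d[, c("pressure", "temperature")]),
                                fit$scaler_in)
  H <- tansig(Xs %*% t(fit$W1) + matrix(fit$b1, nrow(Xs), 5, byrow = TRUE))
  expect_true(all(abs(H) < 1))
  expect_true(all(diff(fit$perf_history) <= 1e-12))
})

test_that("inputs at the scaler bounds map to exactly +/-1 and back", {
  fit <- train_mlp(d, ann_config(seed = 1))
  X <- rbind(fit$scaler_in$min, fit$scaler_in$max)
  Z <- cocoflux:::scale_minmax(X, fit$scaler_in)
  expect_equal(unname(Z), rbind(c(-1, -1), c(1, 1)))
  expect_equal(cocoflux:::unscale_minmax(Z, fit$scaler_in), X)
})

test_that("a zero-weight network predicts the unscaled output bias", {
  fit <- train_mlp(d, ann_config(seed = 1))
  fit$W1[] <- 0; fit$b1[] <- 0; fit$W2[] <- 0; fit$b2[] <- c(0, 0)
  pr <- predict(fit, pressure = c(60, 190), temperature = c(25, 35))
  mid <- (fit$scaler_out$max + fit$scaler_out$min) / 2
  expect_equal(pr$flux, rep(mid[[1]], 2))
  expect_equal(pr$fouling_index, rep(mid[[2]], 2))
})

test_that("constant-response data trains to the constant under the weight penalty", {
  dd <- build_fcd()
  dd$flux <- 500
  dd$fouling_index <- 85
  attr(dd, "factors") <- fcd_factors()
  expect_warning(fit <- train_mlp(dd, ann_config(seed = 3)), "constant")
  pr <- predict(fit, pressure = c(75, 150), temperature = c(25, 35))
  expect_equal(pr$flux, c(500, 500), tolerance = 0.05)
  expect_equal(pr$fouling_index, c(85, 85), tolerance = 0.05)
  msw <- mean(c(fit$W1, fit$b1, fit$W2, fit$b2)^2)
  expect_lt(msw, 0.5)
})

test_that("restart selection returns the minimum-validation network", {
  cfg <- ann_config(n_restarts = 6, seed = 21)
  best <- select_best_mlp(d, cfg)
  expect_equal(best$val_mse, min(best$restarts$val_mse))
  expect_equal(nrow(best$restarts), 6L)
  one <- select_best_mlp(d, ann_config(n_restarts = 1, seed = 21))
  solo <- train_mlp(d, ann_config(seed = 21))
  expect_equal(one$W1, solo$W1)
  expect_equal(one$val_mse, solo$val_mse)
})

test_that("the fixture-trained surrogate lands in the stochastic envelope", {
  best <- select_best_mlp(d, ann_config(n_restarts = 20, seed = 11))
  ctr <- predict(best, pressure = 125, temperature = 30)
  expect_lt(abs(ctr$flux - 659.19) / 659.19, 0.05)
  val <- predict(best, pressure = 75, temperature = 30)
  expect_gt(val$flux, 590)
  expect_lt(val$flux, 680)
})
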