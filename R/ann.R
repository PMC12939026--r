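#' Transfer functions of the feed-forward surrogate
#'
#' `tansig()` is the hyperbolic-tangent sigmoid, `2 / (1 + exp(-2 n)) - 1`,
#' bounded in (-1, 1) and used in the hidden layer; `purelin()` is the
#' identity used in the output layer.
#'
#' @param n Numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' tansig(0)    # 0
#' tansig(1)    # 0.76159
#' @export
tansig <- function(n) 2 / (1 + exp(-2 * n)) - 1

#' @rdname tansig
#' @export
purelin <- function(n) n

#' Random train/validation/test split by largest-remainder apportionment
#'
#' Subset sizes are the largest-remainder apportionment of `n` over the
#' fractions, with remainder ties resolved in favour of the test subset, then
#' validation (so n = 29 with a 70/15/15 split yields 20/4/5). Membership is
#' a seeded random permutation.
#'
#' @param n Number of samples.
#' @param fractions Numeric length-3 summing to 1 (train, validation, test).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list of integer index vectors `train`, `validation`, `test`;
#'   disjoint and exhaustive.
#' @examples
#' lengths(split_samples(29, seed = 1))  # 20 4 5
#' @export
split_samples <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  target <- n * fractions
  sizes <- floor(target)
  left <- n - sum(sizes)
  if (left > 0) {
    rem <- target - sizes
    # rank by remainder descending; ties prefer test (3), then validation (2)
    pref <- order(-rem, -(seq_len(3)))
    for (k in seq_len(left)) sizes[pref[k]] <- sizes[pref[k]] + 1L
  }
  if (any(sizes == 0)) {
    abort("n too small for non-empty train/validation/test subsets",
          class = "cocoflux_split_error")
  }
  perm <- with_seed(seed, sample.int(n))
  list(
    train = sort(perm[seq_len(sizes[1])]),
    validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
    test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  )
}

# Evaluate expr with a temporary RNG state seeded by `seed`
# (restores the caller's state afterwards).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# min-max scaling to [-1, 1], the mapminmax convention. A constant column
# has no range; it is pinned to -1 by widening the span, so constant targets
# stay representable (the degenerate-target case).
fit_scaler <- function(x) {
  rng <- apply(x, 2, range)
  flat <- rng[2, ] <= rng[1, ]
  if (any(flat)) {
    warn("constant column(s) scaled with unit span")
    rng[2, flat] <- rng[1, flat] + 1
  }
  list(min = rng[1, ], max = rng[2, ])
}

scale_minmax <- function(x, s) {
  sweep(sweep(x, 2, s$min), 2, (s$max - s$min) / 2, "/") - 1
}

unscale_minmax <- function(z, s) {
  sweep(sweep(z + 1, 2, (s$max - s$min) / 2, "*"), 2, s$min, "+")
}

#' Training configuration for the neural surrogate
#'
#' Defaults follow the reference training setup: a 5-neuron hidden layer,
#' L2 regularization weight 0.10, a 70/15/15 random sample-level split,
#' Levenberg-Marquardt damping starting at 1e-3 (x10 on a rejected step,
#' /10 on an accepted one, aborting above 1e10), at most 1000 epochs and a
#' patience of 6 consecutive validation failures.
#'
#' @param hidden Hidden-layer width.
#' @param reg_lambda Regularization weight in \[0, 1): the training objective
#'   is `(1 - lambda) * MSE + lambda * MSW` with MSW the mean squared
#'   weight/bias.
#' @param fractions Train/validation/test fractions.
#' @param max_epochs,patience,mu0,mu_inc,mu_dec,mu_max Levenberg-Marquardt
#'   controls.
#' @param n_restarts Number of random initializations for [select_best_mlp()].
#' @param scale_on `"all"` fits the min-max scalers on every sample (default);
#'   `"train"` restricts them to the training subset.
#' @param seed Base seed for the split and the weight initialization.
#' @return A list of class `ann_config`.
#' @export
ann_config <- function(hidden = 5L, reg_lambda = 0.10,
                       fractions = c(0.70, 0.15, 0.15),
                       max_epochs = 1000L, patience = 6L,
                       mu0 = 1e-3, mu_inc = 10, mu_dec = 10, mu_max = 1e10,
                       n_restarts = 1L, scale_on = c("all", "train"),
                       seed = 1L) {
  stopifnot(reg_lambda >= 0, reg_lambda < 1, abs(sum(fractions) - 1) < 1e-9)
  structure(
    list(
      hidden = as.integer(hidden), reg_lambda = reg_lambda,
      fractions = fractions, max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), mu0 = mu0, mu_inc = mu_inc,
      mu_dec = mu_dec, mu_max = mu_max, n_restarts = as.integer(n_restarts),
      scale_on = match.arg(scale_on), seed = as.integer(seed)
    ),
    class = "ann_config"
  )
}

# pack / unpack the 2-h-2 parameter vector
unpack_theta <- function(theta, n_in, n_hid, n_out) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(n_hid * n_in)], n_hid, n_in); i <- i + n_hid * n_in
  b1 <- theta[i + seq_len(n_hid)]; i <- i + n_hid
  W2 <- matrix(theta[i + seq_len(n_out * n_hid)], n_out, n_hid); i <- i + n_out * n_hid
  b2 <- theta[i + seq_len(n_out)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(theta, X, n_hid, n_out) {
  p <- unpack_theta(theta, ncol(X), n_hid, n_out)
  H <- tansig(X %*% t(p$W1) + matrix(p$b1, nrow(X), n_hid, byrow = TRUE))
  Y <- H %*% t(p$W2) + matrix(p$b2, nrow(X), n_out, byrow = TRUE)
  list(H = H, Y = Y)
}

# Jacobian of the stacked output vector (samples x outputs, column-major by
# output) with respect to theta. Tiny problem sizes; dense is fine.
mlp_jacobian <- function(theta, X, n_hid, n_out) {
  p <- unpack_theta(theta, ncol(X), n_hid, n_out)
  n <- nrow(X); n_in <- ncol(X)
  fw <- mlp_forward(theta, X, n_hid, n_out)
  H <- fw$H
  dH <- 1 - H^2  # tansig derivative
  n_par <- length(theta)
  J <- matrix(0, n * n_out, n_par)
  for (k in seq_len(n_out)) {
    rows <- (k - 1) * n + seq_len(n)
    # d y_k / d W1[j, m] = W2[k, j] * dH[, j] * X[, m]
    col <- 0
    for (m in seq_len(n_in)) {
      for (j in seq_len(n_hid)) {
        # theta layout: W1 column-major (j fast), so index = (m-1)*n_hid + j
        J[rows, (m - 1) * n_hid + j] <- p$W2[k, j] * dH[, j] * X[, m]
      }
    }
    col <- n_hid * n_in
    # d y_k / d b1[j]
    J[rows, col + seq_len(n_hid)] <- sweep(dH, 2, p$W2[k, ], "*")
    col <- col + n_hid
    # d y_k / d W2[k', j] nonzero only for k' = k; W2 column-major (k fast)
    for (j in seq_len(n_hid)) {
      J[rows, col + (j - 1) * n_out + k] <- H[, j]
    }
    col <- col + n_out * n_hid
    # d y_k / d b2[k']
    J[rows, col + k] <- 1
  }
  J
}

ann_perf <- function(theta, X, T_, n_hid, n_out, lambda) {
  Y <- mlp_forward(theta, X, n_hid, n_out)$Y
  mse <- mean((T_ - Y)^2)
  (1 - lambda) * mse + lambda * mean(theta^2)
}

# One Levenberg-Marquardt training run on scaled data.
train_lm_core <- function(Xtr, Ttr, Xval, Tval, config, init_seed) {
  n_in <- ncol(Xtr); n_out <- ncol(Ttr); n_hid <- config$hidden
  n_par <- n_hid * n_in + n_hid + n_out * n_hid + n_out
  theta <- with_seed(init_seed, runif(n_par, -0.5, 0.5))
  lambda <- config$reg_lambda
  N <- length(Ttr)

  # Regularized least squares as an augmented residual vector:
  # r = [sqrt((1-lambda)/N) * e ; sqrt(lambda/n_par) * theta]
  w_e <- sqrt((1 - lambda) / N)
  w_t <- sqrt(lambda / n_par)

  resid_aug <- function(th) {
    Y <- mlp_forward(th, Xtr, n_hid, n_out)$Y
    c(w_e * as.vector(Ttr - Y), w_t * th)
  }
  perf_of <- function(th) sum(resid_aug(th)^2)

  mu <- config$mu0
  perf <- perf_of(theta)
  perf_history <- perf
  val_mse <- function(th) {
    if (is.null(Xval) || nrow(Xval) == 0) return(NA_real_)
    mean((Tval - mlp_forward(th, Xval, n_hid, n_out)$Y)^2)
  }
  best_val <- val_mse(theta)
  best_theta <- theta
  fails <- 0L
  stop_reason <- "max_epochs"
  epochs <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    epochs <- epoch
    r <- resid_aug(theta)
    Je <- -w_e * mlp_jacobian(theta, Xtr, n_hid, n_out)
    J <- rbind(Je, diag(w_t, n_par))
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(JtJ + diag(mu, n_par), -g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- theta + as.vector(delta)
        perf_new <- perf_of(cand)
        if (is.finite(perf_new) && perf_new < perf) {
          theta <- cand
          perf <- perf_new
          mu <- mu / config$mu_dec
          accepted <- TRUE
        }
      }
      if (!accepted) {
        mu <- mu * config$mu_inc
        if (mu > config$mu_max) break
      }
    }
    if (!accepted) {
      stop_reason <- "mu_overflow"
      break
    }
    if (!is.finite(perf)) {
      abort("non-finite training loss", class = "cocoflux_train_error")
    }
    perf_history <- c(perf_history, perf)
    v <- val_mse(theta)
    if (!is.na(v)) {
      if (is.na(best_val) || v < best_val) {
        best_val <- v
        best_theta <- theta
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config$patience) {
          stop_reason <- "validation_patience"
          break
        }
      }
    } else {
      best_theta <- theta
    }
  }
  list(theta = best_theta, epochs = epochs, stop_reason = stop_reason,
       val_mse = best_val, perf_history = perf_history)
}

pooled_r2 <- function(T_, Y) {
  1 - sum((T_ - Y)^2) / sum((T_ - mean(T_))^2)
}

#' Train the 2-5-2 neural surrogate
#'
#' Fits a multilayer feed-forward network mapping (pressure, temperature) to
#' (permeate flux, fouling index): tansig hidden layer, purelin output,
#' inputs and targets min-max scaled to \[-1, 1\]. Training minimizes
#' `(1 - lambda) * MSE + lambda * MSW` on the training subset by
#' Levenberg-Marquardt steps `(J'J + mu I) delta = -J'r` with adaptive
#' damping, stopping on the epoch limit, damping overflow or the validation
#' patience; the weights at the best validation error are kept.
#'
#' @param data An `fcd_df` tibble with `flux` and `fouling_index` columns.
#' @param config An [ann_config()].
#' @param split_seed,init_seed Optional seed overrides for the subset split
#'   and the uniform \[-0.5, 0.5\] weight initialization; both default to
#'   `config$seed`.
#' @return An object of class `mlp_surrogate` holding the weight matrices,
#'   the scalers, the subset indices and per-subset diagnostics (MSE and
#'   pooled R-squared on the scaled targets).
#' @export
train_mlp <- function(data, config = ann_config(), split_seed = NULL,
                      init_seed = NULL) {
  split_seed <- split_seed %||% config$seed
  init_seed <- init_seed %||% config$seed
  X <- as.matrix(data[, c("pressure", "temperature")])
  T_ <- as.matrix(data[, c("flux", "fouling_index")])
  split <- split_samples(nrow(X), config$fractions, seed = split_seed)

  scale_rows <- if (config$scale_on == "all") seq_len(nrow(X)) else split$train
  sx <- fit_scaler(X[scale_rows, , drop = FALSE])
  sy <- fit_scaler(T_[scale_rows, , drop = FALSE])
  Xs <- scale_minmax(X, sx)
  Ts <- scale_minmax(T_, sy)

  run <- train_lm_core(
    Xs[split$train, , drop = FALSE], Ts[split$train, , drop = FALSE],
    Xs[split$validation, , drop = FALSE], Ts[split$validation, , drop = FALSE],
    config, init_seed
  )
  p <- unpack_theta(run$theta, 2L, config$hidden, 2L)
  diag_tbl <- purrr::map_dfr(
    list(train = split$train, validation = split$validation, test = split$test,
         all = seq_len(nrow(X))),
    function(idx) {
      Y <- mlp_forward(run$theta, Xs[idx, , drop = FALSE], config$hidden, 2L)$Y
      tibble::tibble(
        n = length(idx),
        mse = mean((Ts[idx, , drop = FALSE] - Y)^2),
        r_squared = pooled_r2(Ts[idx, , drop = FALSE], Y)
      )
    },
    .id = "subset"
  )
  structure(
    list(
      W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
      scaler_in = sx, scaler_out = sy,
      split = split, config = config,
      split_seed = split_seed, init_seed = init_seed,
      epochs = run$epochs, stop_reason = run$stop_reason,
      val_mse = run$val_mse, perf_history = run$perf_history,
      diagnostics = diag_tbl,
      responses = c("flux", "fouling_index")
    ),
    class = "mlp_surrogate"
  )
}

#' Best-of-restarts model selection
#'
#' Runs [train_mlp()] with `config$n_restarts` different weight
#' initializations (seeds `config$seed + 0:(n_restarts - 1)`; the data split
#' is held fixed) and returns the network with the lowest validation-subset
#' MSE. All restart diagnostics are kept in `$restarts`.
#'
#' @inheritParams train_mlp
#' @return The winning `mlp_surrogate`, with a `restarts` tibble attached.
#' @export
select_best_mlp <- function(data, config = ann_config(n_restarts = 20L)) {
  stopifnot(config$n_restarts >= 1L)
  fits <- purrr::map(seq_len(config$n_restarts) - 1L, function(k) {
    train_mlp(data, config, split_seed = config$seed,
              init_seed = config$seed + k)
  })
  val <- purrr::map_dbl(fits, "val_mse")
  best <- fits[[which.min(val)]]
  best$restarts <- tibble::tibble(
    restart = seq_along(fits),
    init_seed = config$seed + seq_along(fits) - 1L,
    val_mse = val,
    epochs = purrr::map_int(fits, "epochs"),
    stop_reason = purrr::map_chr(fits, "stop_reason")
  )
  best
}

#' Predict in physical units from a trained surrogate
#'
#' Scales the inputs with the stored mapminmax parameters, runs the forward
#' pass and unscales the outputs back to physical units.
#'
#' @param object An `mlp_surrogate`.
#' @param newdata Optional tibble with `pressure` and `temperature` columns.
#' @param pressure,temperature Optional actual-unit vectors.
#' @param ... Unused.
#' @return A tibble with columns `pressure`, `temperature`, `flux`
#'   (L h^-1 m^-2) and `fouling_index` (%).
#' @export
predict.mlp_surrogate <- function(object, newdata = NULL, pressure = NULL,
                                  temperature = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- tibble::tibble(pressure = pressure, temperature = temperature)
  }
  X <- as.matrix(newdata[, c("pressure", "temperature")])
  Xs <- scale_minmax(X, object$scaler_in)
  H <- tansig(Xs %*% t(object$W1) +
                matrix(object$b1, nrow(Xs), length(object$b1), byrow = TRUE))
  Ys <- H %*% t(object$W2) +
    matrix(object$b2, nrow(Xs), length(object$b2), byrow = TRUE)
  Y <- unscale_minmax(Ys, object$scaler_out)
  tibble::tibble(
    pressure = X[, 1], temperature = X[, 2],
    flux = Y[, 1], fouling_index = Y[, 2]
  )
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat("Feed-forward surrogate 2-", x$config$hidden, "-2 (tansig/purelin)\n", sep = "")
  cat("  stop: ", x$stop_reason, " after ", x$epochs, " epochs; validation MSE ",
      signif(x$val_mse, 4), "\n", sep = "")
  print(x$diagnostics)
  invisible(x)
}

#' @method tidy mlp_surrogate
#' @export
tidy.mlp_surrogate <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      layer = "hidden",
      neuron = rep(seq_along(x$b1), times = ncol(x$W1) + 1L),
      input = rep(c(colnames(x$W1) %||% c("pressure", "temperature"), "bias"),
                  each = length(x$b1)),
      weight = c(as.vector(x$W1), x$b1)
    ),
    tibble::tibble(
      layer = "output",
      neuron = rep(seq_along(x$b2), times = ncol(x$W2) + 1L),
      input = rep(c(paste0("hidden", seq_len(ncol(x$W2))), "bias"),
                  each = length(x$b2)),
      weight = c(as.vector(x$W2), x$b2)
    )
  )
}

#' @method glance mlp_surrogate
#' @export
glance.mlp_surrogate <- function(x, ...) {
  d <- tidyr::pivot_wider(
    x$diagnostics, names_from = "subset",
    values_from = c("n", "mse", "r_squared")
  )
  dplyr::bind_cols(
    d,
    tibble::tibble(epochs = x$epochs, stop_reason = x$stop_reason)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
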