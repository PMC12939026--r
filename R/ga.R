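#' Genetic-algorithm configuration
#'
#' Defaults mirror the reference optimization setup: population 120, 50
#' generations, 5% elitism and a stall limit of 8 generations, over the
#' pressure-temperature design box. The variation operators are tournament
#' selection of size 2, blend (BLX-0.5) crossover applied to 80% of pairings,
#' and Gaussian mutation whose step size decays linearly over the
#' generations, with offspring clamped to the bounds.
#'
#' @param pop_size Population size.
#' @param generations Generation limit.
#' @param elite_fraction Fraction of the population copied unchanged.
#' @param stall_generations Stop after this many generations without an
#'   absolute best-fitness improvement above `stall_tol`.
#' @param bounds Numeric matrix with one row per decision variable and
#'   columns `lo`, `hi` (defaults to the 50-200 kPa x 20-40 degC box).
#' @param crossover_fraction Probability a pairing undergoes crossover.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_scale Initial mutation standard deviation as a fraction of
#'   the variable span.
#' @param stall_tol Absolute improvement below which a generation counts as
#'   stalled.
#' @param seed Integer seed; a fixed seed gives a bit-identical trajectory.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 120L, generations = 50L,
                      elite_fraction = 0.05, stall_generations = 8L,
                      bounds = rbind(pressure = c(50, 200),
                                     temperature = c(20, 40)),
                      crossover_fraction = 0.8, mutation_rate = 0.2,
                      mutation_scale = 0.1, stall_tol = 1e-6, seed = 1L) {
  stopifnot(pop_size > 0, elite_fraction >= 0, elite_fraction < 1,
            all(is.finite(bounds)), all(bounds[, 2] > bounds[, 1]))
  structure(
    list(
      pop_size = as.integer(pop_size), generations = as.integer(generations),
      elite_fraction = elite_fraction,
      stall_generations = as.integer(stall_generations),
      bounds = bounds, crossover_fraction = crossover_fraction,
      mutation_rate = mutation_rate, mutation_scale = mutation_scale,
      stall_tol = stall_tol, seed = as.integer(seed)
    ),
    class = "ga_config"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run the bounded genetic algorithm
#'
#' Minimizes `fitness` over the box in `config$bounds`. Each generation the
#' elites are copied unchanged; the remainder of the next population is
#' produced by size-2 tournament selection, BLX-0.5 blend crossover and
#' decaying Gaussian mutation, all clamped to the bounds. Candidates whose
#' fitness evaluates non-finite are assigned `+Inf` and counted. Terminates
#' at the generation limit or when the best fitness has not improved by more
#' than `stall_tol` for `stall_generations` consecutive generations.
#'
#' @param fitness Function taking a numeric vector (one point) and returning
#'   a scalar to minimize.
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `best_par`, `best_fitness`, the
#'   per-generation `trajectory` (best and mean fitness), `generations_run`,
#'   `termination` and the count of non-finite evaluations.
#' @examples
#' res <- run_ga(function(p) (p[1] - 100)^2 + (p[2] - 30)^2,
#'               ga_config(seed = 42))
#' res$best_par
#' @export
run_ga <- function(fitness, config = ga_config()) {
  b <- config$bounds
  nvar <- nrow(b)
  span <- b[, 2] - b[, 1]
  n <- config$pop_size
  n_elite <- max(1L, ceiling(config$elite_fraction * n))
  bad <- 0L

  eval_pop <- function(pop) {
    f <- apply(pop, 1, function(p) {
      v <- tryCatch(fitness(p), error = function(e) NaN)
      if (!is.finite(v)) {
        bad <<- bad + 1L
        Inf
      } else {
        v
      }
    })
    as.numeric(f)
  }

  with_seed(config$seed, {
    pop <- sapply(seq_len(nvar), function(j) runif(n, b[j, 1], b[j, 2]))
    fit <- eval_pop(pop)
    best_hist <- numeric(0)
    mean_hist <- numeric(0)
    stall <- 0L
    termination <- "generations"
    gen_run <- 0L

    for (gen in seq_len(config$generations)) {
      gen_run <- gen
      ord <- order(fit)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      best_now <- fit[1]
      best_hist <- c(best_hist, best_now)
      mean_hist <- c(mean_hist, mean(fit[is.finite(fit)]))

      if (gen > 1) {
        if (best_hist[gen - 1] - best_now < config$stall_tol) {
          stall <- stall + 1L
        } else {
          stall <- 0L
        }
        if (stall >= config$stall_generations) {
          termination <- "stall"
          break
        }
      }

      elites <- pop[seq_len(n_elite), , drop = FALSE]
      n_off <- n - n_elite
      # size-2 tournaments
      pick <- function(k) {
        i <- sample.int(n, 2 * k, replace = TRUE)
        j <- sample.int(n, 2 * k, replace = TRUE)
        ifelse(fit[i] <= fit[j], i, j)
      }
      n_pairs <- ceiling(n_off / 2)
      pairs <- matrix(pick(2 * n_pairs), ncol = 2)
      off <- matrix(0, n_off, nvar)
      for (r in seq_len(n_pairs)) {
        p1 <- pop[pairs[r, 1], ]
        p2 <- pop[pairs[r, 2], ]
        if (runif(1) < config$crossover_fraction) {
          lo <- pmin(p1, p2); hi <- pmax(p1, p2); d <- hi - lo
          c1 <- runif(nvar, lo - 0.5 * d, hi + 0.5 * d)
          c2 <- runif(nvar, lo - 0.5 * d, hi + 0.5 * d)
        } else {
          c1 <- p1; c2 <- p2
        }
        off[2 * r - 1, ] <- c1
        if (2 * r <= n_off) off[2 * r, ] <- c2
      }
      # Gaussian mutation with per-generation step decay (small floor keeps
      # late-stage local refinement alive)
      sd_gen <- span * pmax(config$mutation_scale * (1 - gen / config$generations),
                            1e-4)
      mut <- matrix(runif(n_off * nvar) < config$mutation_rate, n_off, nvar)
      noise <- matrix(rnorm(n_off * nvar), n_off, nvar) *
        matrix(sd_gen, n_off, nvar, byrow = TRUE)
      off <- off + mut * noise
      off <- sapply(seq_len(nvar), function(j) clamp(off[, j], b[j, 1], b[j, 2]))
      if (is.null(dim(off))) off <- matrix(off, ncol = nvar)

      pop <- rbind(elites, off)
      fit <- c(fit[seq_len(n_elite)], eval_pop(off))
    }

    ord <- order(fit)
    structure(
      list(
        best_par = setNames(pop[ord[1], ], rownames(b)),
        best_fitness = fit[ord[1]],
        trajectory = tibble::tibble(
          generation = seq_along(best_hist),
          best = best_hist, mean = mean_hist
        ),
        generations_run = gen_run,
        termination = termination,
        n_nonfinite = bad,
        config = config
      ),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA result: best fitness ", signif(x$best_fitness, 6), " after ",
      x$generations_run, " generations (", x$termination, ")\n", sep = "")
  print(round(x$best_par, 4))
  invisible(x)
}

#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    generations_run = x$generations_run,
    termination = x$termination,
    n_nonfinite = x$n_nonfinite
  )
}

# Closure predicting one named response at actual (pressure, temperature),
# for either model class.
response_predictor <- function(model, response) {
  if (inherits(model, "rsm_fit")) {
    if (!identical(model$response, response)) {
      abort(paste0("surface was fitted for `", model$response,
                   "`, not `", response, "`"))
    }
    function(p) {
      predict(model, pressure = p[1], temperature = p[2])$.pred
    }
  } else if (inherits(model, "mlp_surrogate")) {
    if (!response %in% model$responses) abort("unknown response name")
    function(p) {
      predict(model, pressure = p[1], temperature = p[2])[[response]]
    }
  } else {
    abort("`model` must be an `rsm_fit` or `mlp_surrogate`")
  }
}

#' GA setpoint search on a fitted surrogate
#'
#' Wraps a fitted model (quadratic surface or neural surrogate) into a GA
#' fitness with the study's sign convention: a flux maximization minimizes
#' `-prediction` (so the reported best fitness is negative when predictions
#' are positive), while a fouling minimization uses the prediction directly.
#'
#' @param model An `rsm_fit` or `mlp_surrogate`.
#' @param response `"flux"` or `"fouling_index"`.
#' @param direction `"max"` or `"min"`.
#' @param config A [ga_config()].
#' @return A `ga_result`; `best_par` is in actual units and `best_fitness`
#'   follows the sign convention above. The predicted response at the
#'   optimum is in `$best_response`.
#' @export
optimize_response <- function(model, response = c("flux", "fouling_index"),
                              direction = c("max", "min"),
                              config = ga_config()) {
  response <- match.arg(response)
  direction <- match.arg(direction)
  pred <- response_predictor(model, response)
  sgn <- if (direction == "max") -1 else 1
  res <- run_ga(function(p) sgn * pred(p), config)
  res$response <- response
  res$direction <- direction
  res$best_response <- pred(res$best_par)
  res
}
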