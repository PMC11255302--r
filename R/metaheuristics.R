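#' Box bounds for a population optimiser
#'
#' @param lower,upper Numeric vectors of elementwise lower and upper limits
#'   (recycled to a common length). Every position an optimiser emits is
#'   clamped into `[lower, upper]`.
#' @return An object of class `sc_bounds`.
#' @export
bounds <- function(lower, upper) {
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (!all(lower < upper)) {
    sc_stop("validation", "bounds must satisfy lower < upper elementwise")
  }
  structure(list(lower = lower, upper = upper, d = d), class = "sc_bounds")
}

clamp <- function(x, b) {
  if (is.matrix(x)) {
    x <- pmin(pmax(x, matrix(b$lower, nrow(x), b$d, byrow = TRUE)),
              matrix(b$upper, nrow(x), b$d, byrow = TRUE))
  } else {
    x <- pmin(pmax(x, b$lower), b$upper)
  }
  x
}

#' Elephant-herding optimiser parameters
#'
#' @param gamma_control Movement control scalar in `[0, 1]` scaling the pull
#'   of each individual toward the herd guide (default 0.6).
#' @param delta_control Control scalar in `[0, 1]`; each iteration the herd
#'   guide is replaced by `delta_control` times the herd centre (default 0.8).
#' @param population Herd size (default 200).
#' @param max_iter Iteration cap (default 1000).
#' @param mse_tol Stop early once the best fitness falls to or below this
#'   value (default 1e-7).
#' @return An object of class `eho_params`.
#' @export
eho_params <- function(gamma_control = 0.6, delta_control = 0.8,
                       population = 200, max_iter = 1000, mse_tol = 1e-7) {
  if (gamma_control < 0 || gamma_control > 1 ||
      delta_control < 0 || delta_control > 1) {
    sc_stop("validation", "EHO control scalars must lie in [0, 1]")
  }
  structure(list(gamma_control = gamma_control, delta_control = delta_control,
                 population = population, max_iter = max_iter,
                 mse_tol = mse_tol), class = "eho_params")
}

#' Particle-swarm optimiser parameters
#'
#' Defaults follow the study configuration: inertia 0.7, both constriction
#' coefficients 1.5, population 200, at most 1000 iterations or convergence
#' at a fitness of 1e-7.
#'
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social constriction coefficients.
#' @param population Swarm size.
#' @param max_iter Iteration cap.
#' @param mse_tol Early-stop fitness threshold.
#' @return An object of class `pso_params`.
#' @export
pso_params <- function(w = 0.7, c1 = 1.5, c2 = 1.5, population = 200,
                       max_iter = 1000, mse_tol = 1e-7) {
  structure(list(w = w, c1 = c1, c2 = c2, population = population,
                 max_iter = max_iter, mse_tol = mse_tol), class = "pso_params")
}

#' Firefly optimiser parameters
#'
#' Defaults follow the study configuration: initial attractiveness 1,
#' light absorption 0.1, attraction coefficient 0.6, randomisation 0.1,
#' population 200.
#'
#' @param i0 Initial attractiveness.
#' @param gamma_absorb Light absorption coefficient.
#' @param beta_attract Attraction coefficient.
#' @param alpha_rand Randomisation parameter; the random term is
#'   `alpha_rand * (U(0,1) - 0.5)` per dimension.
#' @param population Swarm size.
#' @param max_iter Iteration cap.
#' @param mse_tol Early-stop fitness threshold.
#' @return An object of class `firefly_params`.
#' @export
firefly_params <- function(i0 = 1, gamma_absorb = 0.1, beta_attract = 0.6,
                           alpha_rand = 0.1, population = 200,
                           max_iter = 1000, mse_tol = 1e-7) {
  structure(list(i0 = i0, gamma_absorb = gamma_absorb,
                 beta_attract = beta_attract, alpha_rand = alpha_rand,
                 population = population, max_iter = max_iter,
                 mse_tol = mse_tol), class = "firefly_params")
}

#' Flower-pollination optimiser parameters
#'
#' Defaults follow the study configuration: step size 0.15, Levy exponent
#' 1.5, switch probability 0.65, population 200.
#'
#' @param step_delta Global-pollination step scale.
#' @param levy_lambda Levy-flight exponent in `(1, 2]`.
#' @param switch_prob Probability of a global (Levy) step versus a local
#'   random-walk step, in `[0, 1]`.
#' @param population Population size (at least 3, so the local step can draw
#'   two distinct partners).
#' @param max_iter Iteration cap.
#' @param mse_tol Early-stop fitness threshold.
#' @return An object of class `fpo_params`.
#' @export
fpo_params <- function(step_delta = 0.15, levy_lambda = 1.5,
                       switch_prob = 0.65, population = 200,
                       max_iter = 1000, mse_tol = 1e-7) {
  if (switch_prob < 0 || switch_prob > 1) {
    sc_stop("validation", "switch_prob must lie in [0, 1]")
  }
  if (levy_lambda <= 1 || levy_lambda > 2) {
    sc_stop("validation", "levy_lambda must lie in (1, 2]")
  }
  structure(list(step_delta = step_delta, levy_lambda = levy_lambda,
                 switch_prob = switch_prob, population = population,
                 max_iter = max_iter, mse_tol = mse_tol), class = "fpo_params")
}

new_population <- function(positions, fitnesses, best_position, best_fitness,
                           iteration, trace, extra = list()) {
  structure(c(list(positions = positions, fitnesses = fitnesses,
                   best_position = best_position, best_fitness = best_fitness,
                   iteration = iteration, trace = trace), extra),
            class = "sc_population")
}

#' @export
print.sc_population <- function(x, ...) {
  cat(sprintf("sc_population: %d individuals, %d dims, %d iterations, best fitness %.6g\n",
              nrow(x$positions), ncol(x$positions), x$iteration, x$best_fitness))
  invisible(x)
}

eval_fitness <- function(fitness, positions) {
  vals <- apply(positions, 1, fitness)
  if (!all(is.finite(vals))) {
    i <- which(!is.finite(vals))[[1]]
    sc_stop("optimizer", "fitness returned a non-finite value",
            data = list(position = positions[i, ]))
  }
  as.numeric(vals)
}

init_positions <- function(n, b) {
  matrix(stats::runif(n * b$d, rep(b$lower, each = n), rep(b$upper, each = n)),
         nrow = n, ncol = b$d)
}

#' Elephant-herding optimisation
#'
#' Single-herd variant. Each iteration every individual moves toward the herd
#' guide by `x + gamma * (guide - x) * rand1` with a fresh `rand1` per
#' individual; the guide is then replaced by `delta` times the herd centre;
#' and the worst-fitness individual is re-seeded uniformly over
#' `lower + (upper - lower + 1) * rand` and clamped back into the bounds.
#' An elitist archive of the true best-so-far is kept, so the reported best
#' fitness is non-increasing. With a population of one the re-seeding step is
#' skipped (the sole individual is simultaneously best and worst).
#'
#' @param fitness Function mapping a position vector to a finite scalar;
#'   minimised.
#' @param b A [bounds()] object.
#' @param params An [eho_params()] object.
#' @param seed Integer seed.
#' @param init Optional matrix of starting positions (rows = individuals);
#'   clamped into the bounds. Defaults to uniform draws over the bounds.
#' @return An `sc_population` with the final positions, the archived best
#'   position/fitness, and the per-iteration best-fitness `trace`.
#' @export
eho_optimize <- function(fitness, b, params = eho_params(), seed = 1,
                         init = NULL) {
  stopifnot(inherits(b, "sc_bounds"), inherits(params, "eho_params"))
  with_seed(seed, {
    x <- if (is.null(init)) init_positions(params$population, b) else clamp(as.matrix(init), b)
    n <- nrow(x)
    f <- eval_fitness(fitness, x)
    best_i <- which.min(f)
    best_x <- x[best_i, ]
    best_f <- f[best_i]
    guide <- best_x
    trace <- numeric(0)
    iter <- 0
    while (iter < params$max_iter && best_f > params$mse_tol) {
      iter <- iter + 1
      rand1 <- stats::runif(n)
      x <- x + params$gamma_control * rand1 *
        (matrix(guide, n, b$d, byrow = TRUE) - x)
      guide <- params$delta_control * colMeans(x)
      f_tmp <- eval_fitness(fitness, x)
      if (n >= 2) {
        worst_i <- which.max(f_tmp)
        x[worst_i, ] <- b$lower + (b$upper - b$lower + 1) * stats::runif(b$d)
      }
      x <- clamp(x, b)
      f <- eval_fitness(fitness, x)
      cand <- which.min(f)
      if (f[cand] < best_f) {
        best_f <- f[cand]
        best_x <- x[cand, ]
      }
      trace <- c(trace, best_f)
    }
    new_population(x, f, best_x, best_f, iter, trace)
  })
}

#' Particle-swarm optimisation
#'
#' Velocity update
#' `v = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh scalar
#' `r1, r2` per particle per iteration, followed by `x <- clamp(x + v)`.
#' Personal and global bests are updated on strict improvement, so the global
#' best trace is non-increasing.
#'
#' @inheritParams eho_optimize
#' @param params A [pso_params()] object.
#' @return An `sc_population`.
#' @export
pso_optimize <- function(fitness, b, params = pso_params(), seed = 1,
                         init = NULL) {
  stopifnot(inherits(b, "sc_bounds"), inherits(params, "pso_params"))
  with_seed(seed, {
    x <- if (is.null(init)) init_positions(params$population, b) else clamp(as.matrix(init), b)
    n <- nrow(x)
    v <- matrix(0, n, b$d)
    f <- eval_fitness(fitness, x)
    pbest_x <- x
    pbest_f <- f
    g_i <- which.min(f)
    gbest_x <- x[g_i, ]
    gbest_f <- f[g_i]
    trace <- numeric(0)
    iter <- 0
    while (iter < params$max_iter && gbest_f > params$mse_tol) {
      iter <- iter + 1
      r1 <- stats::runif(n)
      r2 <- stats::runif(n)
      v <- params$w * v +
        params$c1 * r1 * (pbest_x - x) +
        params$c2 * r2 * (matrix(gbest_x, n, b$d, byrow = TRUE) - x)
      x <- clamp(x + v, b)
      f <- eval_fitness(fitness, x)
      better <- f < pbest_f
      pbest_x[better, ] <- x[better, , drop = FALSE]
      pbest_f[better] <- f[better]
      cand <- which.min(pbest_f)
      if (pbest_f[cand] < gbest_f) {
        gbest_f <- pbest_f[cand]
        gbest_x <- pbest_x[cand, ]
      }
      trace <- c(trace, gbest_f)
    }
    new_population(x, f, gbest_x, gbest_f, iter, trace)
  })
}

#' Firefly optimisation
#'
#' Brightness is the negated fitness, cached at the start of each iteration.
#' For every ordered pair `(i, j)` with `j` strictly brighter than `i`,
#' firefly `i` moves by the attraction term
#' `beta * i0 * exp(-gamma * r_ij^2) * (x_j - x_i)` with `r_ij` the Euclidean
#' distance; each firefly additionally takes one random step
#' `alpha * (U(0,1) - 0.5)` per dimension per iteration. Positions are
#' updated in place in ascending index order and clamped; an elitist archive
#' keeps the best-so-far.
#'
#' @inheritParams eho_optimize
#' @param params A [firefly_params()] object.
#' @return An `sc_population`.
#' @export
firefly_optimize <- function(fitness, b, params = firefly_params(), seed = 1,
                             init = NULL) {
  stopifnot(inherits(b, "sc_bounds"), inherits(params, "firefly_params"))
  with_seed(seed, {
    x <- if (is.null(init)) init_positions(params$population, b) else clamp(as.matrix(init), b)
    n <- nrow(x)
    f <- eval_fitness(fitness, x)
    best_i <- which.min(f)
    best_x <- x[best_i, ]
    best_f <- f[best_i]
    trace <- numeric(0)
    iter <- 0
    while (iter < params$max_iter && best_f > params$mse_tol) {
      iter <- iter + 1
      bright <- -f
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (bright[j] > bright[i]) {
            r2 <- sum((x[j, ] - x[i, ])^2)
            attr_ij <- params$i0 * exp(-params$gamma_absorb * r2)
            x[i, ] <- x[i, ] + params$beta_attract * attr_ij * (x[j, ] - x[i, ])
          }
        }
        x[i, ] <- x[i, ] + params$alpha_rand * (stats::runif(b$d) - 0.5)
        x[i, ] <- clamp(x[i, ], b)
      }
      f <- eval_fitness(fitness, x)
      cand <- which.min(f)
      if (f[cand] < best_f) {
        best_f <- f[cand]
        best_x <- x[cand, ]
      }
      trace <- c(trace, best_f)
    }
    new_population(x, f, best_x, best_f, iter, trace)
  })
}

# Mantegna scale for Levy-flight steps:
# sigma = { G(1+l) sin(pi l / 2) / ( l G((1+l)/2) 2^((l-1)/2) ) }^(1/l)
mantegna_sigma <- function(lambda) {
  num <- gamma(1 + lambda) * sin(pi * lambda / 2)
  den <- lambda * gamma((1 + lambda) / 2) * 2^((lambda - 1) / 2)
  (num / den)^(1 / lambda)
}

levy_transform <- function(u, v, lambda) u / abs(v)^(1 / lambda)

#' Mantegna Levy-flight step sampler
#'
#' Draws heavy-tailed step sizes `s = U / |V|^(1/lambda)` with
#' `U ~ N(0, sigma^2)`, `V ~ N(0, 1)` and the Mantegna scale
#' `sigma = {Gamma(1+lambda) sin(pi lambda/2) /
#' (lambda Gamma((1+lambda)/2) 2^((lambda-1)/2))}^(1/lambda)`.
#'
#' @param lambda Levy exponent in `(1, 2]` (default 1.5).
#' @param seed Optional integer seed; when `NULL` draws use the current RNG
#'   stream (as inside an optimiser run).
#' @return An object of class `levy_sampler` with fields `lambda` and
#'   `sigma`.
#' @export
levy_sampler <- function(lambda = 1.5, seed = NULL) {
  if (lambda <= 1 || lambda > 2) {
    sc_stop("validation", "lambda must lie in (1, 2]")
  }
  structure(list(lambda = lambda, sigma = mantegna_sigma(lambda), seed = seed),
            class = "levy_sampler")
}

#' Draw Levy-flight step sizes
#'
#' @param sampler A [levy_sampler()].
#' @param count Number of steps to draw.
#' @return Numeric vector of `count` step sizes; deterministic when the
#'   sampler carries a seed.
#' @export
levy_sample <- function(sampler, count) {
  stopifnot(inherits(sampler, "levy_sampler"))
  draw <- function() {
    u <- stats::rnorm(count, 0, sampler$sigma)
    v <- stats::rnorm(count)
    levy_transform(u, v, sampler$lambda)
  }
  if (is.null(sampler$seed)) draw() else with_seed(sampler$seed, draw())
}

#' Flower-pollination optimisation with Levy flights
#'
#' Each individual each iteration takes, with probability `switch_prob`, a
#' global pollination step `x + delta * L * (gbest - x)` with one Mantegna
#' Levy draw `L` per dimension, and otherwise a local pollination step
#' `x + eps * (x_j - x_k)` with `eps ~ U(0,1)` and `j, k` sampled uniformly
#' without replacement from the other individuals. Moves are clamped and
#' accepted greedily (kept only when fitness improves), so the best-fitness
#' trace is non-increasing.
#'
#' @inheritParams eho_optimize
#' @param params An [fpo_params()] object.
#' @return An `sc_population`; the extra fields `n_global` and `n_local`
#'   count the step types taken.
#' @export
fpo_optimize <- function(fitness, b, params = fpo_params(), seed = 1,
                         init = NULL) {
  stopifnot(inherits(b, "sc_bounds"), inherits(params, "fpo_params"))
  n <- if (is.null(init)) params$population else nrow(init)
  if (n < 3) {
    sc_stop("validation",
            "population must be >= 3 so local pollination can draw distinct j, k")
  }
  sigma <- mantegna_sigma(params$levy_lambda)
  with_seed(seed, {
    x <- if (is.null(init)) init_positions(n, b) else clamp(as.matrix(init), b)
    f <- eval_fitness(fitness, x)
    g_i <- which.min(f)
    gbest_x <- x[g_i, ]
    gbest_f <- f[g_i]
    trace <- numeric(0)
    n_global <- 0L
    n_local <- 0L
    iter <- 0
    while (iter < params$max_iter && gbest_f > params$mse_tol) {
      iter <- iter + 1
      for (i in seq_len(n)) {
        if (stats::runif(1) < params$switch_prob) {
          levy <- levy_transform(stats::rnorm(b$d, 0, sigma), stats::rnorm(b$d),
                                 params$levy_lambda)
          cand <- x[i, ] + params$step_delta * levy * (gbest_x - x[i, ])
          n_global <- n_global + 1L
        } else {
          jk <- sample(setdiff(seq_len(n), i), 2)
          cand <- x[i, ] + stats::runif(1) * (x[jk[1], ] - x[jk[2], ])
          n_local <- n_local + 1L
        }
        cand <- clamp(cand, b)
        f_cand <- fitness(cand)
        if (!is.finite(f_cand)) {
          sc_stop("optimizer", "fitness returned a non-finite value",
                  data = list(position = cand))
        }
        if (f_cand < f[i]) {
          x[i, ] <- cand
          f[i] <- f_cand
          if (f_cand < gbest_f) {
            gbest_f <- f_cand
            gbest_x <- cand
          }
        }
      }
      trace <- c(trace, gbest_f)
    }
    new_population(x, f, gbest_x, gbest_f, iter, trace,
                   extra = list(n_global = n_global, n_local = n_local))
  })
}
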