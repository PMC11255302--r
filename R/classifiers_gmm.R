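# Gaussian mixture classifier: per-class EM fit, Bayes prediction, and
# metaheuristic-tuned hybrids.

feature_values <- function(features, labels = NULL) {
  if (inherits(features, "feature_matrix")) {
    list(x = features$values, labels = features$labels)
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) sc_stop("validation", "labels are required with a plain matrix")
    list(x = x, labels = check_labels(labels, nrow(x)))
  }
}

# Shrink toward the diagonal (intensity growing with D relative to the class
# size) plus a trace-scaled ridge, escalated until the Cholesky succeeds.
regularize_cov <- function(s_mat, n_c, ridge_frac = 1e-6) {
  d <- nrow(s_mat)
  shrink <- d / (d + n_c)
  s_mat <- (1 - shrink) * s_mat + shrink * diag(diag(s_mat), d)
  ridge <- max(ridge_frac * sum(diag(s_mat)) / d, 1e-12)
  for (k in 1:30) {
    ok <- tryCatch({ chol(s_mat + diag(ridge, d)); TRUE },
                   error = function(e) FALSE)
    if (ok) return(s_mat + diag(ridge, d))
    ridge <- ridge * 10
  }
  sc_stop("numerical", "covariance could not be regularised to positive definite")
}

mvn_log_density <- function(x, mean, cov_chol) {
  d <- length(mean)
  z <- backsolve(cov_chol, t(x) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(cov_chol))) - 0.5 * d * log(2 * pi)
}

# k-means++ style seeding: spread initial centres, then one k-means pass.
kmeanspp_centers <- function(x, g) {
  n <- nrow(x)
  centers <- matrix(NA_real_, g, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (g > 1) {
    for (k in 2:g) {
      d2 <- apply(x, 1, function(row) {
        min(colSums((t(centers[1:(k - 1), , drop = FALSE]) - row)^2))
      })
      if (sum(d2) <= 0) {
        centers[k, ] <- x[sample.int(n, 1), ]
      } else {
        centers[k, ] <- x[sample.int(n, 1, prob = d2), ]
      }
    }
  }
  centers
}

fit_class_mixture <- function(x, g, max_iter = 100, tol = 1e-7) {
  n <- nrow(x)
  d <- ncol(x)
  centers <- kmeanspp_centers(x, g)
  assign <- apply(x, 1, function(row) {
    which.min(colSums((t(centers) - row)^2))
  })
  weights <- tabulate(assign, g) / n
  weights[weights == 0] <- 1e-6
  weights <- weights / sum(weights)
  means <- matrix(NA_real_, g, d)
  covs <- vector("list", g)
  pooled <- regularize_cov(stats::cov(x) * (n - 1) / n, n)
  for (k in seq_len(g)) {
    rows <- which(assign == k)
    means[k, ] <- if (length(rows) > 0) colMeans(x[rows, , drop = FALSE]) else x[sample.int(n, 1), ]
    covs[[k]] <- if (length(rows) > d) {
      regularize_cov(stats::cov(x[rows, , drop = FALSE]) * (length(rows) - 1) / length(rows),
                     length(rows))
    } else {
      pooled
    }
  }
  loglik_trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step
    logd <- vapply(seq_len(g), function(k) {
      log(weights[k]) + mvn_log_density(x, means[k, ], chol(covs[[k]]))
    }, numeric(n))
    logd <- matrix(logd, n, g)
    row_lse <- apply(logd, 1, log_sum_exp)
    loglik <- sum(row_lse)
    loglik_trace <- c(loglik_trace, loglik)
    resp <- exp(logd - row_lse)
    # M-step
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    weights <- nk / n
    for (k in seq_len(g)) {
      means[k, ] <- colSums(resp[, k] * x) / nk[k]
      xc <- sweep(x, 2, means[k, ])
      covs[[k]] <- regularize_cov(crossprod(xc * sqrt(resp[, k]), xc * sqrt(resp[, k])) / nk[k],
                                  nk[k])
    }
    if (is.finite(prev) && abs(loglik - prev) < tol * (abs(prev) + 1)) break
    prev <- loglik
  }
  list(weights = weights, means = means, covs = covs,
       loglik_trace = loglik_trace)
}

#' Fit a per-class Gaussian mixture classifier
#'
#' Fits, independently for each class, a `G`-component Gaussian mixture by
#' expectation-maximisation with k-means++ seeded initialisation and
#' regularised full covariances (shrinkage toward the diagonal that grows
#' with the dimension-to-class-size ratio, plus a trace-scaled ridge).
#' Class priors are the class frequencies. The per-class log-likelihood is
#' recorded every EM step and is non-decreasing.
#'
#' @param features A [feature_matrix()], or a plain samples x features
#'   matrix with `labels` supplied.
#' @param labels Per-sample labels when `features` is a plain matrix.
#' @param G Components per class (default 2); each class needs at least `G`
#'   samples.
#' @param seed Integer seed for the initialisation.
#' @return An object of class `gmm_class_model`.
#' @export
gmm_fit <- function(features, labels = NULL, G = 2, seed = 1) {
  fv <- feature_values(features, labels)
  x <- fv$x
  labels <- fv$labels
  d <- ncol(x)
  if (d < 1) sc_stop("validation", "need at least one feature")
  classes <- list()
  with_seed(seed, {
    for (cls in CLASS_LEVELS) {
      rows <- which(labels == cls)
      if (length(rows) < G) {
        sc_stop("validation", "class '%s' has %d samples but G = %d",
                cls, length(rows), G)
      }
      classes[[cls]] <- fit_class_mixture(x[rows, , drop = FALSE], G)
    }
  })
  priors <- c(cancer = mean(labels == "cancer"),
              normal = mean(labels == "normal"))
  structure(list(classes = classes, priors = priors, G = G, D = d),
            class = "gmm_class_model")
}

class_log_density <- function(cm, x) {
  n <- nrow(x)
  g <- length(cm$weights)
  logd <- vapply(seq_len(g), function(k) {
    log(cm$weights[k]) + mvn_log_density(x, cm$means[k, ], chol(cm$covs[[k]]))
  }, numeric(n))
  apply(matrix(logd, n, g), 1, log_sum_exp)
}

#' Predict with a Gaussian mixture classifier
#'
#' Posterior proportional to class prior times mixture density, normalised
#' per sample. The label is the posterior argmax (ties to cancer) and the
#' continuous score is the posterior-weighted combination of the class
#' targets, `p(normal|f) t_normal + p(cancer|f) t_cancer`.
#'
#' @param model A `gmm_class_model` (or the model inside a hybrid fit).
#' @param features A [feature_matrix()] or samples x features matrix with
#'   the model's dimensionality.
#' @param scheme A [target_scheme()].
#' @return List with `labels`, a samples x 2 `posteriors` matrix (columns
#'   cancer, normal), and continuous `scores`.
#' @export
gmm_predict <- function(model, features, scheme = target_scheme()) {
  stopifnot(inherits(model, "gmm_class_model"))
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (ncol(x) != model$D) {
    sc_stop("validation", "feature dimensionality %d does not match model D = %d",
            ncol(x), model$D)
  }
  ll <- cbind(
    cancer = log(model$priors[["cancer"]]) + class_log_density(model$classes$cancer, x),
    normal = log(model$priors[["normal"]]) + class_log_density(model$classes$normal, x)
  )
  m <- pmax(ll[, 1], ll[, 2])
  post <- exp(ll - m)
  post <- post / rowSums(post)
  labels <- ifelse(post[, "cancer"] >= post[, "normal"], "cancer", "normal")
  scores <- post[, "normal"] * scheme$t_normal + post[, "cancer"] * scheme$t_cancer
  list(labels = labels, posteriors = post, scores = scores)
}

# ---- hybrid (metaheuristic-tuned) GMM -------------------------------------

# Decision vector layout per class: G*D means, G*D log diagonal variances,
# G weight logits.
hybrid_encode <- function(model) {
  unlist(lapply(model$classes, function(cm) {
    c(as.vector(t(cm$means)),
      log(pmax(t(vapply(cm$covs, diag, numeric(ncol(cm$means)))), 1e-12)),
      log(pmax(cm$weights, 1e-12)))
  }), use.names = FALSE)
}

hybrid_decode_raw <- function(v, G, D) {
  per_class <- G * D * 2 + G
  out <- list()
  for (ci in seq_along(CLASS_LEVELS)) {
    off <- (ci - 1) * per_class
    means <- matrix(v[off + seq_len(G * D)], G, D, byrow = TRUE)
    vars <- matrix(exp(v[off + G * D + seq_len(G * D)]), G, D)
    logits <- v[off + 2 * G * D + seq_len(G)]
    w <- exp(logits - max(logits))
    out[[CLASS_LEVELS[ci]]] <- list(means = means, vars = pmax(vars, 1e-12),
                                    weights = w / sum(w))
  }
  out
}

hybrid_decode_model <- function(v, G, D, priors) {
  raw <- hybrid_decode_raw(v, G, D)
  classes <- lapply(raw, function(cm) {
    list(weights = cm$weights, means = cm$means,
         covs = lapply(seq_len(G), function(k) diag(cm$vars[k, ], D)),
         loglik_trace = numeric(0))
  })
  structure(list(classes = classes, priors = priors, G = G, D = D),
            class = "gmm_class_model")
}

# Fast diagonal-covariance scorer used as the optimiser fitness.
hybrid_scores <- function(raw, priors, x, scheme) {
  n <- nrow(x)
  xt <- t(x)
  class_ll <- vapply(CLASS_LEVELS, function(cls) {
    cm <- raw[[cls]]
    g <- length(cm$weights)
    comp <- vapply(seq_len(g), function(k) {
      log(cm$weights[k]) -
        0.5 * colSums((xt - cm$means[k, ])^2 / cm$vars[k, ]) -
        0.5 * sum(log(2 * pi * cm$vars[k, ]))
    }, numeric(n))
    apply(matrix(comp, n, g), 1, log_sum_exp) + log(priors[[cls]])
  }, numeric(n))
  class_ll <- matrix(class_ll, n, 2)
  m <- pmax(class_ll[, 1], class_ll[, 2])
  p <- exp(class_ll - m)
  p_cancer <- p[, 1] / (p[, 1] + p[, 2])
  (1 - p_cancer) * scheme$t_normal + p_cancer * scheme$t_cancer
}

#' Tune a Gaussian mixture classifier with a swarm optimiser
#'
#' Starts from the EM solution of [gmm_fit()], flattens the per-class
#' parameters (means, log diagonal covariances, weight logits) into a
#' decision vector, and minimises the training mean squared error between
#' the model's continuous scores and the per-sample class targets using
#' particle swarm, firefly, or flower-pollination optimisation. The
#' optimiser population is initialised around the EM solution (the EM vector
#' itself is included), so the returned model never has higher training MSE
#' than the EM initialisation. A zero-iteration budget returns the EM
#' initialisation unchanged.
#'
#' @param features A [feature_matrix()] or matrix with `labels`.
#' @param labels Labels when `features` is a plain matrix.
#' @param optimizer One of `"pso"`, `"firefly"`, `"fpo"`.
#' @param params Optimiser parameters ([pso_params()], [firefly_params()],
#'   or [fpo_params()]); defaults to that family's standard configuration.
#' @param scheme A [target_scheme()].
#' @param G Components per class.
#' @param seed Integer seed.
#' @return An object of class `hybrid_gmm_model` containing the tuned
#'   `model`, the optimiser tag, the fitness `trace`, and the initial and
#'   final training MSE.
#' @export
hybrid_gmm_fit <- function(features, labels = NULL,
                           optimizer = c("pso", "firefly", "fpo"),
                           params = NULL, scheme = target_scheme(), G = 2,
                           seed = 1) {
  optimizer <- match.arg(optimizer)
  fv <- feature_values(features, labels)
  x <- fv$x
  labels <- fv$labels
  base <- gmm_fit(x, labels, G = G, seed = seed)
  D <- base$D
  v0 <- hybrid_encode(base)
  targets <- ifelse(labels == "cancer", scheme$t_cancer, scheme$t_normal)
  fitness <- function(v) {
    raw <- hybrid_decode_raw(v, G, D)
    mean((targets - hybrid_scores(raw, base$priors, x, scheme))^2)
  }
  init_mse <- fitness(v0)

  if (is.null(params)) {
    params <- switch(optimizer, pso = pso_params(), firefly = firefly_params(),
                     fpo = fpo_params())
  }
  if (params$max_iter == 0) {
    model <- hybrid_decode_model(v0, G, D, base$priors)
    return(structure(list(model = model, optimizer = optimizer,
                          params = params, vector = v0, trace = numeric(0),
                          init_mse = init_mse, final_mse = init_mse),
                     class = "hybrid_gmm_model"))
  }

  feat_sd <- apply(x, 2, stats::sd)
  feat_sd[!is.finite(feat_sd) | feat_sd < 1e-6] <- 1
  half_class <- c(rep(pmax(2 * feat_sd, 0.5), G), rep(2, G * D), rep(3, G))
  half <- rep(half_class, length(CLASS_LEVELS))
  b <- bounds(v0 - half, v0 + half)
  n_pop <- params$population
  init <- with_seed(seed + 1L, {
    pert <- matrix(stats::runif(n_pop * length(v0), -0.1, 0.1), n_pop) *
      matrix(half, n_pop, length(v0), byrow = TRUE)
    sweep(pert, 2, v0, "+")
  })
  init[1, ] <- v0
  opt_fun <- switch(optimizer, pso = pso_optimize, firefly = firefly_optimize,
                    fpo = fpo_optimize)
  pop <- opt_fun(fitness, b, params, seed = seed, init = init)
  best_v <- if (pop$best_fitness <= init_mse) pop$best_position else v0
  final_mse <- min(pop$best_fitness, init_mse)
  model <- hybrid_decode_model(best_v, G, D, base$priors)
  structure(list(model = model, optimizer = optimizer, params = params,
                 vector = best_v, trace = pop$trace, init_mse = init_mse,
                 final_mse = final_mse),
            class = "hybrid_gmm_model")
}

#' @export
print.hybrid_gmm_model <- function(x, ...) {
  cat(sprintf("hybrid_gmm_model [%s]: training MSE %.6g (EM init %.6g)\n",
              x$optimizer, x$final_mse, x$init_mse))
  invisible(x)
}
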