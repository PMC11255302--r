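#' Feature matrix container
#'
#' Samples x features output of an extractor, with provenance (method tag,
#' parameter snapshot, selected gene indices where applicable) and the
#' sample labels carried through in dataset order.
#'
#' @param values Numeric samples x features matrix (finite).
#' @param feature_names Character vector, one name per column.
#' @param method Extractor tag (e.g. `"stft"`, `"lasso"`, `"eho"`).
#' @param params List snapshot of the extractor configuration.
#' @param labels Per-sample class labels.
#' @param sample_ids Sample identifiers, aligned with rows.
#' @param selected_gene_indices Optional integer vector of retained gene
#'   indices (selection-type extractors).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_names, method, params, labels,
                           sample_ids, selected_gene_indices = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    sc_stop("validation", "feature matrix contains non-finite values")
  }
  if (ncol(values) != length(feature_names)) {
    sc_stop("structural", "feature name count does not match column count")
  }
  labels <- check_labels(labels, nrow(values))
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 method = method, params = params, labels = labels,
                 sample_ids = sample_ids,
                 selected_gene_indices = selected_gene_indices),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d samples x %d features\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Short-time Fourier transform configuration
#'
#' @param window_length Window length M (default 256).
#' @param hop Frame advance (default `window_length / 2`).
#' @param statistics Per-frame aggregation statistics of the magnitude
#'   spectrum, a subset of `c("mean_mod", "max_mod", "energy")`.
#' @param window `"blackman"` (default) or `"rectangular"`.
#' @param zero_pad Pad the signal tail with zeros so the final partial frame
#'   is included (default TRUE).
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_length = 256, hop = window_length / 2,
                        statistics = c("mean_mod", "max_mod", "energy"),
                        window = c("blackman", "rectangular"),
                        zero_pad = TRUE) {
  window <- match.arg(window)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (window_length < 1) sc_stop("validation", "window_length must be >= 1")
  if (hop < 1 || hop > window_length) {
    sc_stop("validation", "hop must satisfy 0 < hop <= window_length")
  }
  structure(list(window_length = as.integer(window_length),
                 hop = as.integer(hop), statistics = statistics,
                 window = window, zero_pad = zero_pad),
            class = "stft_config")
}

#' Blackman window
#'
#' `w[n] = 0.42 - 0.5 cos(2 pi n / M) + 0.08 cos(4 pi n / M)` for
#' `n = 0, ..., M - 1`.
#'
#' @param m Window length M (>= 1).
#' @return Numeric vector of M window coefficients.
#' @export
blackman_window <- function(m) {
  if (m < 1) sc_stop("validation", "window length must be >= 1")
  n <- seq_len(m) - 1
  0.42 - 0.5 * cos(2 * pi * n / m) + 0.08 * cos(4 * pi * n / m)
}

stft_n_frames <- function(n, m, hop, zero_pad) {
  if (zero_pad) {
    if (n <= m) 1L else as.integer(ceiling((n - m) / hop) + 1)
  } else {
    if (n < m) sc_stop("validation", "signal shorter than window and zero_pad is disabled")
    as.integer(floor((n - m) / hop) + 1)
  }
}

#' Short-time Fourier transform of a signal
#'
#' Frame `t` starts at offset `t * hop` (zero-based); each frame is
#' multiplied by the window and discrete-Fourier transformed. With
#' `zero_pad = TRUE` the tail is padded with zeros so the final partial
#' frame is included.
#'
#' @param signal Numeric vector.
#' @param config An [stft_config()].
#' @return Complex matrix of shape `n_frames x window_length`.
#' @export
stft <- function(signal, config = stft_config()) {
  stopifnot(inherits(config, "stft_config"))
  if (length(signal) == 0) sc_stop("validation", "empty signal")
  m <- config$window_length
  n_frames <- stft_n_frames(length(signal), m, config$hop, config$zero_pad)
  needed <- (n_frames - 1) * config$hop + m
  if (needed > length(signal)) {
    signal <- c(signal, numeric(needed - length(signal)))
  }
  w <- if (config$window == "blackman") blackman_window(m) else rep(1, m)
  out <- matrix(complex(real = 0), n_frames, m)
  for (t in seq_len(n_frames)) {
    start <- (t - 1) * config$hop + 1
    out[t, ] <- stats::fft(signal[start:(start + m - 1)] * w)
  }
  out
}

#' Spectral features from an expression dataset
#'
#' Treats each sample's gene-intensity vector (genes in file order) as a
#' sequence, computes its windowed spectrum with [stft()], and emits the
#' configured per-frame statistics of the magnitude spectrum: mean |X|,
#' max |X|, and spectral energy `sum(|X|^2)`. The feature count is
#' `n_frames * length(statistics)`.
#'
#' @param dataset An [expression_dataset()].
#' @param config An [stft_config()].
#' @return A [feature_matrix()] with method tag `"stft"`.
#' @export
stft_features <- function(dataset, config = stft_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n_genes <- nrow(dataset$values)
  n_frames <- stft_n_frames(n_genes, config$window_length, config$hop,
                            config$zero_pad)
  stats_fun <- list(
    mean_mod = function(mod) mean(mod),
    max_mod = function(mod) max(mod),
    energy = function(mod) sum(mod^2)
  )
  n_stats <- length(config$statistics)
  values <- matrix(NA_real_, ncol(dataset$values), n_frames * n_stats)
  for (s in seq_len(ncol(dataset$values))) {
    spec <- stft(dataset$values[, s], config)
    mod <- Mod(spec)
    row <- numeric(0)
    for (t in seq_len(n_frames)) {
      row <- c(row, vapply(config$statistics,
                           function(st) stats_fun[[st]](mod[t, ]), numeric(1)))
    }
    values[s, ] <- row
  }
  feature_names <- as.vector(t(outer(seq_len(n_frames), config$statistics,
                                     function(t, st) sprintf("frame%02d_%s", t, st))))
  feature_matrix(values, feature_names, "stft",
                 params = unclass(config), labels = dataset$labels,
                 sample_ids = dataset$sample_ids)
}

#' Lasso configuration
#'
#' @param lambda_grid Optional descending positive penalty grid; when `NULL`
#'   a 50-point logarithmic grid from `lambda_max = max |X'y| / n` down to
#'   `lambda_min_ratio * lambda_max` is built per dataset.
#' @param n_lambda Grid size when the grid is built automatically.
#' @param lambda_min_ratio Ratio of the smallest to the largest grid value.
#' @param cv_folds Cross-validation folds for penalty selection (default 10).
#' @param tol Coordinate-descent convergence threshold on the maximum
#'   coefficient change per sweep (default 1e-6).
#' @param max_iter Maximum coordinate-descent sweeps (default 1e4).
#' @param target_n_features Optional cap: select the penalty as the smallest
#'   grid value with at most this many nonzero coefficients instead of by
#'   cross-validation.
#' @return An object of class `lasso_config`.
#' @export
lasso_config <- function(lambda_grid = NULL, n_lambda = 50,
                         lambda_min_ratio = 1e-3, cv_folds = 10, tol = 1e-6,
                         max_iter = 1e4, target_n_features = NULL) {
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid), strictly = TRUE)) {
      sc_stop("validation", "lambda_grid must be strictly positive and descending")
    }
  }
  structure(list(lambda_grid = lambda_grid, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, cv_folds = cv_folds,
                 tol = tol, max_iter = as.integer(max_iter),
                 target_n_features = target_n_features),
            class = "lasso_config")
}

#' Lasso fit by cyclic coordinate descent
#'
#' Minimises `(1/(2n)) ||y - X beta||^2 + lambda ||beta||_1` by cyclic
#' coordinate descent with soft-thresholding, converged when the largest
#' coefficient change in a sweep falls below `config$tol`. Predictor columns
#' must be standardised (mean 0); the response should be centred.
#'
#' @param x Standardised n x p predictor matrix.
#' @param y Centred response vector.
#' @param lambda Non-negative penalty.
#' @param config A [lasso_config()].
#' @param beta0 Optional warm-start coefficient vector.
#' @return Coefficient vector of length p, with the per-sweep objective
#'   values in `attr(, "objective_trace")`.
#' @export
lasso_fit <- function(x, y, lambda, config = lasso_config(), beta0 = NULL) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) sc_stop("validation", "length(y) != nrow(x)")
  if (lambda < 0) sc_stop("validation", "lambda must be >= 0")
  mu <- colMeans(x)
  if (any(abs(mu) > 1e-8)) {
    j <- which.max(abs(mu))
    sc_stop("validation",
            "predictor column %d is not standardised (mean %.3g; expected 0)",
            j, mu[j])
  }
  if (is.null(beta0)) beta0 <- numeric(ncol(x))
  .lasso_cd(x, as.numeric(y), lambda, as.numeric(beta0), config$tol,
            config$max_iter)
}

build_lambda_grid <- function(x, y, config) {
  if (!is.null(config$lambda_grid)) return(config$lambda_grid)
  lambda_max <- max(abs(crossprod(x, y))) / nrow(x)
  exp(seq(log(lambda_max), log(config$lambda_min_ratio * lambda_max),
          length.out = config$n_lambda))
}

lasso_path <- function(x, y, grid, config) {
  p <- ncol(x)
  betas <- matrix(0, p, length(grid))
  beta <- numeric(p)
  for (k in seq_along(grid)) {
    beta <- lasso_fit(x, y, grid[k], config, beta0 = beta)
    betas[, k] <- beta
  }
  betas
}

#' Embedded gene selection by the lasso
#'
#' Encodes the binary labels as a -1/+1 response (cancer = +1), standardises
#' genes, and fits the full lasso path over a descending penalty grid with
#' warm starts. The penalty is chosen by `cv_folds`-fold cross-validated
#' squared error, or, when `config$target_n_features` is set, as the
#' smallest grid value whose active set has at most that many genes. The
#' returned features are the raw intensities of the selected genes.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [lasso_config()].
#' @param seed Integer seed for the cross-validation folds.
#' @return A [feature_matrix()] with method tag `"lasso"` and the selected
#'   gene indices recorded.
#' @export
lasso_features <- function(dataset, config = lasso_config(), seed = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  labels <- dataset$labels
  if (length(unique(labels)) < 2) {
    sc_stop("validation", "label vector is constant; need both classes")
  }
  y_raw <- ifelse(labels == "cancer", 1, -1)
  y <- y_raw - mean(y_raw)
  xs <- scale(t(dataset$values))
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  xs <- as.matrix(xs)
  grid <- build_lambda_grid(xs, y, config)

  if (!is.null(config$target_n_features)) {
    betas <- lasso_path(xs, y, grid, config)
    nnz <- colSums(betas != 0)
    ok <- which(nnz > 0 & nnz <= config$target_n_features)
    if (length(ok) == 0) {
      sc_stop("selection",
              "no grid penalty yields between 1 and %d features; lower the penalty floor",
              config$target_n_features)
    }
    best_k <- max(ok)  # smallest penalty within the cap
    beta <- betas[, best_k]
  } else {
    n <- nrow(xs)
    x_raw <- t(dataset$values)
    folds <- with_seed(seed, sample(rep_len(seq_len(config$cv_folds), n)))
    cv_err <- matrix(NA_real_, config$cv_folds, length(grid))
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      st <- standardize_fit(x_raw[tr, , drop = FALSE])
      xtr <- standardize_apply(x_raw[tr, , drop = FALSE], st)
      xva <- standardize_apply(x_raw[!tr, , drop = FALSE], st)
      ytr <- y_raw[tr] - mean(y_raw[tr])
      yva <- y_raw[!tr] - mean(y_raw[tr])
      betas_f <- lasso_path(xtr, ytr, grid, config)
      pred <- xva %*% betas_f
      cv_err[f, ] <- colMeans((yva - pred)^2)
    }
    best_k <- which.min(colMeans(cv_err))
    beta <- lasso_fit(xs, y, grid[best_k], config)
    if (all(beta == 0)) {
      nz_any <- lasso_path(xs, y, grid, config)
      if (all(nz_any == 0)) {
        sc_stop("selection",
                "all coefficients are zero at every grid penalty; lower the penalty floor")
      }
      best_k <- which(colSums(nz_any != 0) > 0)[1]
      beta <- nz_any[, best_k]
    }
  }
  sel <- sort(which(beta != 0))
  feature_matrix(t(dataset$values[sel, , drop = FALSE]),
                 dataset$gene_ids[sel], "lasso",
                 params = c(unclass(config), list(lambda = grid[best_k], seed = seed)),
                 labels = labels, sample_ids = dataset$sample_ids,
                 selected_gene_indices = sel)
}

#' Elephant-herding wrapper configuration
#'
#' @param n_select Number of genes to retain.
#' @param eho A [eho_params()] controlling the wrapper search.
#' @return An object of class `eho_feature_config`.
#' @export
eho_feature_config <- function(n_select = 20,
                               eho = eho_params(population = 30, max_iter = 100)) {
  if (n_select < 1) sc_stop("validation", "n_select must be >= 1")
  structure(list(n_select = as.integer(n_select), eho = eho),
            class = "eho_feature_config")
}

# Lightweight wrapper fitness: training-resubstitution MSE of a
# single-Gaussian-per-class scorer against the class targets.
subset_fitness_factory <- function(values, labels, scheme) {
  is_cancer <- labels == "cancer"
  prior_c <- mean(is_cancer)
  targets <- ifelse(is_cancer, scheme$t_cancer, scheme$t_normal)
  function(subset) {
    x <- t(values[subset, , drop = FALSE])
    st <- standardize_fit(x)
    x <- standardize_apply(x, st)
    score_gauss <- function(rows) {
      mu <- colMeans(x[rows, , drop = FALSE])
      v <- apply(x[rows, , drop = FALSE], 2, stats::var)
      v <- pmax(v, 1e-6)
      -0.5 * colSums((t(x) - mu)^2 / v) - 0.5 * sum(log(2 * pi * v))
    }
    ll_c <- score_gauss(is_cancer) + log(prior_c)
    ll_n <- score_gauss(!is_cancer) + log(1 - prior_c)
    m <- pmax(ll_c, ll_n)
    p_c <- exp(ll_c - m) / (exp(ll_c - m) + exp(ll_n - m))
    score <- (1 - p_c) * scheme$t_normal + p_c * scheme$t_cancer
    mean((targets - score)^2)
  }
}

top_k_subset <- function(position, k) sort(order(position, decreasing = TRUE)[seq_len(k)])

#' Wrapper gene selection by elephant-herding optimisation
#'
#' Each herd position is a continuous score vector in `[0, 1]` per gene; the
#' candidate subset is the `n_select` top-scoring genes, and the wrapper
#' fitness is the training-resubstitution mean squared error of a
#' single-Gaussian-per-class scorer (diagonal covariances) against the class
#' targets. [eho_optimize()] minimises this fitness; the returned features
#' are the raw intensities of the best subset found.
#'
#' @param dataset An [expression_dataset()].
#' @param config An [eho_feature_config()].
#' @param seed Integer seed.
#' @param scheme A [target_scheme()] supplying the class targets.
#' @return A [feature_matrix()] with method tag `"eho"`, the selected gene
#'   indices, and the optimiser run in `attr(, "optimizer")`.
#' @export
eho_features <- function(dataset, config = eho_feature_config(), seed = 1,
                         scheme = target_scheme()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n_genes <- nrow(dataset$values)
  if (config$n_select > n_genes) {
    sc_stop("validation", "n_select (%d) exceeds the gene count (%d)",
            config$n_select, n_genes)
  }
  subset_fit <- subset_fitness_factory(dataset$values, dataset$labels, scheme)
  if (config$n_select == n_genes) {
    sel <- seq_len(n_genes)
    pop <- NULL
  } else {
    fitness <- function(pos) subset_fit(top_k_subset(pos, config$n_select))
    pop <- eho_optimize(fitness, bounds(rep(0, n_genes), rep(1, n_genes)),
                        config$eho, seed = seed)
    sel <- top_k_subset(pop$best_position, config$n_select)
  }
  fm <- feature_matrix(t(dataset$values[sel, , drop = FALSE]),
                       dataset$gene_ids[sel], "eho",
                       params = list(n_select = config$n_select,
                                     eho = unclass(config$eho), seed = seed),
                       labels = dataset$labels, sample_ids = dataset$sample_ids,
                       selected_gene_indices = sel)
  attr(fm, "optimizer") <- pop
  fm
}

#' Write a feature matrix as TSV with a JSON provenance sidecar
#'
#' @param fm A [feature_matrix()].
#' @param path Destination TSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  tab <- data.frame(sample_id = fm$sample_ids, label = fm$labels,
                    fm$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(method = fm$method, params = fm$params,
               selected_gene_indices = fm$selected_gene_indices,
               n_samples = nrow(fm$values), n_features = ncol(fm$values))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
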