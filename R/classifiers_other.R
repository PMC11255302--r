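# Detrended fluctuation analysis, Gaussian naive Bayes, and the RBF support
# vector machine.

#' Detrended fluctuation analysis configuration
#'
#' @param scale_ratio Geometric ratio between successive window sizes
#'   (default 1.6); the ladder holds strictly increasing integers from
#'   `min_scale` up to a quarter of the series length.
#' @param min_scale Smallest window size (default 4).
#' @param poly_order Detrending polynomial order per window (default 1,
#'   linear).
#' @param overlap Fractional window overlap (default 0.5).
#' @return An object of class `dfa_config`.
#' @export
dfa_config <- function(scale_ratio = 1.6, min_scale = 4, poly_order = 1,
                       overlap = 0.5) {
  if (scale_ratio <= 1) sc_stop("validation", "scale_ratio must exceed 1")
  if (min_scale < 4) sc_stop("validation", "min_scale must be >= 4")
  if (overlap < 0 || overlap >= 1) sc_stop("validation", "overlap must lie in [0, 1)")
  structure(list(scale_ratio = scale_ratio, min_scale = as.integer(min_scale),
                 poly_order = as.integer(poly_order), overlap = overlap),
            class = "dfa_config")
}

dfa_scales <- function(n, config) {
  ladder <- function(cap) {
    scales <- integer(0)
    s <- config$min_scale
    while (s <= cap) {
      scales <- c(scales, s)
      s <- max(s + 1L, as.integer(round(s * config$scale_ratio)))
    }
    scales
  }
  scales <- ladder(n %/% 4)
  # short series: relax the quarter-length cap to half-length so the
  # log-log slope remains identifiable (needs at least two window sizes)
  if (length(scales) < 2) scales <- ladder(n %/% 2)
  scales
}

#' Detrended fluctuation scaling exponent
#'
#' Integrates the mean-centred series into the profile
#' `y(k) = sum_{i<=k} (B(i) - mean(B))`, splits it into windows of each
#' ladder size with the configured overlap, removes a least-squares
#' polynomial trend per window, and computes the root-mean-square
#' fluctuation `F(n)`. The exponent is the least-squares slope of
#' `log F(n)` against `log n`. A constant series gives a zero profile; the
#' exponent is then reported as 0 with the `"degenerate"` attribute set.
#'
#' @param series Numeric vector, length at least four times the smallest
#'   window.
#' @param config A [dfa_config()].
#' @return The scaling exponent (white noise is near 0.5, integrated white
#'   noise near 1.5), with attributes `scales`, `fluctuation`, and
#'   `degenerate`.
#' @export
dfa_exponent <- function(series, config = dfa_config()) {
  stopifnot(inherits(config, "dfa_config"))
  n <- length(series)
  if (n < 4 * config$min_scale) {
    sc_stop("validation", "series length %d is below 4 x min_scale = %d",
            n, 4 * config$min_scale)
  }
  scales <- dfa_scales(n, config)
  if (length(scales) < 2) {
    sc_stop("validation", "series too short for at least two window scales")
  }
  y <- cumsum(series - mean(series))
  fluct <- vapply(scales, function(s) {
    step <- max(1L, as.integer(round(s * (1 - config$overlap))))
    starts <- seq(1L, n - s + 1L, by = step)
    t_in <- seq_len(s)
    design <- stats::poly(t_in, degree = config$poly_order, raw = TRUE)
    design <- cbind(1, design)
    ss <- 0
    for (st in starts) {
      seg <- y[st:(st + s - 1L)]
      fit <- stats::lm.fit(design, seg)
      ss <- ss + sum(fit$residuals^2)
    }
    sqrt(ss / (length(starts) * s))
  }, numeric(1))
  degenerate <- all(fluct < 1e-12)
  if (degenerate) {
    expo <- 0
  } else {
    keep <- fluct > 1e-300
    expo <- unname(stats::coef(stats::lm(log(fluct[keep]) ~ log(scales[keep])))[2])
  }
  structure(expo, scales = scales, fluctuation = fluct, degenerate = degenerate)
}

#' Nearest-mean classification on detrended fluctuation exponents
#'
#' Learns the mean scaling exponent of each class on the training samples
#' (each sample's feature vector is treated as a series) and assigns a test
#' sample to the class whose mean exponent is nearer. Ties, including a test
#' exponent exactly at the midpoint, resolve toward cancer
#' (sensitivity-first); equal class means trigger a warning and an
#' all-cancer assignment.
#'
#' @param train_x Training samples x features matrix (features per sample
#'   usable as a series, length >= 16).
#' @param train_labels Training labels.
#' @param test_x Test samples x features matrix.
#' @param config A [dfa_config()].
#' @return Character vector of test labels, with per-sample exponents in
#'   `attr(, "exponents")` and the class means in `attr(, "class_means")`.
#' @export
dfa_classify <- function(train_x, train_labels, test_x, config = dfa_config()) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_labels <- check_labels(train_labels, nrow(train_x))
  tr_expo <- apply(train_x, 1, function(row) as.numeric(dfa_exponent(row, config)))
  m_cancer <- mean(tr_expo[train_labels == "cancer"])
  m_normal <- mean(tr_expo[train_labels == "normal"])
  if (isTRUE(all.equal(m_cancer, m_normal))) {
    warning("class mean exponents are equal; assigning all samples to cancer")
  }
  te_expo <- apply(test_x, 1, function(row) as.numeric(dfa_exponent(row, config)))
  labels <- ifelse(abs(te_expo - m_cancer) <= abs(te_expo - m_normal),
                   "cancer", "normal")
  structure(labels, exponents = te_expo,
            class_means = c(cancer = m_cancer, normal = m_normal))
}

#' Gaussian naive Bayes with a variance-floor smoothing factor
#'
#' Per-feature Gaussian likelihoods per class, multiplied under the
#' conditional-independence assumption (computed in log space), with class
#' priors equal to training frequencies. Every class-feature variance is
#' floored at `alpha` times the largest overall feature variance, which is
#' the package's reading of a smoothing factor for a continuous-feature
#' naive Bayes.
#'
#' @param train_x Training samples x features matrix.
#' @param train_labels Training labels.
#' @param test_x Test samples x features matrix.
#' @param alpha Variance-floor fraction (default 0.06).
#' @return List with `labels` (ties to cancer) and a samples x 2
#'   `posteriors` matrix (columns cancer, normal).
#' @export
nbc_fit_predict <- function(train_x, train_labels, test_x, alpha = 0.06) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_labels <- check_labels(train_labels, nrow(train_x))
  if (alpha < 0) sc_stop("validation", "alpha must be >= 0")
  feat_var <- apply(train_x, 2, stats::var)
  floor_v <- alpha * max(feat_var)
  ll <- vapply(CLASS_LEVELS, function(cls) {
    rows <- train_x[train_labels == cls, , drop = FALSE]
    mu <- colMeans(rows)
    v <- apply(rows, 2, stats::var)
    v[!is.finite(v)] <- 0
    v <- pmax(v, floor_v)
    if (any(v <= 0)) {
      sc_stop("numerical",
              "zero-variance feature with alpha = 0; use a smoothing factor alpha > 0")
    }
    prior <- mean(train_labels == cls)
    log(prior) - 0.5 * colSums((t(test_x) - mu)^2 / v) -
      0.5 * sum(log(2 * pi * v))
  }, numeric(nrow(test_x)))
  ll <- matrix(ll, nrow(test_x), 2, dimnames = list(NULL, CLASS_LEVELS))
  m <- pmax(ll[, 1], ll[, 2])
  post <- exp(ll - m)
  post <- post / rowSums(post)
  labels <- ifelse(post[, "cancer"] >= post[, "normal"], "cancer", "normal")
  list(labels = labels, posteriors = post)
}

#' Radial basis function kernel
#'
#' `K(x, z) = exp(-||x - z||^2 / (2 sigma^2))`, always in `(0, 1]`.
#'
#' @param x,z Numeric vectors of equal length.
#' @param sigma Kernel width, strictly positive (default 0.1).
#' @return Scalar similarity.
#' @export
svm_rbf_kernel <- function(x, z, sigma = 0.1) {
  if (sigma <= 0) sc_stop("validation", "sigma must be > 0")
  if (length(x) != length(z)) sc_stop("validation", "x and z lengths differ")
  exp(-sum((x - z)^2) / (2 * sigma^2))
}

#' Soft-margin RBF support vector machine
#'
#' Solves the C-SVM dual (sequential-minimal-optimisation solver from
#' libsvm via the e1071 package) with the radial kernel of
#' [svm_rbf_kernel()] and recomputes decision values
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` from the support vectors so
#' the orientation cancer = +1 is guaranteed. Labels are the decision sign,
#' with zero resolving to cancer.
#'
#' @param train_x Training samples x features matrix.
#' @param train_labels Training labels (both classes must be present).
#' @param test_x Test samples x features matrix.
#' @param sigma Kernel width (default 0.1).
#' @param cost Regularisation parameter C (default 1).
#' @return List with `labels`, `decision_values`, the signed dual
#'   coefficients `alpha_signed` (`alpha_i y_i`, satisfying
#'   `|alpha_i| <= C` and `sum alpha_i y_i = 0` to solver tolerance),
#'   `bias`, and the support-vector row indices `support`.
#' @export
svm_fit_predict <- function(train_x, train_labels, test_x, sigma = 0.1,
                            cost = 1) {
  if (sigma <= 0) sc_stop("validation", "sigma must be > 0")
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_labels <- check_labels(train_labels, nrow(train_x))
  if (length(unique(train_labels)) < 2) {
    sc_stop("validation", "both classes must be present in the training data")
  }
  # libsvm orients +1 toward the first label it encounters; put a cancer
  # sample first so the recomputed decision values have cancer = +1.
  ord <- order(train_labels != "cancer")
  xo <- train_x[ord, , drop = FALSE]
  yo <- factor(train_labels[ord], levels = CLASS_LEVELS)
  model <- e1071::svm(xo, yo, type = "C-classification", kernel = "radial",
                      gamma = 1 / (2 * sigma^2), cost = cost, scale = FALSE)
  sv <- model$SV
  coefs <- as.numeric(model$coefs)
  decision <- function(x) {
    d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * x %*% t(sv)
    k <- exp(-pmax(d2, 0) / (2 * sigma^2))
    as.numeric(k %*% coefs) - model$rho
  }
  dv <- decision(test_x)
  list(labels = ifelse(dv >= 0, "cancer", "normal"),
       decision_values = dv,
       alpha_signed = coefs,
       bias = -model$rho,
       support = ord[model$index],
       model = model)
}
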