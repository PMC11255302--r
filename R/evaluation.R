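# Confusion-matrix metrics, pooled K-fold cross-validation, class-level
# feature statistics, and the benchmark grid.

#' Binary confusion matrix with cancer as the positive class
#'
#' @param y_true,y_pred Equal-length label vectors with values in
#'   `c("cancer", "normal")`.
#' @return An object of class `confusion_matrix` with counts `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  y_true <- check_labels(y_true, arg = "y_true")
  y_pred <- check_labels(y_pred, arg = "y_pred")
  if (length(y_true) != length(y_pred)) {
    sc_stop("validation", "y_true and y_pred lengths differ")
  }
  structure(list(
    tp = sum(y_true == "cancer" & y_pred == "cancer"),
    tn = sum(y_true == "normal" & y_pred == "normal"),
    fp = sum(y_true == "normal" & y_pred == "cancer"),
    fn = sum(y_true == "cancer" & y_pred == "normal")
  ), class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) sc_stop("validation", "counts must be >= 0")
  structure(list(tp = unname(tp), tn = unname(tn), fp = unname(fp),
                 fn = unname(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Confusion-matrix performance metrics
#'
#' Computes accuracy, precision, recall, F1 (`2 TP / (2 TP + FP + FN)`),
#' error rate, the Matthews correlation coefficient, and Cohen's kappa from
#' the observed and chance agreement
#' `Pe = ((TP+FP)(TP+FN) + (FP+TN)(FN+TN)) / total^2`. Metrics are stored
#' as proportions with a 0-100 `percent` rendering alongside. A zero MCC or
#' precision denominator yields 0 with the corresponding flag set.
#'
#' @param cm A [confusion_matrix()] with at least one sample.
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  total <- tp + tn + fp + fn
  if (total < 1) sc_stop("validation", "confusion matrix is empty")
  accuracy <- (tp + tn) / total
  # algebraically (FP + FN) / total; written as the complement so the
  # accuracy + error_rate = 1 identity holds exactly in floating point
  error_rate <- 1 - accuracy
  flags <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else { flags <- c(flags, "precision_undefined"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { flags <- c(flags, "recall_undefined"); 0 }
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else { flags <- c(flags, "f1_undefined"); 0 }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else { flags <- c(flags, "mcc_undefined"); 0 }
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fp + tn) * (fn + tn)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else { flags <- c(flags, "kappa_undefined"); 0 }
  structure(list(
    accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
    error_rate = error_rate, mcc = mcc, po = po, pe = pe, kappa = kappa,
    kappa_band = kappa_band(kappa),
    percent = list(accuracy = 100 * accuracy, f1 = 100 * f1,
                   error_rate = 100 * error_rate),
    flags = flags
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | F1 %.4f | MCC %.4f | error %.4f | kappa %.4f (%s)\n",
              x$accuracy, x$f1, x$mcc, x$error_rate, x$kappa, x$kappa_band))
  invisible(x)
}

#' Agreement band for Cohen's kappa
#'
#' Bands: poor (< 0.2), fair (0.2-0.4), moderate (0.4-0.6), good (0.6-0.8),
#' very good (0.8-1). Boundary values belong to the upper band.
#'
#' @param kappa Kappa value, at most 1.
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"good"`, `"very good"`.
#' @export
kappa_band <- function(kappa) {
  if (kappa > 1 + 1e-12) sc_stop("validation", "kappa cannot exceed 1")
  if (kappa < 0.2) "poor"
  else if (kappa < 0.4) "fair"
  else if (kappa < 0.6) "moderate"
  else if (kappa < 0.8) "good"
  else "very good"
}

#' Cross-validation plan
#'
#' @param k Number of folds (default 10; accepted range 2-20, the study
#'   varies 5-20).
#' @param seed Integer seed for fold assignment.
#' @param stratified Preserve class proportions per fold (default TRUE).
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(k = 10, seed = 1, stratified = TRUE) {
  if (k < 2) sc_stop("validation", "K must be at least 2")
  if (k > 20) sc_stop("validation", "K above 20 is not supported")
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = stratified), class = "cv_plan")
}

make_folds <- function(labels, plan) {
  n <- length(labels)
  with_seed(plan$seed, {
    folds <- integer(n)
    if (plan$stratified) {
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        if (length(idx) < plan$k) {
          warning(sprintf("class '%s' has fewer samples (%d) than folds (%d); folds rebalanced",
                          cls, length(idx), plan$k))
        }
        folds[idx] <- sample(rep_len(seq_len(plan$k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(plan$k), n))
    }
    folds
  })
}

#' Classifier configuration for cross-validation and benchmarking
#'
#' @param name One of `"gmm"`, `"pso_gmm"`, `"firefly_gmm"`, `"fpo_gmm"`,
#'   `"dfa"`, `"nbc"`, `"svm_rbf"`.
#' @param ... Overrides for that classifier's parameters (e.g. `G`,
#'   `params`, `alpha`, `sigma`, `cost`, `config`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("gmm", "pso_gmm", "firefly_gmm",
                                     "fpo_gmm", "dfa", "nbc", "svm_rbf"),
                            ...) {
  name <- match.arg(name)
  structure(list(name = name, args = list(...)), class = "classifier_spec")
}

# Median-distance heuristic for the RBF width on standardised features.
median_sigma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 60) sample.int(n, 60) else seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  m <- stats::median(d)
  if (!is.finite(m) || m <= 0) 1 else m / sqrt(2)
}

# Fit on the training rows, predict labels for the test rows. GMM-family,
# NBC and SVM see column-standardised features (training statistics); DFA
# sees the raw per-sample series.
fit_predict_fold <- function(spec, train_x, train_labels, test_x, seed,
                             scheme = target_scheme()) {
  a <- spec$args
  standardized <- function() {
    st <- standardize_fit(train_x)
    list(train = standardize_apply(train_x, st),
         test = standardize_apply(test_x, st))
  }
  switch(spec$name,
    gmm = {
      z <- standardized()
      model <- gmm_fit(z$train, train_labels, G = a$G %||% 2, seed = seed)
      gmm_predict(model, z$test, scheme)$labels
    },
    pso_gmm = ,
    firefly_gmm = ,
    fpo_gmm = {
      z <- standardized()
      opt <- sub("_gmm$", "", spec$name)
      fit <- hybrid_gmm_fit(z$train, train_labels, optimizer = opt,
                            params = a$params %||% benchmark_optimizer_params(opt),
                            scheme = scheme, G = a$G %||% 2, seed = seed)
      gmm_predict(fit$model, z$test, scheme)$labels
    },
    dfa = {
      as.character(dfa_classify(train_x, train_labels, test_x,
                                config = a$config %||% dfa_config()))
    },
    nbc = {
      z <- standardized()
      nbc_fit_predict(z$train, train_labels, z$test,
                      alpha = a$alpha %||% 0.06)$labels
    },
    svm_rbf = {
      z <- standardized()
      sigma <- a$sigma %||% with_seed(seed, median_sigma(z$train))
      svm_fit_predict(z$train, train_labels, z$test, sigma = sigma,
                      cost = a$cost %||% 1)$labels
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Benchmark-scale optimiser budgets for the hybrid classifiers: small
# populations and iteration counts, sufficient because the search starts at
# the EM solution and only refines it.
benchmark_optimizer_params <- function(opt) {
  switch(opt,
    pso = pso_params(population = 20, max_iter = 25),
    firefly = firefly_params(population = 15, max_iter = 15),
    fpo = fpo_params(population = 15, max_iter = 25)
  )
}

#' Pooled K-fold cross-validation
#'
#' Stratified folds; for each fold the classifier is fitted on the other
#' K-1 folds and predicts the held-out fold. Out-of-fold predictions are
#' pooled over all samples and the metric suite is computed once on the
#' pooled confusion matrix, so metric denominators equal the full sample
#' count.
#'
#' @param features A [feature_matrix()], or a samples x features matrix with
#'   `labels`.
#' @param classifier A [classifier_spec()] or a classifier name.
#' @param plan A [cv_plan()].
#' @param labels Labels when `features` is a plain matrix.
#' @param scheme A [target_scheme()].
#' @return List with pooled `predictions`, fold assignment `folds`, the
#'   pooled `cm`, and `metrics`.
#' @export
cross_validate <- function(features, classifier, plan = cv_plan(),
                           labels = NULL, scheme = target_scheme()) {
  fv <- feature_values(features, labels)
  x <- fv$x
  labels <- fv$labels
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  stopifnot(inherits(classifier, "classifier_spec"), inherits(plan, "cv_plan"))
  folds <- make_folds(labels, plan)
  pred <- character(length(labels))
  for (f in sort(unique(folds))) {
    te <- folds == f
    pred[te] <- fit_predict_fold(classifier, x[!te, , drop = FALSE],
                                 labels[!te], x[te, , drop = FALSE],
                                 seed = plan$seed + f, scheme = scheme)
  }
  cm <- confusion_matrix(labels, pred)
  list(predictions = pred, folds = folds, cm = cm,
       metrics = compute_metrics(cm))
}

#' Class-level statistics of a feature matrix
#'
#' For each class, statistics of the pooled (samples x features, flattened)
#' values: mean, unbiased variance, adjusted Fisher-Pearson skewness,
#' Pearson kurtosis (normal = 3), and the mean off-diagonal pairwise Pearson
#' correlation across features. Constant pooled values leave skewness and
#' kurtosis `NA` with the `degenerate` flag set. The cross-class first
#' canonical correlation pairs samples by truncating both classes to the
#' smaller size, ranking samples within class by their feature mean.
#'
#' @param features A [feature_matrix()], or a matrix with `labels`.
#' @param labels Labels when `features` is a plain matrix.
#' @return An object of class `class_statistics`: per-class statistic list
#'   plus `cca` for the cross-class canonical correlation.
#' @export
feature_statistics <- function(features, labels = NULL) {
  fv <- feature_values(features, labels)
  x <- fv$x
  labels <- fv$labels
  per_class <- lapply(CLASS_LEVELS, function(cls) {
    rows <- x[labels == cls, , drop = FALSE]
    pooled <- as.numeric(rows)
    if (length(pooled) < 3) {
      sc_stop("statistics", "class '%s' has fewer than 3 pooled values", cls)
    }
    v <- stats::var(pooled)
    degenerate <- v <= 0
    pcc <- NA_real_
    if (ncol(rows) >= 2 && nrow(rows) >= 2) {
      cm <- suppressWarnings(stats::cor(rows))
      off <- cm[upper.tri(cm)]
      pcc <- mean(off[is.finite(off)])
    }
    list(mean = mean(pooled), variance = v,
         skewness = if (degenerate) NA_real_ else skewness_adjusted(pooled),
         kurtosis = if (degenerate) NA_real_ else kurtosis_pearson(pooled),
         mean_pcc = pcc, degenerate = degenerate)
  })
  names(per_class) <- CLASS_LEVELS
  a <- x[labels == "cancer", , drop = FALSE]
  b <- x[labels == "normal", , drop = FALSE]
  n_pair <- min(nrow(a), nrow(b))
  cca <- NA_real_
  if (n_pair >= 3) {
    rank_rows <- function(m) m[order(rowMeans(m))[seq_len(n_pair)], , drop = FALSE]
    cca <- canonical_correlation(rank_rows(a), rank_rows(b))
  }
  structure(c(per_class, list(cca = cca)), class = "class_statistics")
}

#' First canonical correlation between two variable sets
#'
#' Largest singular value of the whitened cross-covariance
#' `Sa^{-1/2} Sab Sb^{-1/2}`, with a ridge of `1e-8` times the mean
#' diagonal added to each within-set covariance before whitening to handle
#' rank deficiency. The result is clipped into `[0, 1]`.
#'
#' @param a,b Observations x variables matrices with equal row counts
#'   (at least 3).
#' @return The first canonical correlation.
#' @export
canonical_correlation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) sc_stop("validation", "observation counts differ")
  if (nrow(a) < 3) sc_stop("validation", "need at least 3 observations")
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  n <- nrow(a)
  sa <- crossprod(ac) / (n - 1)
  sb <- crossprod(bc) / (n - 1)
  sab <- crossprod(ac, bc) / (n - 1)
  inv_sqrt <- function(s) {
    s <- s + diag(1e-8 * mean(diag(s)) + 1e-300, nrow(s))
    e <- eigen(s, symmetric = TRUE)
    vals <- pmax(e$values, 1e-12 * max(e$values))
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  m <- inv_sqrt(sa) %*% sab %*% inv_sqrt(sb)
  min(max(svd(m)$d[1], 0), 1)
}

#' Benchmark grid of extractors by classifiers
#'
#' Runs every extractor once on the dataset (seeded), then pooled K-fold
#' cross-validation of every classifier on each extracted feature matrix.
#' Failed cells are recorded (with their error message in
#' `attr(, "errors")`) and the run continues.
#'
#' @param dataset An [expression_dataset()].
#' @param extractors Character subset of `c("stft", "lasso", "eho")`.
#' @param classifiers List of [classifier_spec()]s or a character vector of
#'   classifier names (default: all seven).
#' @param plan A [cv_plan()].
#' @param seed Integer seed for the extractors (fold seeds come from
#'   `plan`).
#' @param stft_cfg,lasso_cfg,eho_cfg Extractor configurations.
#' @return A data.frame with columns `method`, `classifier`, `accuracy`,
#'   `f1`, `mcc`, `error_rate`, `kappa`, `seed`.
#' @export
benchmark <- function(dataset,
                      extractors = c("stft", "lasso", "eho"),
                      classifiers = c("gmm", "pso_gmm", "dfa", "nbc",
                                      "firefly_gmm", "svm_rbf", "fpo_gmm"),
                      plan = cv_plan(), seed = 1,
                      stft_cfg = stft_config(),
                      lasso_cfg = lasso_config(target_n_features = 20),
                      eho_cfg = eho_feature_config(
                        eho = eho_params(population = 20, max_iter = 30))) {
  stopifnot(inherits(dataset, "expression_dataset"))
  extractors <- match.arg(extractors, several.ok = TRUE)
  if (is.character(classifiers)) {
    classifiers <- lapply(classifiers, classifier_spec)
  }
  rows <- list()
  errors <- list()
  for (ext in extractors) {
    fm <- tryCatch(switch(ext,
      stft = stft_features(dataset, stft_cfg),
      lasso = lasso_features(dataset, lasso_cfg, seed = seed),
      eho = eho_features(dataset, eho_cfg, seed = seed)
    ), error = function(e) e)
    for (cls in classifiers) {
      key <- paste(ext, cls$name, sep = ":")
      if (inherits(fm, "error")) {
        errors[[key]] <- conditionMessage(fm)
        met <- NULL
      } else {
        met <- tryCatch(cross_validate(fm, cls, plan)$metrics,
                        error = function(e) e)
        if (inherits(met, "error")) {
          errors[[key]] <- conditionMessage(met)
          met <- NULL
        }
      }
      rows[[key]] <- data.frame(
        method = ext, classifier = cls$name,
        accuracy = if (is.null(met)) NA_real_ else met$accuracy,
        f1 = if (is.null(met)) NA_real_ else met$f1,
        mcc = if (is.null(met)) NA_real_ else met$mcc,
        error_rate = if (is.null(met)) NA_real_ else met$error_rate,
        kappa = if (is.null(met)) NA_real_ else met$kappa,
        seed = seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "errors") <- errors
  out
}
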