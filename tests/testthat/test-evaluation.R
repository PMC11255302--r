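test_that("confusion matrix counts follow the cancer-positive orientation", {
  y <- c(rep("cancer", 40), rep("normal", 22))
  cm <- confusion_matrix(y, y)
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 40, tn = 22, fp = 0, fn = 0))
  all_cancer <- confusion_matrix(y, rep("cancer", 62))
  expect_equal(unlist(all_cancer[c("tp", "tn", "fp", "fn")]),
               c(tp = 40, tn = 0, fp = 22, fn = 0))
  set.seed(17)
  pred <- sample(c("cancer", "normal"), 62, replace = TRUE)
  a <- confusion_matrix(y, pred)
  b <- confusion_matrix(pred, y)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
  expect_error(confusion_matrix(y, rep("tumour", 62)), "unknown class")
})

test_that("a perfect classifier maxes out every metric", {
  m <- compute_metrics(confusion_counts(40, 22, 0, 0))
  expect_equal(c(m$accuracy, m$f1, m$mcc, m$kappa), c(1, 1, 1, 1))
  expect_equal(m$error_rate, 0)
  expect_equal(m$kappa_band, "very good")
})

test_that("metric identities hold over fuzzed confusion matrices", {
  set.seed(18)
  for (i in 1:2000) {
    cts <- rmultinom(1, sample(1:200, 1), rep(0.25, 4))
    m <- compute_metrics(confusion_counts(cts[1], cts[2], cts[3], cts[4]))
    expect_identical(m$accuracy + m$error_rate, 1)
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    }
    expect_lte(m$kappa, 1)
    expect_gte(m$mcc, -1 - 1e-12)
    expect_lte(m$mcc, 1 + 1e-12)
  }
})

test_that("kappa equals MCC for symmetric, margin-balanced matrices", {
  m <- compute_metrics(confusion_counts(37, 19, 3, 3))
  expect_equal(m$kappa, m$mcc)
  expect_equal(m$kappa, 0.788636364, tolerance = 1e-9)
})

test_that("degenerate metric denominators yield flagged zeros", {
  m <- compute_metrics(confusion_counts(0, 10, 0, 0))
  expect_equal(m$mcc, 0)
  expect_true("mcc_undefined" %in% m$flags)
})

test_that("kappa bands assign boundaries to the upper band", {
  expect_equal(kappa_band(0.93), "very good")
  expect_equal(kappa_band(0.788636364), "good")
  expect_equal(kappa_band(1.0), "very good")
  expect_equal(kappa_band(0.2), "fair")
  expect_equal(kappa_band(0.6), "good")
  expect_equal(kappa_band(-0.3), "poor")
  expect_error(kappa_band(1.2), "exceed")
})

test_that("pooled cross-validation covers each sample exactly once", {
  for (k in c(5, 10, 20)) {
    for (n_pair in list(c(20, 15), c(40, 22), c(60, 40))) {
      sep <- separable_features(k * 100 + n_pair[1], n_cancer = n_pair[1],
                                n_normal = n_pair[2], shift = 3)
      res <- suppressWarnings(
        cross_validate(sep$x, "nbc", cv_plan(k = k, seed = 1),
                       labels = sep$labels))
      expect_length(res$predictions, sum(n_pair))
      expect_true(all(res$predictions %in% c("cancer", "normal")))
      expect_equal(sort(unique(res$folds)), 1:k)
      tab <- table(res$folds)
      expect_lte(max(tab) - min(tab), 2)
    }
  }
  expect_error(cv_plan(k = 1), "at least 2")
  expect_equal(cv_plan()$k, 10L)
})

test_that("cross-validation is deterministic under a fixed plan", {
  sep <- separable_features(77, shift = 1.5)
  r1 <- cross_validate(sep$x, "svm_rbf", cv_plan(k = 5, seed = 9),
                       labels = sep$labels)
  r2 <- cross_validate(sep$x, "svm_rbf", cv_plan(k = 5, seed = 9),
                       labels = sep$labels)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$metrics$accuracy, r2$metrics$accuracy)
})

test_that("class statistics match hand arithmetic and asymptotics", {
  vals <- rbind(c(1, 2), c(3, 4), c(10, 11), c(12, 13))
  labs <- c("cancer", "cancer", "normal", "normal")
  st <- feature_statistics(vals, labs)
  expect_equal(st$cancer$mean, 2.5)
  expect_equal(st$cancer$variance, 5 / 3)

  set.seed(8)
  x <- matrix(rnorm(20000), 200, 100)
  labs2 <- c(rep("cancer", 100), rep("normal", 100))
  st2 <- feature_statistics(x, labs2)
  expect_lt(abs(st2$cancer$skewness), 0.08)
  expect_lt(abs(st2$cancer$kurtosis - 3), 0.15)
  expect_lt(abs(st2$normal$skewness), 0.08)

  const <- matrix(2, 6, 4)
  st3 <- feature_statistics(const, c(rep("cancer", 3), rep("normal", 3)))
  expect_true(st3$cancer$degenerate)
  expect_true(is.na(st3$cancer$skewness))
  expect_error(feature_statistics(matrix(1:4, 2, 2),
                                  c("cancer", "normal")),
               "pooled values")
})

test_that("canonical correlation matches an eigen-decomposition oracle", {
  set.seed(20)
  a <- matrix(rnorm(10), 5, 2)
  b_same <- a
  expect_equal(canonical_correlation(a, b_same), 1, tolerance = 1e-6)
  expect_equal(canonical_correlation(a, a[, 2:1]), 1, tolerance = 1e-6)

  b <- matrix(rnorm(10), 5, 2) + 0.5 * a
  got <- canonical_correlation(a, b)
  # textbook generalised eigenproblem on the normal equations
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  saa <- crossprod(ac) / 4; sbb <- crossprod(bc) / 4; sab <- crossprod(ac, bc) / 4
  ev <- eigen(solve(saa) %*% sab %*% solve(sbb) %*% t(sab))$values
  expect_equal(got, sqrt(max(Re(ev))), tolerance = 1e-6)
  expect_equal(got, unname(stats::cancor(a, b)$cor[1]), tolerance = 1e-6)
  expect_error(canonical_correlation(a[1:2, ], b[1:2, ]), "3 observations")
})

test_that("benchmark emits the fixed schema and internally consistent metrics", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_genes = 150,
                                                  n_informative = 10,
                                                  effect_size = 3,
                                                  block_size = 25, seed = 5))
  res <- benchmark(ds,
                   extractors = c("stft", "lasso"),
                   classifiers = c("gmm", "nbc", "svm_rbf"),
                   plan = cv_plan(k = 5, seed = 5), seed = 5,
                   stft_cfg = stft_config(window_length = 32, hop = 16),
                   lasso_cfg = lasso_config(target_n_features = 8))
  expect_equal(names(res), c("method", "classifier", "accuracy", "f1", "mcc",
                             "error_rate", "kappa", "seed"))
  expect_equal(nrow(res), 6)
  expect_length(attr(res, "errors"), 0)
  expect_true(all(res$accuracy + res$error_rate == 1))
  expect_true(all(res$kappa <= res$mcc + 0.05))
})
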