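test_that("GMM priors equal class frequencies and EM recovers parameters", {
  set.seed(4)
  x <- matrix(c(rnorm(100, 0), rnorm(100, 10)), ncol = 1)
  lab <- c(rep("cancer", 100), rep("normal", 100))
  m <- gmm_fit(x, lab, G = 1, seed = 4)
  expect_lt(abs(m$classes$cancer$means[1, 1] - 0), 0.5)
  expect_lt(abs(m$classes$normal$means[1, 1] - 10), 0.5)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  for (cls in c("cancer", "normal")) {
    expect_false(is.unsorted(m$classes[[cls]]$loglik_trace))
    expect_equal(sum(m$classes[[cls]]$weights), 1)
  }

  ds <- generate_synthetic_dataset(synthetic_spec(n_genes = 30,
                                                  n_informative = 5, seed = 3))
  fm <- stft_features(ds, stft_config(window_length = 16, hop = 8))
  g <- gmm_fit(fm, G = 2, seed = 1)
  expect_equal(unname(g$priors), c(40 / 62, 22 / 62))
})

test_that("GMM posteriors normalise and the equal-covariance boundary is the bisector", {
  sep <- separable_features(40, d = 1, shift = 10)
  m <- gmm_fit(sep$x, sep$labels, G = 1, seed = 2)
  pr <- gmm_predict(m, matrix(seq(-3, 3, length.out = 31), ncol = 1))
  expect_true(all(abs(rowSums(pr$posteriors) - 1) < 1e-12))
  expect_true(all(pr$posteriors >= 0 & pr$posteriors <= 1))

  # symmetric construction: equal priors, unit variances, means at 0 and 2
  model <- gmm_fit(matrix(c(rnorm(500, 0), rnorm(500, 2)), ncol = 1),
                   c(rep("cancer", 500), rep("normal", 500)), G = 1, seed = 3)
  probe <- gmm_predict(model, matrix(c(0.8, 1.2), ncol = 1))
  expect_equal(probe$labels, c("cancer", "normal"))

  expect_error(gmm_predict(model, matrix(0, 1, 3)), "dimensionality")
})

test_that("posterior at a well-separated class mean matches the Gaussian ratio", {
  # closed form: with equal priors and unit variances at separation delta,
  # p(cancer | x = mu_cancer) = 1 / (1 + exp(-delta^2 / 2))
  set.seed(8)
  n <- 4000
  x <- matrix(c(rnorm(n, 0), rnorm(n, 10)), ncol = 1)
  lab <- c(rep("cancer", n), rep("normal", n))
  m <- gmm_fit(x, lab, G = 1, seed = 8)
  p <- gmm_predict(m, matrix(0, ncol = 1))$posteriors[1, "cancer"]
  expect_gt(p, 0.999)
})

test_that("gmm_fit rejects classes smaller than G", {
  sep <- separable_features(41, n_cancer = 3, n_normal = 3)
  expect_error(gmm_fit(sep$x, sep$labels, G = 5), "G = 5")
})

test_that("hybrid tuning never degrades the EM initialisation", {
  improved <- 0L
  for (sd in 1:10) {
    sep <- separable_features(sd + 100, d = 2, shift = 2)
    h <- hybrid_gmm_fit(sep$x, sep$labels, "fpo",
                        fpo_params(population = 15, max_iter = 40), seed = sd)
    expect_lte(h$final_mse, h$init_mse)
    expect_false(is.unsorted(-h$trace))
    if (h$final_mse < h$init_mse) improved <- improved + 1L
  }
  expect_gte(improved, 8)
})

test_that("hybrid models decode to valid mixtures and honour a zero budget", {
  sep <- separable_features(6, d = 2, shift = 3)
  h0 <- hybrid_gmm_fit(sep$x, sep$labels, "pso",
                       pso_params(population = 10, max_iter = 0), seed = 6)
  expect_identical(h0$init_mse, h0$final_mse)
  for (cls in c("cancer", "normal")) {
    cm <- h0$model$classes[[cls]]
    expect_equal(sum(cm$weights), 1)
    for (k in seq_along(cm$covs)) {
      expect_true(all(diag(cm$covs[[k]]) > 0))
    }
  }
  pred <- gmm_predict(h0$model, sep$x)
  expect_true(all(abs(rowSums(pred$posteriors) - 1) < 1e-12))

  h1 <- hybrid_gmm_fit(sep$x, sep$labels, "firefly",
                       firefly_params(population = 8, max_iter = 10), seed = 6)
  expect_lte(h1$final_mse, h1$init_mse)
})

test_that("DFA exponents hit the classical limits and flag degeneracy", {
  const <- dfa_exponent(rep(5, 100))
  expect_equal(as.numeric(const), 0)
  expect_true(attr(const, "degenerate"))

  set.seed(9)
  wn <- rnorm(4096)
  expect_lt(abs(as.numeric(dfa_exponent(wn)) - 0.5), 0.1)
  expect_lt(abs(as.numeric(dfa_exponent(cumsum(wn))) - 1.5), 0.1)
  expect_error(dfa_exponent(rnorm(10)), "length")
})

test_that("DFA classification separates scaling regimes by nearest class mean", {
  set.seed(12)
  tr <- rbind(t(replicate(20, cumsum(rnorm(64)))),
              t(replicate(20, rnorm(64))))
  te <- rbind(t(replicate(5, cumsum(rnorm(64)))),
              t(replicate(5, rnorm(64))))
  lab <- c(rep("cancer", 20), rep("normal", 20))
  pred <- dfa_classify(tr, lab, te)
  truth <- c(rep("cancer", 5), rep("normal", 5))
  expect_gte(mean(pred == truth), 0.9)
  means <- attr(pred, "class_means")
  expect_gt(means[["cancer"]], means[["normal"]])

  # equal class means: warned, resolved toward cancer
  const <- matrix(5, 4, 64)
  expect_warning(p2 <- dfa_classify(const, c("cancer", "cancer", "normal", "normal"),
                                    const),
                 "equal")
  expect_true(all(p2 == "cancer"))
})

test_that("naive Bayes matches a brute-force Bayes oracle", {
  # hand-set 2-feature 2-class instance, no variance flooring (alpha = 0)
  tr <- rbind(c(0, 0), c(0.4, -0.2), c(-0.3, 0.3), c(2, 2), c(2.5, 1.7), c(1.8, 2.2))
  lab <- c(rep("cancer", 3), rep("normal", 3))
  te <- rbind(c(0.2, 0.1), c(2.2, 1.9), c(1.0, 1.0))
  out <- nbc_fit_predict(tr, lab, te, alpha = 0)
  oracle <- t(apply(te, 1, function(z) {
    lik <- vapply(c("cancer", "normal"), function(cls) {
      rows <- tr[lab == cls, ]
      prod(stats::dnorm(z, colMeans(rows), apply(rows, 2, sd))) * 0.5
    }, numeric(1))
    lik / sum(lik)
  }))
  expect_equal(unname(out$posteriors), unname(oracle), tolerance = 1e-12)
  expect_true(all(abs(rowSums(out$posteriors) - 1) < 1e-12))
  expect_equal(out$labels[1:2], c("cancer", "normal"))
})

test_that("naive Bayes boundary sits at the midpoint for equal variances", {
  set.seed(14)
  tr <- matrix(c(rnorm(4000, 0, 1), rnorm(4000, 2, 1)), ncol = 1)
  lab <- c(rep("cancer", 4000), rep("normal", 4000))
  out <- nbc_fit_predict(tr, lab, matrix(c(0.9, 1.1), ncol = 1), alpha = 0)
  expect_equal(out$labels, c("cancer", "normal"))

  zv <- matrix(c(1, 1, 1, 1), ncol = 1)
  expect_error(nbc_fit_predict(zv, c("cancer", "cancer", "normal", "normal"),
                               zv, alpha = 0),
               "alpha")
})

test_that("RBF kernel is a valid similarity with PSD Gram matrices", {
  expect_equal(svm_rbf_kernel(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(svm_rbf_kernel(c(0, 0), c(1, 0), 0.1), exp(-50))
  expect_error(svm_rbf_kernel(1, 1, 0), "sigma")
  expect_error(svm_rbf_kernel(c(1, 2), 1), "lengths")
  set.seed(15)
  pts <- matrix(rnorm(30), 10, 3)
  gram <- outer(seq_len(10), seq_len(10),
                Vectorize(function(i, j) svm_rbf_kernel(pts[i, ], pts[j, ], 1)))
  ev <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(gram > 0 & gram <= 1))
  expect_gt(min(ev), -1e-10)
})

test_that("SVM separates the XOR construction and satisfies dual feasibility", {
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE)
  xor_y <- c("cancer", "cancer", "normal", "normal")
  fit <- svm_fit_predict(xor_x, xor_y, xor_x, sigma = 0.5, cost = 10)
  expect_equal(fit$labels, xor_y)
  expect_true(all(abs(fit$alpha_signed) <= 10 + 1e-7))
  expect_lt(abs(sum(fit$alpha_signed)), 1e-5)
})

test_that("SVM predictions are invariant to duplicating the training set", {
  sep <- separable_features(16, n_cancer = 15, n_normal = 10, shift = 2.5)
  te <- matrix(rnorm(20), 10, 2)
  f1 <- svm_fit_predict(sep$x, sep$labels, te, sigma = 1, cost = 1)
  f2 <- svm_fit_predict(rbind(sep$x, sep$x), c(sep$labels, sep$labels), te,
                        sigma = 1, cost = 1)
  expect_equal(f1$labels, f2$labels)
})

test_that("target scheme validation follows the separation constraint", {
  ok <- target_scheme(0.85, 0.1)
  expect_equal(ok$t_normal - ok$t_cancer, 0.75)
  expect_error(target_scheme(0.6, 0.4), "separated")
  expect_error(target_scheme(1.2, 0.1), "\\[0, 1\\]")
})

test_that("mse is the mean of squared differences", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(1, 0), c(0, 1)), 1)
  expect_equal(mse(0.85, 0.95), 0.01)
  expect_error(mse(1:3, 1:2), "lengths")
})
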