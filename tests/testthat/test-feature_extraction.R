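test_that("Blackman window hits its closed-form anchor points", {
  for (m in c(4, 8, 64, 256)) {
    w <- blackman_window(m)
    expect_equal(w[1], 0, tolerance = 1e-12)
    expect_equal(w[m / 2 + 1], 1.0)  # n = M/2
  }
  expect_equal(blackman_window(8)[3], 0.34)  # n = 2, M = 8
  expect_error(blackman_window(0), "window length")
})

test_that("STFT matches a direct DFT oracle on a single-tone frame", {
  m <- 32
  k <- 3
  sig <- cos(2 * pi * k * (0:(m - 1)) / m)
  cfg <- stft_config(window_length = m, hop = m, window = "rectangular")
  spec <- stft(sig, cfg)
  expect_equal(dim(spec), c(1L, m))
  expect_equal(as.complex(spec[1, ]), dft_oracle(sig), tolerance = 1e-10)
  mod <- Mod(spec[1, ])
  expect_equal(mod[k + 1], m / 2)
  expect_equal(mod[m - k + 1], m / 2)
  expect_lt(max(mod[-c(k + 1, m - k + 1)]), 1e-10)
})

test_that("STFT is linear, pure, and Parseval-consistent", {
  expect_true(all(Mod(stft(numeric(64), stft_config(window_length = 16))) == 0))
  sig <- sin(0.3 * (1:100))
  cfg <- stft_config(window_length = 32, hop = 16)
  expect_identical(stft(sig, cfg), stft(sig, cfg))
  # Parseval for a rectangular window frame
  set.seed(21)
  frame <- rnorm(64)
  spec <- stft(frame, stft_config(window_length = 64, hop = 64,
                                  window = "rectangular"))
  lhs <- sum(Mod(spec[1, ])^2)
  rhs <- 64 * sum(frame^2)
  expect_lt(abs(lhs - rhs) / rhs, 1e-8)
})

test_that("spectral feature layout follows the frame-count arithmetic", {
  ds <- generate_synthetic_dataset()
  fm <- stft_features(ds)
  # 2000 genes, M = 256, hop = 128, padded tail frame: 15 frames x 3 stats
  expect_equal(ncol(fm$values), 45)
  expect_equal(nrow(fm$values), 62)
  expect_equal(fm$labels, ds$labels)
  expect_error(stft_features(ds, stft_config(window_length = 4096,
                                             zero_pad = FALSE)),
               "zero_pad")
})

test_that("constant samples concentrate energy at the DC bin", {
  vals <- matrix(3, nrow = 32, ncol = 2)
  ds <- expression_dataset(vals, sprintf("g%02d", 1:32), c("s1", "s2"),
                           c("cancer", "normal"))
  cfg <- stft_config(window_length = 32, hop = 32)
  spec <- stft(ds$values[, 1], cfg)
  mod <- Mod(spec[1, ])
  expect_equal(which.max(mod), 1L)  # DC bin
  expect_equal(mod[1]^2, (3 * sum(blackman_window(32)))^2)
  fm <- stft_features(ds, cfg)
  expect_identical(fm$values[1, ], fm$values[2, ])  # per-sample purity
})

test_that("duplicated sample columns give duplicated feature rows", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_genes = 40, n_informative = 5,
                                                  n_cancer = 3, n_normal = 2,
                                                  seed = 9))
  dup <- expression_dataset(ds$values[, c(1, 1, 4, 4)],
                            ds$gene_ids, paste0("s", 1:4),
                            c("cancer", "cancer", "normal", "normal"))
  fm <- stft_features(dup, stft_config(window_length = 16, hop = 8))
  expect_identical(fm$values[1, ], fm$values[2, ])
  expect_identical(fm$values[3, ], fm$values[4, ])
})

test_that("lasso limits: orthonormal OLS at zero penalty, exact zeroing at lambda_max", {
  # orthonormal design via QR
  set.seed(31)
  q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  q <- sweep(q, 2, colMeans(q))  # standardise means to 0
  y <- rnorm(6)
  ols <- solve(crossprod(q), crossprod(q, y))
  beta0 <- lasso_fit(q, y, 0)
  expect_equal(as.numeric(beta0), as.numeric(ols), tolerance = 1e-8)

  x <- scale(matrix(rnorm(40), 10, 4))
  yc <- rnorm(10); yc <- yc - mean(yc)
  lambda_max <- max(abs(crossprod(x, yc))) / 10
  expect_true(all(lasso_fit(x, yc, lambda_max * (1 + 1e-10)) == 0))
  expect_true(any(lasso_fit(x, yc, 0.5 * lambda_max) != 0))
})

test_that("univariate lasso equals the soft-threshold closed form", {
  set.seed(32)
  x <- matrix(rnorm(20), 20, 1)
  x <- x - mean(x)
  y <- rnorm(20); y <- y - mean(y)
  lambda <- 0.07
  z <- sum(x * y) / 20
  expected <- sign(z) * max(abs(z) - lambda, 0) / (sum(x^2) / 20)
  expect_equal(as.numeric(lasso_fit(x, y, lambda)), expected, tolerance = 1e-8)
})

test_that("coordinate descent matches the sign-enumeration oracle and is monotone", {
  set.seed(33)
  for (rep in 1:20) {
    x <- scale(matrix(rnorm(15), 5, 3))
    y <- rnorm(5); y <- y - mean(y)
    lambda <- runif(1, 0.05, 0.5)
    beta <- lasso_fit(x, y, lambda, lasso_config(tol = 1e-10))
    oracle <- lasso_enumeration_oracle(x, y, lambda)
    expect_equal(as.numeric(beta), as.numeric(oracle), tolerance = 1e-6)
    trace <- attr(beta, "objective_trace")
    expect_true(all(diff(trace) <= 1e-12))
  }
})

test_that("coordinate descent agrees with glmnet on a larger instance", {
  skip_if_not_installed("glmnet")
  set.seed(34)
  x <- scale(matrix(rnorm(50 * 8), 50, 8))
  y <- rnorm(50); y <- y - mean(y)
  lambda <- 0.1
  fit <- glmnet::glmnet(x, y, lambda = lambda, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14)
  expect_equal(as.numeric(lasso_fit(x, y, lambda)),
               as.numeric(fit$beta), tolerance = 1e-5)
})

test_that("lasso_fit validates its standardisation precondition", {
  x <- matrix(rnorm(20, mean = 5), 10, 2)
  expect_error(lasso_fit(x, rnorm(10), 0.1), "not standardised")
})

test_that("lasso selection recovers informative genes and honours the cap", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_informative = 10,
                                                  effect_size = 3, seed = 1))
  fm <- lasso_features(ds, seed = 1)
  expect_gte(sum(fm$selected_gene_indices <= 10), 6)
  expect_identical(fm$values,
                   t(ds$values[fm$selected_gene_indices, , drop = FALSE]),
                   ignore_attr = TRUE)
  fm5 <- lasso_features(ds, lasso_config(target_n_features = 5))
  expect_lte(ncol(fm5$values), 5)
  const <- expression_dataset(ds$values[, 1:40], ds$gene_ids,
                              ds$sample_ids[1:40], rep("cancer", 40))
  expect_error(lasso_features(const), "constant")
})

test_that("lasso selection is invariant to gene-order permutation", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_genes = 300,
                                                  n_informative = 10,
                                                  effect_size = 3, seed = 5))
  fm1 <- lasso_features(ds, lasso_config(target_n_features = 8))
  set.seed(55)
  perm <- sample(300)
  ds2 <- expression_dataset(ds$values[perm, ], ds$gene_ids[perm],
                            ds$sample_ids, ds$labels)
  fm2 <- lasso_features(ds2, lasso_config(target_n_features = 8))
  expect_setequal(perm[fm2$selected_gene_indices], fm1$selected_gene_indices)
})

test_that("EHO wrapper recovers informative genes and keeps its contracts", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_informative = 20,
                                                  effect_size = 3, seed = 2))
  fm <- eho_features(ds, eho_feature_config(
    n_select = 20, eho = eho_params(population = 30, max_iter = 100)), seed = 2)
  expect_gte(sum(fm$selected_gene_indices <= 20), 8)
  expect_length(fm$selected_gene_indices, 20)
  pop <- attr(fm, "optimizer")
  expect_false(is.unsorted(-pop$trace))
  expect_lte(pop$best_fitness, pop$trace[1])

  # saturation: selecting every gene needs no search
  small <- generate_synthetic_dataset(synthetic_spec(n_genes = 12,
                                                     n_informative = 4,
                                                     seed = 3))
  fs <- eho_features(small, eho_feature_config(n_select = 12), seed = 1)
  expect_equal(fs$selected_gene_indices, 1:12)
  expect_error(eho_features(small, eho_feature_config(n_select = 13)),
               "n_select")
})

test_that("feature matrices are finite and sample-aligned", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_genes = 64,
                                                  n_informative = 8, seed = 11))
  for (fm in list(stft_features(ds, stft_config(window_length = 32, hop = 16)),
                  lasso_features(ds, lasso_config(target_n_features = 6)),
                  eho_features(ds, eho_feature_config(
                    n_select = 5, eho = eho_params(population = 10, max_iter = 10)),
                    seed = 4))) {
    expect_true(all(is.finite(fm$values)))
    expect_equal(nrow(fm$values), 62)
    expect_equal(fm$sample_ids, ds$sample_ids)
  }
})
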