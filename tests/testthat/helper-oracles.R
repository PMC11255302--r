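# Shared fixtures and independent oracles used across the suite.

toy_dataset <- function() {
  expression_dataset(
    values = matrix(c(1.5, 2.5, 10, 20, 100.25, 7), nrow = 3, byrow = TRUE),
    gene_ids = c("gA", "gB", "gC"),
    sample_ids = c("s1", "s2"),
    labels = c("cancer", "normal")
  )
}

# Direct O(M^2) discrete Fourier transform, independent of stats::fft.
dft_oracle <- function(x) {
  m <- length(x)
  vapply(0:(m - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(m - 1)) / m))
  }, complex(1))
}

# Exact lasso solution for small p by sign-pattern enumeration: for each
# sign vector s the KKT stationarity system on the active set is solved in
# closed form and checked for sign consistency and inactive-gradient bounds.
lasso_enumeration_oracle <- function(x, y, lambda) {
  n <- nrow(x)
  p <- ncol(x)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    active <- which(s != 0)
    beta <- numeric(p)
    if (length(active) > 0) {
      xa <- x[, active, drop = FALSE]
      beta_a <- try(solve(crossprod(xa) / n,
                          crossprod(xa, y) / n - lambda * s[active]),
                    silent = TRUE)
      if (inherits(beta_a, "try-error")) next
      if (any(sign(beta_a) != s[active])) next
      beta[active] <- beta_a
    }
    grad <- crossprod(x, y - x %*% beta) / n
    if (length(active) > 0 && any(abs(grad[active] - lambda * s[active]) > 1e-9)) next
    inactive <- setdiff(seq_len(p), active)
    if (length(inactive) > 0 && any(abs(grad[inactive]) > lambda + 1e-9)) next
    return(beta)
  }
  stop("enumeration oracle found no KKT-consistent sign pattern")
}

# Enumerate the integer confusion matrix with margins 40 cancer / 22 normal
# that reproduces a printed accuracy and F1 percentage; errors unless the
# solution is unique.
confusion_from_printed <- function(accuracy_pct, f1_pct,
                                   n_cancer = 40, n_normal = 22) {
  total <- n_cancer + n_normal
  hits <- list()
  for (tp in 0:n_cancer) {
    for (fp in 0:n_normal) {
      fn <- n_cancer - tp
      tn <- n_normal - fp
      acc <- 100 * (tp + tn) / total
      f1 <- if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else 0
      if (abs(acc - accuracy_pct) < 5e-7 && abs(f1 - f1_pct) < 5e-7) {
        hits[[length(hits) + 1]] <- c(tp = tp, tn = tn, fp = fp, fn = fn)
      }
    }
  }
  if (length(hits) != 1) {
    stop(sprintf("expected a unique margin-consistent matrix, found %d", length(hits)))
  }
  hits[[1]]
}

# Small well-separated two-class feature fixture.
separable_features <- function(seed, n_cancer = 40, n_normal = 22, d = 2,
                               shift = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_cancer * d, shift), n_cancer, d),
             matrix(rnorm(n_normal * d, 0), n_normal, d))
  list(x = scale(x), labels = c(rep("cancer", n_cancer), rep("normal", n_normal)))
}
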