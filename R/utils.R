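# Internal helpers shared across modules.

CLASS_LEVELS <- c("cancer", "normal")

sc_stop <- function(type, msg, ..., data = NULL) {
  cond <- errorCondition(
    sprintf(msg, ...),
    class = c(paste0("swarmclass_", type, "_error"), "swarmclass_error"),
    data = data
  )
  stop(cond)
}

#' @noRd
check_labels <- function(labels, n = NULL, arg = "labels") {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!is.character(labels)) {
    sc_stop("validation", "%s must be a character vector", arg)
  }
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad) > 0) {
    sc_stop("validation", "%s contains unknown class value(s): %s (allowed: %s)",
            arg, paste(bad, collapse = ", "), paste(CLASS_LEVELS, collapse = ", "))
  }
  if (!is.null(n) && length(labels) != n) {
    sc_stop("structural", "%s has length %d but %d samples are present",
            arg, length(labels), n)
  }
  labels
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded package functions do not perturb the
# user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Adjusted Fisher-Pearson sample skewness (the usual "type 2" estimator).
skewness_adjusted <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- sum((x - m)^2) / n
  if (s2 <= 0) return(NA_real_)
  g1 <- (sum((x - m)^3) / n) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Pearson (non-excess) kurtosis: fourth standardised moment, normal = 3.
kurtosis_pearson <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x)
  s2 <- sum((x - m)^2) / n
  if (s2 <= 0) return(NA_real_)
  (sum((x - m)^4) / n) / s2^2
}

# Column standardisation with training-set statistics; sd floor guards
# constant features.
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

standardize_apply <- function(x, stats) {
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
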