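#' Class-target scheme for score-based training
#'
#' Classifier scores are trained by mean squared error against scalar class
#' targets: `t_normal` for normal samples and `t_cancer` for cancer samples.
#' The defaults (0.85 and 0.1) keep the targets at least 0.5 apart.
#'
#' @param t_normal Target for the normal class, in `[0, 1]` (default 0.85).
#' @param t_cancer Target for the cancer class, in `[0, 1]` (default 0.1).
#' @param min_separation Minimum allowed `|t_normal - t_cancer|`
#'   (default 0.5).
#' @return An object of class `target_scheme`.
#' @export
target_scheme <- function(t_normal = 0.85, t_cancer = 0.1,
                          min_separation = 0.5) {
  scheme <- structure(list(t_normal = t_normal, t_cancer = t_cancer,
                           min_separation = min_separation),
                      class = "target_scheme")
  check_targets(scheme)
}

#' Validate a target scheme
#'
#' Asserts both targets lie in `[0, 1]` and are separated by at least
#' `min_separation`.
#'
#' @param scheme A [target_scheme()].
#' @return The validated scheme, invisibly usable in pipelines.
#' @export
check_targets <- function(scheme) {
  stopifnot(inherits(scheme, "target_scheme"))
  if (scheme$t_normal < 0 || scheme$t_normal > 1 ||
      scheme$t_cancer < 0 || scheme$t_cancer > 1) {
    sc_stop("configuration", "class targets must lie in [0, 1] (got %.3g and %.3g)",
            scheme$t_normal, scheme$t_cancer)
  }
  if (abs(scheme$t_normal - scheme$t_cancer) < scheme$min_separation) {
    sc_stop("configuration",
            "class targets must be separated by at least %.2f (|%.3g - %.3g| = %.3g)",
            scheme$min_separation, scheme$t_normal, scheme$t_cancer,
            abs(scheme$t_normal - scheme$t_cancer))
  }
  scheme
}

#' Mean squared error
#'
#' `(1/N) sum_j (actual_j - predicted_j)^2`.
#'
#' @param actual,predicted Numeric vectors of equal length (N >= 1).
#' @return Scalar mean squared error.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    sc_stop("validation", "actual and predicted lengths differ (%d vs %d)",
            length(actual), length(predicted))
  }
  if (length(actual) == 0) sc_stop("validation", "need at least one element")
  mean((actual - predicted)^2)
}

# Map a continuous score to a class label: nearest target, ties to cancer
# (sensitivity-first tie rule used throughout the package).
score_to_label <- function(score, scheme) {
  ifelse(abs(score - scheme$t_cancer) <= abs(score - scheme$t_normal),
         "cancer", "normal")
}
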