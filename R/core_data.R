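#' Construct an expression dataset
#'
#' Container for a genes x samples microarray intensity matrix with gene and
#' sample identifiers and a binary class label per sample. The cancer class is
#' treated as the positive class throughout the package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. All
#'   entries must be finite.
#' @param gene_ids Character vector of unique gene identifiers (one per row).
#' @param sample_ids Character vector of unique sample identifiers (one per
#'   column).
#' @param labels Character vector of per-sample classes, values in
#'   `c("cancer", "normal")`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, gene_ids, sample_ids, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids)) {
    sc_stop("structural", "matrix has %d rows but %d gene ids",
            nrow(values), length(gene_ids))
  }
  if (ncol(values) != length(sample_ids)) {
    sc_stop("structural", "matrix has %d columns but %d sample ids",
            ncol(values), length(sample_ids))
  }
  if (anyDuplicated(gene_ids)) sc_stop("structural", "duplicate gene ids")
  if (anyDuplicated(sample_ids)) sc_stop("structural", "duplicate sample ids")
  labels <- check_labels(labels, ncol(values))
  if (!all(is.finite(values))) {
    sc_stop("validation", "intensity matrix contains non-finite values")
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d cancer, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "cancer"), sum(x$labels == "normal")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

sniff_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

#' Read a delimited expression matrix
#'
#' Reads a comma- or tab-delimited text matrix (delimiter sniffed from the
#' header line). The first column holds gene identifiers and the header row
#' holds sample identifiers. Class labels come either from a second header
#' row whose first cell is `label`, or from a sidecar file
#' `<path-without-extension>.labels.tsv` with columns sample id and class.
#'
#' @param path Path to the delimited file.
#' @param orientation Either `"genes_in_rows"` (default) or
#'   `"samples_in_rows"`; the returned dataset is always genes x samples.
#' @param label_source `"auto"` (header row if present, else sidecar),
#'   `"header"`, or `"sidecar"`.
#' @return An [expression_dataset()].
#' @export
load_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows"),
                                   label_source = c("auto", "header", "sidecar")) {
  orientation <- match.arg(orientation)
  label_source <- match.arg(label_source)
  if (!file.exists(path)) sc_stop("io", "file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) sc_stop("structural", "file %s has no data rows", path)
  sep <- sniff_sep(lines[[1]])
  split <- strsplit(lines, sep, fixed = TRUE)
  header <- split[[1]]
  col_ids <- header[-1]

  header_labels <- NULL
  body_start <- 2
  second <- split[[2]]
  if (identical(tolower(second[[1]]), "label") && label_source != "sidecar") {
    header_labels <- second[-1]
    body_start <- 3
  }

  body <- split[seq(body_start, length(split))]
  row_ids <- vapply(body, `[[`, character(1), 1)
  n_col <- length(col_ids)
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col)
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    if (length(cells) != n_col) {
      sc_stop("structural", "row '%s' has %d cells, expected %d",
              row_ids[[i]], length(cells), n_col)
    }
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num)) {
      j <- which(is.na(num))[[1]]
      sc_stop("parse", "non-numeric value '%s' at row '%s' (row %d), column '%s' (column %d)",
              cells[[j]], row_ids[[i]], i, col_ids[[j]], j)
    }
    values[i, ] <- num
  }

  if (orientation == "samples_in_rows") {
    values <- t(values)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }

  # resolve labels against the sample identifiers (columns after any
  # orientation normalisation)
  if (!is.null(header_labels)) {
    if (orientation == "samples_in_rows") {
      sc_stop("structural",
              "a label header row labels file columns; use a sidecar label file for samples-in-rows input")
    }
    labels <- header_labels
    if (length(labels) != length(col_ids)) {
      sc_stop("structural", "found %d labels for %d columns",
              length(labels), length(col_ids))
    }
  } else {
    if (label_source == "header") {
      sc_stop("structural", "no label header row found in %s", path)
    }
    sidecar <- paste0(sub("\\.[^.]*$", "", path), ".labels.tsv")
    if (!file.exists(sidecar)) {
      sc_stop("structural", "no label row and no sidecar label file %s", sidecar)
    }
    lab_tab <- utils::read.table(sidecar, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE)
    labels <- lab_tab[[2]][match(col_ids, lab_tab[[1]])]
    if (anyNA(labels)) {
      sc_stop("structural", "sidecar %s is missing labels for some samples", sidecar)
    }
  }
  expression_dataset(values, row_ids, col_ids, labels)
}

#' Write an expression dataset to delimited text
#'
#' Writes a genes x samples matrix that [load_expression_matrix()] inverts
#' exactly: values are serialised with 17 significant digits, so the
#' write/load round trip is bit-exact for doubles. Labels are stored in a
#' second header row. A `.csv` extension selects commas, anything else tabs.
#'
#' @param dataset An [expression_dataset()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (ncol(dataset$values) == 0 || nrow(dataset$values) == 0) {
    sc_stop("structural", "refusing to write an empty dataset (%d genes, %d samples)",
            nrow(dataset$values), ncol(dataset$values))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c(
    paste(c("gene_id", dataset$sample_ids), collapse = sep),
    paste(c("label", dataset$labels), collapse = sep),
    vapply(seq_len(nrow(dataset$values)), function(i) {
      paste(c(dataset$gene_ids[[i]], fmt(dataset$values[i, ])), collapse = sep)
    }, character(1))
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) sc_stop("io", "cannot write to %s", path)
  invisible(path)
}

#' Specification for the synthetic microarray generator
#'
#' Defines the study conditions the generator emulates: a 2000-gene,
#' 62-sample (40 tumour / 22 normal) two-class intensity matrix with
#' strictly positive, right-skewed, heavy-tailed marginals. Intensities are
#' log-normal with block-constant correlation between genes; the first
#' `n_informative` genes carry a log-scale mean shift of `effect_size` in the
#' cancer class.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_cancer,n_normal Per-class sample counts (defaults 40 and 22).
#' @param n_informative Number of differentially expressed genes (default 50).
#' @param effect_size Log-scale mean shift of informative genes in the cancer
#'   class (default 3).
#' @param base_log_mean,base_log_sd Log-normal marginal parameters (defaults
#'   6 and 0.5, giving raw-scale skewness near 1.8 and kurtosis near 9).
#' @param block_size,block_rho Size of correlated gene blocks and the
#'   within-block correlation (defaults 50 and 0.3).
#' @param seed Integer seed; identical specs give bit-identical datasets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_cancer = 40, n_normal = 22,
                           n_informative = 50, effect_size = 3,
                           base_log_mean = 6, base_log_sd = 0.5,
                           block_size = 50, block_rho = 0.3, seed = 1) {
  spec <- list(n_genes = n_genes, n_cancer = n_cancer, n_normal = n_normal,
               n_informative = n_informative, effect_size = effect_size,
               base_log_mean = base_log_mean, base_log_sd = base_log_sd,
               block_size = block_size, block_rho = block_rho,
               seed = as.integer(seed))
  bad <- character(0)
  if (n_genes < 1) bad <- c(bad, "n_genes must be >= 1")
  if (n_cancer < 1 || n_normal < 1) bad <- c(bad, "each class needs >= 1 sample")
  if (n_informative < 0 || n_informative > n_genes) {
    bad <- c(bad, "n_informative must lie in [0, n_genes]")
  }
  if (effect_size < 0) bad <- c(bad, "effect_size must be >= 0")
  if (base_log_sd <= 0) bad <- c(bad, "base_log_sd must be > 0")
  if (block_size < 1) bad <- c(bad, "block_size must be >= 1")
  if (block_rho < 0 || block_rho >= 1) bad <- c(bad, "block_rho must lie in [0, 1)")
  if (length(bad) > 0) {
    sc_stop("validation", "invalid synthetic_spec: %s", paste(bad, collapse = "; "))
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic two-class microarray dataset
#'
#' Draws `exp(Gaussian)` intensities with block-constant gene-gene
#' correlation. For sample s and gene g in block b,
#' `log X[g,s] = mu_g + sd * (sqrt(rho) Z_b(s) + sqrt(1-rho) E_g(s))`,
#' with `mu_g` shifted by `effect_size` for informative genes in cancer
#' samples. Labels are `n_cancer` cancers followed by `n_normal` normals.
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_dataset()], deterministic given `spec` (including
#'   its seed).
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_s <- spec$n_cancer + spec$n_normal
  n_g <- spec$n_genes
  block <- ((seq_len(n_g) - 1) %/% spec$block_size) + 1
  n_blocks <- max(block)
  with_seed(spec$seed, {
    shared <- matrix(stats::rnorm(n_blocks * n_s), n_blocks, n_s)
    eps <- matrix(stats::rnorm(n_g * n_s), n_g, n_s)
    z <- sqrt(spec$block_rho) * shared[block, , drop = FALSE] +
      sqrt(1 - spec$block_rho) * eps
    logx <- spec$base_log_mean + spec$base_log_sd * z
    if (spec$n_informative > 0 && spec$n_cancer > 0) {
      idx <- seq_len(spec$n_informative)
      logx[idx, seq_len(spec$n_cancer)] <-
        logx[idx, seq_len(spec$n_cancer), drop = FALSE] + spec$effect_size
    }
    values <- exp(logx)
    labels <- c(rep("cancer", spec$n_cancer), rep("normal", spec$n_normal))
    sample_ids <- c(sprintf("cancer_%02d", seq_len(spec$n_cancer)),
                    sprintf("normal_%02d", seq_len(spec$n_normal)))
    expression_dataset(values, sprintf("g%04d", seq_len(n_g)), sample_ids, labels)
  })
}

#' Split samples into training and test index sets
#'
#' Stratified (default) or plain random partition. The rounding rule is
#' fixed: the training side takes `floor(fraction * n)` samples (per class in
#' stratified mode) and the remainder goes to the test side, so counts are
#' deterministic.
#'
#' @param dataset An [expression_dataset()].
#' @param train_fraction Proportion of samples assigned to training
#'   (default 0.85).
#' @param seed Integer seed for the shuffle.
#' @param stratified Preserve class proportions per partition (default TRUE).
#' @return A list with integer index vectors `train` and `test`; together
#'   they cover all samples exactly once.
#' @export
train_test_split <- function(dataset, train_fraction = 0.85, seed = 1,
                             stratified = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    sc_stop("validation", "train_fraction must lie strictly between 0 and 1")
  }
  labels <- dataset$labels
  n <- length(labels)
  with_seed(seed, {
    if (stratified) {
      train <- integer(0)
      for (cls in CLASS_LEVELS) {
        idx <- which(labels == cls)
        if (length(idx) == 0) next
        n_train <- floor(train_fraction * length(idx))
        if (n_train == 0) {
          sc_stop("validation",
                  "train_fraction %.3f leaves class '%s' with an empty training partition",
                  train_fraction, cls)
        }
        train <- c(train, sample(idx, n_train))
      }
    } else {
      n_train <- floor(train_fraction * n)
      if (n_train == 0 || n_train == n) {
        sc_stop("validation", "train_fraction %.3f leaves an empty partition",
                train_fraction)
      }
      train <- sample(n, n_train)
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}
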