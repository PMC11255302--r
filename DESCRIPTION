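Package: swarmclass
Title: Swarm-Intelligence Feature Extraction and Classification for
    Two-Class Microarray Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a metaheuristic-integrated machine-learning stack for
    binary (tumour versus normal) classification of microarray gene-expression
    matrices. Feature extraction by short-time Fourier transform spectra,
    L1-penalised (lasso) gene selection, or an elephant-herding wrapper;
    classification by Gaussian mixture models (optionally tuned by particle
    swarm, firefly, or flower-pollination optimisers with Mantegna Levy
    flights), detrended fluctuation analysis, Gaussian naive Bayes, and a
    radial-basis support vector machine. Includes a seeded synthetic
    microarray generator, stratified pooled K-fold evaluation, and the full
    confusion-matrix metric suite (accuracy, F1, MCC, error rate, Cohen's
    kappa with agreement bands).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
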