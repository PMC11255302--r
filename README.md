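# swarmclass

Swarm-intelligence feature extraction and classification for two-class
microarray gene-expression data.

## What it is for

Bulk microarray studies produce a genes × samples intensity matrix — on the
order of 2000 genes against a few dozen samples — and ask whether a sample
is tumour or normal. With far more features than samples, naive classifiers
overfit badly, so the practical pipeline is: reduce the dimensionality
first, then classify, and evaluate with chance-corrected agreement
statistics rather than accuracy alone. `swarmclass` implements that
pipeline end to end for the two-class (cancer vs. normal, cancer positive)
setting, for method researchers who want a reproducible, fully seeded
reference implementation to probe and compare.

Three feature extractors:

* **STFT** — each sample's gene-intensity vector is treated as a sequence
  and windowed-Fourier transformed (Blackman window,
  `w[n] = 0.42 − 0.5 cos(2πn/M) + 0.08 cos(4πn/M)`, M = 256, hop 128);
  per-frame summaries of |X(m, ω)| become 45 spectral features.
* **LASSO** — embedded gene selection by L1-penalised regression of the
  ±1 class labels on standardised genes,
  `argmin (1/2n)‖y − Xβ‖² + λ‖β‖₁`, solved by compiled cyclic coordinate
  descent with warm-started penalty paths and cross-validated λ.
* **EHO** — a wrapper selector driven by elephant-herding optimisation
  over continuous gene scores, with a single-Gaussian-per-class scorer's
  training MSE as fitness.

Seven classifiers: a per-class Gaussian mixture model (Bayes rule over
per-class mixture densities), the same model post-tuned by particle swarm,
firefly, or flower-pollination optimisation (Mantegna Lévy flights,
`s = U/|V|^{1/λ}`), detrended fluctuation analysis (nearest class mean on
the scaling exponent), Gaussian naive Bayes with a variance-floor
smoothing factor, and an RBF-kernel SVM. Classifier scores are trained
against scalar class targets (normal 0.85, cancer 0.10) under a mean
squared error criterion, and evaluated by stratified pooled K-fold
cross-validation with the full confusion-matrix metric suite: accuracy,
precision/recall/F1, error rate, Matthews correlation and Cohen's kappa
with the poor/fair/moderate/good/very good banding.

A seeded synthetic generator emulates the reference study conditions
(2000 × 62, 40/22 class split, log-normal block-correlated intensities,
configurable differentially expressed genes), so everything is testable
without external downloads.

## Worked example

```r
library(swarmclass)

ds <- generate_synthetic_dataset(synthetic_spec(seed = 42))
ds
#> expression_dataset: 2000 genes x 62 samples (40 cancer, 22 normal)

panel <- lasso_features(ds, lasso_config(target_n_features = 20), seed = 42)
panel
#> feature_matrix [lasso]: 62 samples x 18 features
sum(panel$selected_gene_indices <= 50)   # truly informative genes recovered
#> [1] 15

res <- cross_validate(panel, "fpo_gmm", cv_plan(k = 10, seed = 42))
res$cm
#> confusion_matrix: TP=40 TN=22 FP=0 FN=0
res$metrics
#> accuracy 1.0000 | F1 1.0000 | MCC 1.0000 | error 0.0000 | kappa 1.0000 (very good)
```

The lasso panel recovers 15 of the 50 planted genes (18 selected in total —
with correlated gene blocks the lasso keeps representatives, not whole
blocks), and the flower-pollination-tuned mixture classifier then separates
the classes perfectly in pooled 10-fold cross-validation. The same
pipeline on the 45 spectral features is harder, because the planted signal
sits in a single frame:

```r
res2 <- cross_validate(stft_features(ds), "gmm", cv_plan(k = 10, seed = 42))
res2$metrics
#> accuracy 0.8548 | F1 0.8941 | MCC 0.6776 | error 0.1452 | kappa 0.6659 (good)
```

Metrics can also be computed directly from counts; `kappa` ≈ `mcc` is the
expected near-agreement for margin-balanced matrices:

```r
compute_metrics(confusion_counts(tp = 37, tn = 20, fp = 2, fn = 3))
#> accuracy 0.9194 | F1 0.9367 | MCC 0.8261 | error 0.0806 | kappa 0.8256 (very good)
```

`benchmark()` runs the full extractor × classifier grid and returns a
tidy table (`method`, `classifier`, `accuracy`, `f1`, `mcc`, `error_rate`,
`kappa`, `seed`).

## Command line

A thin CLI wraps the same functions:

```sh
swarmclass simulate  --out data.csv --seed 1
swarmclass extract   --in data.csv --method lasso --out feats.tsv --seed 1
swarmclass classify  --features feats.tsv --classifier svm_rbf --out pred.tsv
swarmclass evaluate  --predictions pred.tsv --out metrics.json
swarmclass benchmark --in data.csv --out results.tsv --k 10
```

(Installed under `<library>/swarmclass/exec/swarmclass`; run via `Rscript`
or add it to your `PATH`.)

## Package layout

* `R/core_data.R` — dataset container, delimited I/O, synthetic generator,
  train/test split.
* `R/metaheuristics.R` — EHO, PSO, firefly and flower-pollination
  optimisers behind one minimise-this-fitness contract; Lévy sampler.
* `R/feature_extraction.R`, `src/lasso_cd.cpp` — STFT, lasso and wrapper
  extractors.
* `R/classifiers_gmm.R`, `R/classifiers_other.R`, `R/targets.R` — the seven
  classifiers and the class-target/MSE training scheme.
* `R/evaluation.R` — metrics, pooled cross-validation, class statistics,
  canonical correlation, benchmark grid.
* `vignettes/swarmclass-methods.Rmd` — the model, its assumptions, design
  decisions and known limitations.
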