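---
title: "Methods: swarm-tuned mixture classification of two-class expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-tuned mixture classification of two-class expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmclass)
```

## The problem

Bulk microarray experiments produce a genes × samples matrix of fluorescence
intensities — typically a few thousand genes against a few dozen samples.
Classifying such samples into tumour versus normal suffers from the curse of
dimensionality: with ~2000 features and ~62 samples, almost any classifier
can separate the training data, and almost none of that separation
generalises. `swarmclass` implements a pipeline that tackles this in two
stages: a dimensionality-reducing **feature extractor**, followed by a
**classifier** whose continuous output is trained against scalar class
targets, with population metaheuristics used both as a wrapper feature
selector and as a post-hoc tuner of the mixture classifier.

The reference conditions are the Alon et al. colon adenocarcinoma matrix:
2000 genes, 62 samples, 40 tumour ("cancer") and 22 normal. The cancer class
is the positive class everywhere (true positives are correctly identified
cancers).

## The synthetic generator

The package ships no real data; `generate_synthetic_dataset()` emulates the
reference conditions so the whole pipeline is testable offline:

* **Shape**: 2000 genes × (40 cancer + 22 normal) samples by default.
* **Marginals**: raw intensities are log-normal,
  $\log X_{gs} = \mu + \sigma z_{gs}$ with $\mu = 6$, $\sigma = 0.5$. This
  puts raw-scale skewness near 1.7 and Pearson kurtosis near 8, i.e. the
  strongly right-skewed, heavy-tailed regime that raw microarray
  intensities and their spectral summaries exhibit.
* **Correlation**: genes come in blocks of 50 with within-block correlation
  ρ = 0.3 on the log scale (`z = √ρ · shared + √(1−ρ) · noise`), a crude but
  serviceable stand-in for co-regulated gene modules.
* **Signal**: the first `n_informative` genes (default 50) get a log-mean
  shift of `effect_size` (default 3) in the cancer class.

Defaults were fixed once from the reference dataset's shape and the
reported feature statistics; they are study conditions, not tuning knobs.
What the generator does **not** emulate: probe-level noise structure,
array batch effects, intensity-dependent variance, or any label noise.
Passing tests on this generator therefore demonstrates correctness of the
algorithms under a clean mean-shift signal, not clinical performance.

Identical `synthetic_spec`s (including the seed) give bit-identical
matrices, and `write_expression_matrix()` serialises with 17 significant
digits so the file round trip is exact.

## Feature extraction

**Spectral (STFT).** Each sample's 2000-long gene-intensity vector is
treated as a sequence in file order and passed through a windowed Fourier
transform: Blackman window `0.42 − 0.5 cos(2πn/M) + 0.08 cos(4πn/M)`,
window length M = 256, hop 128, with the tail zero-padded so the final
partial frame is kept — 15 frames for 2000 genes. Per frame we emit mean
|X|, max |X| and the spectral energy Σ|X|², i.e. 45 features per sample.
Whether the original study transformed along genes or along samples is not
deducible from its text; per-sample transformation is the reading
consistent with per-class feature statistics, and the axis is a config
choice. The per-frame statistic set is this package's design: the raw
spectrogram would multiply, not reduce, the dimensionality.

**Lasso.** Binary labels are encoded −1/+1 (cancer = +1) and used as a
centred regression response against standardised genes; the penalty path is
solved by cyclic coordinate descent with soft-thresholding (compiled, with
residual updating, warm starts along a descending 50-point log grid from
λ_max = max|Xᵀy|/n down to 10⁻³λ_max, and active-set cycling between full
sweeps). The penalty is chosen by 10-fold cross-validated squared error, or
by an explicit `target_n_features` cap. Selected genes are returned as raw
intensities. Note that with correlated informative blocks the lasso keeps
representatives and drops correlated companions — recovering *all*
informative genes is not expected behaviour.

**Elephant-herding wrapper.** Positions are continuous scores in
[0,1]^2000; a candidate subset is the top-`n_select` scores; the wrapper
fitness is the training-resubstitution mean squared error of a lightweight
single-Gaussian-per-class scorer (diagonal covariances) against the class
targets, and the herding optimiser minimises it. The fitness is this
package's construction — the source text never defines one — chosen to tie
the wrapper to the same target/MSE training contract the classifiers use.
A caveat discovered in testing and worth stating: once any candidate subset
separates the training classes, the resubstitution MSE saturates at ~0 and
the search loses its gradient, so the recovered subset is only partially
enriched for truly informative genes.

## The metaheuristics

All four optimisers minimise a fitness over box bounds, clamp every emitted
position into the bounds, stop at `max_iter` **or** when the best fitness
falls to the tolerance (default 10⁻⁷), and keep an elitist archive so the
reported best-fitness trace is non-increasing. Identical seeds reproduce
identical traces.

* **EHO** (single herd): each individual moves toward a guide by
  `x + γ(guide − x)·rand`, the guide is then replaced by δ times the herd
  centre, and the worst individual is re-seeded over
  `lower + (upper − lower + 1)·rand` and clamped. The guide replacement can
  worsen the guide; the elitist archive is what makes the reported best
  monotone. With a population of one the re-seed is skipped (the sole
  member is simultaneously best and worst).
* **PSO**: classic inertia/constriction velocity update (defaults w = 0.7,
  c1 = c2 = 1.5), fresh scalar r1, r2 per particle per iteration, strict
  improvement updates of personal/global bests.
* **Firefly**: brightness is −fitness, cached at iteration start; for every
  ordered pair with a strictly brighter partner the attraction term
  `β·I₀·exp(−γ r²)·(x_j − x_i)` is applied (ties attract nobody), and every
  firefly takes one random step `α(U(0,1) − 0.5)` per dimension per
  iteration. The source's update rule is written as a difference of scalar
  intensities; the displacement form used here is the standard formulation
  that the stated limiting behaviours (γ = 0, γ → ∞) require.
* **FPO**: with probability ρ = 0.65 a global pollination step
  `x + δ·L·(gbest − x)` with one Mantegna Lévy draw per dimension
  (σ = {Γ(1+λ)sin(πλ/2)/(λΓ((1+λ)/2)2^((λ−1)/2))}^(1/λ); λ = 1.5 gives
  σ ≈ 0.6966), otherwise a local step `x + ε(x_j − x_k)` with distinct
  random partners (hence population ≥ 3). Moves are accepted greedily —
  the source does not state an acceptance rule, and unconditional
  acceptance would make convergence untestable.

## Classifiers and the target/MSE contract

Scores are trained against scalar class targets `t_normal = 0.85` and
`t_cancer = 0.10` (validated to be ≥ 0.5 apart); a model's continuous score
is the posterior-weighted combination of the two targets and its training
quality is the mean squared error against the per-sample targets. All label
ties resolve toward cancer (sensitivity first).

**GMM.** Per class, a G-component Gaussian mixture (default G = 2) fitted
by EM with k-means++ seeding; priors are class frequencies. Covariances are
full but regularised: shrunk toward their diagonal with intensity
D/(D + N_c) and ridged by 10⁻⁶·trace/D (escalated tenfold until the
Cholesky factorisation succeeds). The shrinkage term goes beyond a bare
ridge because with D ≈ 45 features and 20–40 samples per class the
empirical covariance is singular and a tiny ridge alone yields degenerate
likelihoods; the chosen intensity vanishes when N_c ≫ D, so
low-dimensional fits are essentially unshrunk. The per-class log-likelihood
is recorded at every EM step and is non-decreasing.

**Hybrid (PSO/Firefly/FPO) GMM.** The source describes the metaheuristics
as changing the mixture's means, covariances and mixing coefficients; the
implementable reading used here is that the optimiser searches the
flattened parameter vector (means, log diagonal covariances, weight logits
per class), initialised at the EM solution with the EM vector included in
the starting population, minimising the training target MSE. The returned
model therefore never scores worse on training MSE than its EM
initialisation, and a zero-iteration budget returns the EM initialisation
exactly. The alternative reading — that the optimisers transform the data —
is not implementable from the text.

**DFA.** Each sample's feature vector is treated as a series: cumulative
sum of the mean-centred values, windows at sizes growing geometrically by
1.6 from 4 up to a quarter of the length (half for short series, so at
least two ladder rungs exist), 50% overlap, linear detrend per window; the
scaling exponent is the slope of log F(n) on log n. White noise gives
≈ 0.5, integrated noise ≈ 1.5. Classification learns per-class mean
exponents on training data and assigns test samples to the nearer mean.
A constant series has a zero profile and is reported as exponent 0 with a
degeneracy flag rather than NaN.

**Naive Bayes.** Gaussian per-feature likelihoods in log space. The
configured smoothing factor α = 0.06 is interpreted as a variance floor —
every class-feature variance is floored at α times the largest overall
feature variance — because a Gaussian NB has no Laplace-count analogue.

**SVM-RBF.** Kernel `exp(−‖x−z‖²/2σ²)`; the soft-margin dual is solved by
the SMO-type solver in libsvm (via e1071) behind the package's interface,
with decision values recomputed from the support vectors so cancer = +1 is
guaranteed regardless of data ordering. Function defaults keep σ = 0.1 and
C = 1.

## Evaluation

`confusion_matrix()` orients TP to cancer. `compute_metrics()` implements
accuracy, precision/recall/F1, error rate (computed as 1 − accuracy so the
identity is exact in floating point), MCC, and Cohen's kappa from observed
and chance agreement; degenerate denominators yield flagged zeros. Kappa
bands are poor/fair/moderate/good/very good at 0.2/0.4/0.6/0.8 with
boundaries in the upper band.

Cross-validation is stratified K-fold (default K = 10) with **pooled**
out-of-fold predictions: metrics are computed once on the pooled confusion
matrix so denominators equal the full sample count — the only reading under
which published per-classifier metrics with denominator 62 are consistent.
The 85/15 holdout (`train_test_split()`, per-class floor on the training
side, so 62 samples split 52/10) is available as a separate mode.

Class-level feature statistics report, per class, the pooled mean, unbiased
variance, adjusted Fisher–Pearson skewness, Pearson kurtosis (normal = 3)
and mean off-diagonal Pearson correlation; the cross-class association is
the first canonical correlation of the whitened cross-covariance (ridge
10⁻⁸ for rank deficiency). Because the two classes have unequal sizes, CCA
pairing truncates both classes to the smaller size after ranking samples
within class by their feature mean — a deterministic, documented
interpretation; no published value for this quantity is reproduced.

## Benchmark configuration

`benchmark()` runs each extractor once per dataset and cross-validates
every classifier on the extracted features (extraction is not nested inside
the folds; the per-class statistics of the published workflow are likewise
computed on full-data features). Its defaults differ from the bare function
defaults in three places, all package design choices:

* the lasso extractor uses a fixed 20-gene panel (`target_n_features = 20`)
  so every downstream classifier's input contract holds — DFA needs at
  least a 16-long series — and so feature counts are comparable with the
  20-gene wrapper;
* the SVM kernel width defaults to the median-pairwise-distance heuristic
  on the standardised features (the fixed σ = 0.1 presumes features on
  that scale);
* the hybrid optimiser budgets are small (populations 15–20, 15–25
  iterations) because the search starts at the EM optimum and only refines
  it; Table-scale budgets (population 200, 1000 iterations) remain the
  documented defaults of the parameter constructors.

GMM-family, NBC and SVM classifiers see column-standardised features
(training-fold statistics); DFA sees the raw per-sample series, since the
exponent is invariant to the affine per-feature rescaling anyway.

## Numerical choices

* Seeded runs restore the caller's RNG state; every public stochastic
  function takes an explicit integer seed.
* Coordinate descent converges on the maximum coefficient change
  (default 10⁻⁶; the per-sweep objective trace is exposed and
  non-increasing).
* Mixture EM stops on a 10⁻⁷ relative log-likelihood change or 100
  iterations.
* Exact-zero lasso coefficients are genuine zeros (soft threshold), so
  "number of selected genes" is well defined without a tolerance.
* Optimiser positions are clamped, not reflected, at the bounds.
* All probability computations are done in log space with log-sum-exp
  normalisation.

## Known limitations

* On the default synthetic conditions the spectral features dilute the
  50-gene signal (only the first frame's statistics carry it), capping
  pooled 10-fold accuracy of every classifier near 0.75–0.94; and the DFA
  exponent, being invariant to the location and scale of a sample's
  feature series, carries almost no information about a pure mean-shift
  class difference, so DFA accuracy hovers near chance on lasso/EHO panels.
  Both are properties of the methods, not implementation artefacts; the
  selection-based extractors with the mixture/NBC/SVM classifiers reach
  0.9–1.0 under the same conditions.
* The wrapper selector's fitness saturates on separable training data (see
  above), limiting its enrichment of truly informative genes.
* A handful of configured constants in the source material (a GMM "test
  point likelihood probability" of 0.1 and "convergence rate" of 0.6) have
  no defined role in the stated model equations; they are accepted in
  configuration for completeness but deliberately unused.
* No multiclass support, no probability calibration, no kernels beyond the
  RBF, and no hyperparameter search — matching the stated scope.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run the full 2000 × 62 pipeline: a
five-seed 3 × 7 benchmark grid (~8 s per seed), DFA exponent recovery at
length 4096, 10⁵ Lévy draws, and 10-seed optimiser convergence studies on
1-D and 2-D toy objectives. These sizes were chosen so the whole suite
completes in a few minutes on one CPU while keeping every check at the
study's native data scale.
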