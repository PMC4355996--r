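---
title: "Sparse quadratic discriminant analysis: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse quadratic discriminant analysis: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseqda)
```

## The problem

Gene-expression classification problems routinely have tens of thousands of
features and tens of samples. Linear discriminant analysis (LDA) fails
outright in this regime because the pooled sample covariance is singular,
and the common workaround — assuming a diagonal covariance (DLDA/DQDA) —
throws away the correlation structure among genes. Worse, LDA-type rules
assume both classes share one covariance matrix, while tumor and normal
tissues are known to *rewire* their co-expression networks: the covariance
itself carries class information that a quadratic rule can exploit and a
linear rule cannot.

`sparseqda` implements a quadratic discriminant analysis whose per-class
covariance matrices are estimable at `p >> n`: each class's covariance is
assumed block-diagonal, and each block is estimated by a sparse,
positive-definite penalized fit. The package also provides the standard
comparators (DLDA, DQDA, SCRDA, nearest neighbour, and block-selection
variants DLDA2/DQDA2), a simulator for four benchmark covariance regimes,
and a replicated benchmarking harness.

## The model

Observations from class $k$ are modelled as $X \mid Y = k \sim
N(\mu_k, \Sigma_k)$, and a new sample is assigned by maximum likelihood:

$$\hat Y(x) = \arg\max_k \log f(x \mid \mu_k, \Sigma_k).$$

No prior term is used; the rule is pure maximum likelihood, and ties are
broken toward the earlier class label so results are reproducible. With
block-diagonal $\Sigma_k$ both the log-determinant and the quadratic form
decompose over blocks, so density evaluation never touches a full
$p \times p$ matrix.

### Sparse covariance estimation per block

For a block of $d$ features in class $k$, the sample correlation matrix
$\hat R$ is shrunk by solving

$$\tilde R_\lambda \;=\; \arg\min_{R \succ 0}\;
  \tfrac12 \lVert R - \hat R\rVert_F^2 \;-\; \tau \log |R|
  \;+\; \lambda \lvert R^- \rvert_1,$$

where $R^-$ is $R$ with the diagonal zeroed. The Frobenius term keeps the
estimate close to the data, the log-determinant barrier ($\tau > 0$)
guarantees strict positive definiteness even when $d$ exceeds the class
sample size, and the L1 term zeroes weak partial correlations exactly. The
estimate is mapped back to the covariance scale as
$D^{1/2} \tilde R_\lambda D^{1/2}$ with $D$ the diagonal matrix of sample
variances.

**Solver.** The objective splits into a smooth part (Frobenius + barrier)
and the nonsmooth L1 part, so we use a proximal-gradient scheme: a gradient
step on the smooth part followed by soft-thresholding of the off-diagonal
entries, with a backtracking line search that rejects any step leaving the
positive-definite cone (the Cholesky factorization fails there, which is
also the cheapest possible PD test). A Nesterov-type extrapolation is
layered on top, but an extrapolated step is only accepted when it does not
increase the objective, so the objective sequence is monotone
non-increasing, which makes non-convergence diagnosable; the returned
solution's objective is verified against independent dense searches in the
test suite. The inner loop is implemented in C++
(RcppArmadillo), since the pipeline solves this problem hundreds of times
per fit.

At $\lambda = 0$ the minimizer has a closed form: it shares eigenvectors
with $\hat R$, and each eigenvalue $e$ maps to $(e + \sqrt{e^2 + 4\tau})/2$
(the positive root of the stationarity condition $x^2 - ex - \tau = 0$).
This closed form is the solver's warm start, the exact solution returned
for $\lambda = 0$ and $d = 1$, and an oracle for the tests.

**Numerical choices.**

* $\tau = 10^{-4}$ by default: small enough that well-conditioned inputs
  are essentially unperturbed (the diagonal of an exact-correlation input
  moves to $\approx 1 + 10^{-4}$), large enough to keep every iterate
  usably conditioned. It is exposed as an argument.
* Convergence requires both the maximum entrywise change between iterates
  and the relative objective change to fall below `tol = 1e-7`
  (`max_iter = 1000`), and additionally requires near-stationarity of the
  minimal subgradient: close to the positive-definite boundary the line
  search shrinks steps so much that movement-based criteria alone can fire
  long before optimality. Non-convergence returns the last iterate with
  `converged = FALSE` and a warning, never an error.
  Cross-validation refits inside the pipeline silence that warning (the
  last iterate still scores the block); final fits surface it.
* Off-diagonal magnitudes below `1e-10` are snapped to exact zeros after
  convergence so sparsity patterns are well defined; soft-thresholding
  already produces exact zeros, so this only cleans up round-off.
* A first-order stationarity measure (max-norm of the minimal subgradient)
  is reported with every solution.

## The pipeline

1. **Ranking.** Features are ordered by absolute pooled two-sample
   t statistic (one-way ANOVA F beyond two classes). The pooled rather
   than Welch form is used: the simulation regimes and typical expression
   data have comparable within-class spread, and the pooled form matches
   the classical DLDA/DQDA literature. Genes with similar
   mean-difference evidence — and, in correlated blocks, similar
   statistics — end up adjacent, which is what makes a block-diagonal
   approximation in the *ranked* order reasonable.
2. **Blocking.** Consecutive runs of `block_size` features (default 100)
   form blocks; a trailing remainder that cannot fill a block is dropped —
   by construction those are the least informative features. Ranking ties
   break toward the lower original index, making the layout deterministic.
3. **Variable selection by blocks.** Each block is scored in isolation by
   stratified 5-fold cross-validated misclassification of a per-block QDA
   whose covariance is the sparse estimate at a fixed screening sparsity
   $\lambda = 0.2$. Blocks within `error_margin` (default 0.05) of the best
   block are retained; the best block is always retained.
4. **Per-block sparsity tuning.** For each retained block, $\lambda$ is
   chosen from `{0.01, 0.05, 0.1, 0.2, 0.3, 0.5}` by the same
   cross-validation, shared across classes; ties go to the smallest
   $\lambda$ (the densest of the tied fits). The grid brackets the
   screening value and spans near-dense to essentially diagonal fits.
   Tuning is per block in isolation — blocks are independent under the
   model, and this keeps the work embarrassingly parallel.
5. **Final model.** Per class: means over the retained features and one
   sparse covariance estimate per retained block at its tuned $\lambda$.
   Prediction is the maximum-likelihood rule above.

`dlda2()` and `dqda2()` run the same ranking and selection path with the
sparse estimator replaced by the pooled-diagonal and per-class-diagonal
estimators; comparing them with `sqda()` isolates the value of estimating
correlations from the value of the block-selection procedure itself.

Cross-validation everywhere is stratified by class and seeded: one integer
seed determines the folds, hence the whole fit. The same seed, data, and
configuration reproduce the identical model and predictions.

### Defaults and their provenance

* `block_size = 100`, `error_margin = 0.05`: sweeps across the bundled
  simulation regimes show performance flat and near-optimal at these
  values (reproducible via `benchmark_sweep()`), so they are the defaults
  for all analyses.
* Screening $\lambda = 0.2$ during block selection.
* 5-fold stratified CV for every tuning loop, for consistency with the
  comparators' tuning.
* Variance estimators use $n_k - 1$ (and pooled variances the summed
  within-class degrees of freedom); the classical unbiased choice.

## Comparators

* **SCRDA**: the pooled covariance is shrunk toward the identity,
  $\tilde\Sigma = \alpha\hat\Sigma + (1 - \alpha)I$ (a correlation-scale
  variant is available), and the transformed centroids
  $\tilde\Sigma^{-1}\bar x_k$ are soft-thresholded at $\Delta$. The pair
  $(\alpha, \Delta)$ is tuned by CV with the MIN-MIN rule: among tied
  pairs, fewest nonzero score components, then the larger $\Delta$, then
  the smaller $\alpha$. The default grids
  ($\alpha \in \{0, .25, .5, .75, .99\}$,
  $\Delta \in \{0, .5, \dots, 3\}$) follow common practice for this
  estimator; with $\alpha = 1, \Delta = 0$ the rule provably reduces to
  dense LDA, which the tests exploit. If every score shrinks to zero the
  fit warns and falls back to nearest-centroid classification in the
  $\tilde\Sigma$ metric.
* **Nearest neighbour**: Euclidean 3-NN by default; vote ties go to the
  class of the single nearest neighbour, making the rule deterministic.
* **DLDA/DQDA (+ NN, SVM)** are combined with a top-gene screen: the count
  of top-ranked genes is tuned over 50–2000 in steps of 50 by stratified
  CV, with genes ranked once on the full training set. Ranking outside the
  folds makes the CV errors optimistic at small counts (the held-out
  labels influenced the ranking) and, with the smallest-count tie rule,
  biases the screen towards small gene sets — this mirrors the classical
  screening protocol these comparators reproduce, and the resulting counts
  and test errors match its published behaviour. Only the count, never the
  test error, is taken from these optimistic CV estimates.
* **SVM and random forest** are delegated to `e1071` and `randomForest`
  when installed — they carry no formulas specific to this method and
  re-implementing them would add nothing; the benchmark records a failure
  for them otherwise.

The gene ranking used by the screen is the plain two-sample t statistic
rather than an empirical-Bayes moderated statistic; at the sample sizes
involved the two orderings nearly coincide, and this keeps the package
self-contained; it is a deliberate substitution for the empirical-Bayes
moderated statistics common in this literature.

## The simulator

`sim_spec()`/`generate_data()` produce two balanced classes ("tumor",
"normal") of Gaussian expression-like data under four regimes:

| regime | covariance | classes differ in |
|--------|------------|-------------------|
| ISSC | identity | means only |
| ISDC | diagonal; class 1's first 400 variances are 1.5 | means + variances |
| DSSC | 200-dim AR blocks alternating $\rho = \pm 0.95$ | means only |
| DSDC | as DSSC, but class 2 swaps the sign order of the first two blocks | means + correlations |

Class 1 has mean 0.5 on its first 400 coordinates (class 2 is centred);
defaults are $p = 10{,}000$, 50 training and 500 test samples per class.
The alternation of block signs continues down the whole diagonal. Sampling
is per block via a Cholesky factor computed once per distinct block, so the
full $p \times p$ covariance is never materialized.

What the generator does *not* emulate: count-scale noise, skewness and
heavy tails of real RNA-seq, batch effects, unbalanced classes, and
covariance structure that ignores the t-ranking (real co-expression blocks
do not align with mean-difference order). Passing benchmarks here
demonstrates correctness of the machinery and behaviour under the stated
Gaussian regimes — not performance claims about any particular real
dataset.

## Problem sizes used by the tests and the acceptance script

Full-size SQDA runs (p = 10,000) take tens of CPU-minutes per replicate,
which is out of proportion for a routine check, so the packaged
experiments run a reduced configuration chosen to preserve the *signal
geometry*: the feature dimension is reduced (p = 1000–2000) while the
signal block (400 informative features, mean shift 0.5, AR parameter 0.95,
200-dim AR blocks) and the per-class training size (50) are kept at their
full-size values. Shrinking everything proportionally (the `scale`
argument of `sim_spec()`) would instead shrink the between-class
Mahalanobis distance and inflate error rates, making results incomparable
with the full-size regime. Under dimension-only reduction the Bayes error
and the estimation task per block are unchanged; only the number of pure
noise blocks shrinks, so measured error rates are comparable with — and if
anything slightly favourable to — the full-size configuration. Cheap
methods (DLDA, DQDA, NN) are run at the full p = 10,000 scale. One known
consequence: the *number of blocks* passing the error-margin rule depends
on how much ranking contamination noise features contribute, so
selected-feature counts at reduced p can sit below their full-scale
counterparts. Regimes whose blocks solve quickly (the diagonal-covariance
ones) are additionally run at the full p = 10,000.

## Known limitations

* Block structure is imposed by the t-statistic ordering and a fixed block
  size, not learned from the correlation structure; data whose
  co-expression modules are unrelated to mean differences will be
  approximated crudely.
* Per-block tuning optimizes each block's own CV error, not the error of
  the assembled model; this matches the method's independence assumption
  and keeps the computation parallel.
* Multi-class fitting works (F-statistic ranking, per-class estimates) but
  the packaged benchmark regimes are binary.
* The block-selection error margin operates on CV error estimated from a
  handful of samples per fold; with very small classes its granularity is
  coarse and a larger margin may be warranted.
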