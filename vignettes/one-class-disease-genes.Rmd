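---
title: "One-class classification for disease-gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class classification for disease-gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocgene)
```

## The problem

Known disease genes form a positive class; everything else is *unlabeled*,
not negative — an unknown gene may simply be an undiscovered disease gene.
Training a binary classifier with unlabeled genes as pseudo-negatives
therefore injects label noise, and evaluating against pseudo-negative test
labels punishes exactly the discoveries one is after. `ocgene` treats the
task as what it is: one-class classification with positive-unlabeled (PU)
evaluation. Genes are represented by their expression profiles — gene
$g$'s feature vector is its row of a genes × samples matrix, one feature
per sample — so that co-regulated disease genes cluster in feature space.

The package's reference use case is an acute myeloid leukemia (AML)
microarray benchmark (GEO series GSE9476, 38 normal and 26 AML samples,
platform GPL96) in which differential expression defines 1174 positive
and 1300 unlabeled genes. The benchmark files themselves are too large to
ship; `run_benchmark_experiment()` consumes them in their published two-file
CSV layout (a positives matrix and the complete matrix) when available,
and the whole pipeline is exercised on synthetic data otherwise.

## The one-class model

### ν-one-class SVM

For training vectors $x_1,\dots,x_l$ mapped by a kernel feature map
$\phi$, the ν-one-class SVM separates the data from the origin with
maximum margin:

$$\min_{w,\rho,\xi}\; \tfrac12\|w\|^2 - \rho + \tfrac{1}{\nu l}\sum_i \xi_i
\quad\text{s.t.}\quad w\cdot\phi(x_i) \ge \rho - \xi_i,\; \xi_i \ge 0 .$$

`ocsvm()` solves the equivalent dual

$$\min_\alpha \tfrac12 \alpha^\top K \alpha \quad\text{s.t.}\quad
0 \le \alpha_i \le \tfrac{1}{\nu l},\;\; \textstyle\sum_i \alpha_i = 1,$$

with $K_{ij} = k(x_i, x_j)$, and recovers
$w = \sum_i \alpha_i \phi(x_i)$ implicitly. The decision score of a query
$x$ is $f(x) = \sum_i \alpha_i k(x_i, x) - \rho$; non-negative scores are
inliers (the tie at exactly zero is an inlier by convention). ν has its
usual double role: an upper bound on the fraction of training points
scored negative and a lower bound on the support-vector fraction — both
are asserted property-style in the test suite.

### SVDD and when the two coincide

`svdd()` fits the support vector data description: the minimum-radius
hypersphere around the data in feature space, via the dual

$$\max_\alpha \textstyle\sum_i \alpha_i k(x_i,x_i)
  - \sum_{i,j}\alpha_i\alpha_j k(x_i,x_j), \quad
0 \le \alpha_i \le C,\; \textstyle\sum_i \alpha_i = 1 .$$

For kernels with constant self-similarity — the RBF kernel anywhere, or
any kernel on unit-normalized data — the sphere and the hyperplane
describe the same set, and with $C = 1/(\nu l)$ the two fitted models
label points identically; the suite checks ≥ 99% grid agreement across
seeds.

### Solver

Both duals are instances of one box-and-simplex quadratic program, solved
by sequential minimal optimization: the first coordinate of the working
pair is the steepest feasible descent coordinate, the second is chosen by
the second-order (maximum-gain) rule, and each update is the exact
one-dimensional minimizer clipped to the box. Convergence is declared on
a certified duality gap of $10^{-8}$, computed by bounding the linearized
objective over the feasible set (a greedy pour of unit mass into the
smallest-gradient coordinates). The second-order pair choice matters on
near-degenerate geometries (e.g. unit-norm RBF data) where first-order
selection zigzags.

Correctness is established against `qp_oracle()`, an independent
brute-force reference that enumerates all $3^l$ active-set assignments
(each coordinate at its lower bound, upper bound, or free), solves each
free block through its KKT linear system, and returns the best feasible
candidate. It refuses $l > 12$; the acceptance suite drives 50 random
problems through both routes and requires dual objectives to agree within
$10^{-6}$. A third, fully external route — the libsvm one-class mode in
`e1071`, whose dual is this one scaled by $\nu l$ — is used as a
label-agreement cross-check only.

Numerical conventions:

* support vectors are points with $\alpha_i > 10^{-7}\max_j \alpha_j$;
  margin SVs additionally sit below the box bound by the analogous
  relative tolerance;
* $\rho$ is the mean of $\sum_j \alpha_j k(x_j, x_i)$ over margin SVs.
  When no margin SV exists the KKT conditions only bracket $\rho$
  between the largest raw score among at-bound points and the smallest
  among zero-$\alpha$ points; the midpoint is taken (deterministic), or
  the finite end when one side is empty;
* slacks are reported as $\xi_i = \max(0, \rho - f_{raw}(x_i))$;
* RBF `gamma` defaults to $1/d$; `nu` defaults to 0.05. The AML study
  conditions this package emulates do not pin either value, so both are
  ordinary configuration, and the defaults are the field's customary
  ones.

## Benchmark construction

`differential_expression()` computes, per gene, the log2 fold change
(disease mean minus healthy mean, values assumed log2; a flag
log-transforms raw intensities first), a Welch two-sample t-test p-value,
and Benjamini–Hochberg adjusted p-values across genes. Welch + BH is a
deliberate, assumption-light choice: the originating analysis tooling for
the AML benchmark is not recorded, so exact reproduction of its 1174/1300
gene counts from raw GEO data is not promised — the packaged experiment
instead consumes the published benchmark files directly, where those
counts are inputs.

`select_positive_unlabeled()` labels a gene positive iff
$|\log_2 FC| > 1$ (strictly) **and** adjusted $p < 0.05$ (strictly);
boundary values stay unlabeled. All non-positives are unlabeled by
default; `max_unlabeled` optionally caps the unlabeled set to the genes
with smallest $|\log_2 FC|$, mirroring benchmarks built from the least
differential genes.

Before training, `remove_outliers()` drops training genes farther than 4
robust z-units (median/MAD per feature) from the cohort on any feature —
a guard against anchoring the scaling range on aberrant profiles; MAD-0
features are skipped. `minmax_scale()` then maps each feature to
$[0,1]$ using *training-set* minima and maxima only, applying the same
parameters (with clipping) to evaluation data, so no information leaks
from the test pool into the representation. A `scale_all` switch
reproduces the global-scaling variant in which parameters come from the
full benchmark; it changes little in practice but is provided for
compatibility with analyses that scaled everything at once.

`split_train_test()` puts a random 70% of positives into training;
held-out positives plus *all* unlabeled genes form the evaluation pool —
unlabeled genes never reach training. `cross_validate()` provides 10-fold
CV recall within training positives (recall is the only classical metric
computable there).

## Positive-unlabeled evaluation

With no labelled negatives, only two quantities are directly estimable on
the evaluation pool: recall
$\hat r = $ (held-out positives predicted inlier)/(held-out positives),
and the positive-prediction rate
$\widehat{P}[f(x){=}1] = $ (pool predicted inlier)/(pool size).
Precision $P[Y{=}1 \mid f(x){=}1]$ follows by Bayes inversion:

$$\hat p = \mathrm{clip}\!\left(
  \frac{\hat r \cdot P[Y{=}1]}{\widehat{P}[f(x){=}1]},\; 0, 1\right),$$

with the class prior $P[Y{=}1]$ taken as the known-positive fraction of
the pool. This is the only estimator constructible from the three
quantities involved, and it has a structural consequence worth knowing
when reading comparison tables: whenever the predicted-positive rate
equals the prior, $\hat p = \hat r$ exactly — precision/recall/F triplets
with identical values are a signature of this estimator, not a
coincidence. Estimates above 1 (sampling noise) are clipped and reported.
`pu_criterion()` additionally exposes $\hat r^2 / \widehat{P}[f(x){=}1]$,
proportional to $p \cdot r$, for prior-free model ranking.

Whether published one-class results were computed this way or by treating
unlabeled test genes as negatives is generally unknowable, so both modes
are emitted: PU mode (the default) and a "naive" mode
(unlabeled-as-negative classical counts).

On synthetic data the estimators are validated against hidden ground
truth: with ~4700-gene validation pools containing hidden positives, the
mean absolute gap between Bayes-inverted and truth-based precision is
well under 0.02 (the acceptance suite recomputes this over 20 seeds, and
`scripts/acceptance.R` reports it).

## Binary baselines and the comparison harness

`run_baseline()` wraps the three conventional binary routes — RBF-kernel
SVM (`e1071`), k-nearest neighbours (`class`, k = 5), and a decision tree
(`rpart`) — trained on balanced sets: all training positives plus an
equal-size pseudo-negative sample drawn uniformly from the unlabeled
genes (`make_balanced_binary()`, never touching a known positive).
`run_comparison_experiment()` scores every method, one-class included, on
the identical test pool through the identical metric functions;
`compare_methods()` renders the method × (precision, recall, F) table
with two-decimal percentages. Baseline hyperparameters are ordinary
defaults exposed in configuration — the harness reproduces a comparison
*protocol*, not any specific published row, and the table renderer
accepts externally supplied rows so published numbers can be juxtaposed.

## The synthetic generator

`generate_expression()` emulates the structure of a preprocessed
two-condition microarray study: gene $g$ draws a baseline mean
$\mu_g \sim U(4, 12)$ (log2-intensity range typical of such arrays);
entries are $\mu_g + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with
$\sigma = 1$ by default; a `disease_gene_fraction` of genes (default
0.15) adds a shift of magnitude `effect_size_delta` (default 3, i.e.
3σ — comfortably above the $|\log_2 FC| > 1$ labeling threshold at the
default 26 + 38 samples) to their disease-sample means, with random sign
per gene so both over- and under-expression occur. Sample counts default
to the AML benchmark's 26 disease / 38 healthy.
`contamination_fraction` (default 0) withholds that fraction of planted
disease genes from the positive label so they hide in the unlabeled set —
the situation PU evaluation exists for; it is switched on explicitly in
the estimator-recovery and contamination experiments.

What the generator does **not** emulate: probe-level artifacts, batch
effects, heavy-tailed intensity distributions, and gene–gene correlation.
Passing tests on this generator therefore demonstrate the correctness of
the machinery (labeling, solver, estimators, bookkeeping) under the
stated model, not classifier performance on real arrays.

One empirical property of the default geometry deserves emphasis. Planted
effects are two-sided, so the positive class is bimodal in every
disease-sample feature, and a *linear* one-class hyperplane cannot carve
out both modes while rejecting the nulls that sit between them — on
synthetic benchmarks the linear model accepts most of the pool and its PU
precision is accordingly low (the acceptance script prints these numbers
each run). This is a property of the simulated geometry, not a solver
defect (the dual is verified exact against enumeration), and it is why
real benchmarks — where positives are jointly extreme in a way nulls are
not — can behave very differently. Conversely it makes the synthetic
benchmark a sharp test of the *estimators*, which must stay calibrated
regardless of how good the classifier is.

For the contamination experiment the harness uses a variant regime
(effect 2.5σ, baseline means in $[7, 9]$) in which kernel distances are
signal-dominated and the binary SVM is genuinely competent; contaminating
its pseudo-negatives with hidden positives then visibly degrades its
measured precision (hidden positives it correctly flags count as false
positives under the unlabeled-as-negative convention). With truth-based
precision the direction is *not* stable — contaminated training shrinks
the predicted-positive set, which can raise true precision while recall
falls — so the measured-precision convention, which is also how binary
baselines are scored in practice, is the one asserted.

## Problem sizes and reproducibility

The test suite runs its simulations at sizes chosen to make the
statistical assertions sharp but cheap: solver exactness at $l \le 8$
against a $3^l$ enumeration, the ν-property at $l = 200$ over 20 seeds ×
4 values of ν, estimator recovery on 6000-gene simulations over 20 seeds,
and the labeling pipeline at 2000 genes × 60 samples. Every randomized
stage (generation, splits, balanced sampling, CV folds) takes an explicit
seed, and the command-line layer fans a single global seed out to
stage-specific derived seeds, recording everything in a per-stage JSON
manifest so any stage can be rerun in isolation, bit-for-bit.

## Known limitations

* Linear and RBF kernels only; no polynomial/sigmoid, no online updates.
* The DE step is Welch + BH on a preprocessed matrix; no probe collapsing
  or array normalization (inputs are assumed preprocessed, as in
  published benchmark files).
* PU precision inherits any error in the class prior; with the
  known-positive fraction as prior it is a lower-bound-flavoured
  estimate when the unlabeled pool hides true positives.
* The SMO solver is dense ($O(l^2)$ memory in the Gram matrix) and sized
  for benchmark-scale problems (thousands of genes), not for $l \gg 10^4$.
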