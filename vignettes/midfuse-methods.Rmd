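---
title: "Mid-level fusion of omics feature tables: models and design choices"
author: "midfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mid-level fusion of omics feature tables: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midfuse)
```

## The problem

Two instrument platforms — say LC-MS peptide abundances and binned NMR
intensities — profile the same biological samples, grouped into `g`
classes (here typically healthy control, treatment control, disease).
Each platform measures far more variables than there are samples, each
carries its own nuisance variance (batch runs, instrumental drift), and
in practice a few samples are lost per platform, so the two tables cover
overlapping but unequal sample sets. The goal is a single classification
model that uses the discriminant information of *both* platforms,
together with an interpretation layer that points back to the individual
peptides, bins and proteins that drive it.

Concatenating the raw tables ("low-level fusion") fails in exactly the
way unsupervised analysis of a single wide table fails: the dominant
variance directions are biological and instrumental background, not
class structure. `midfuse` therefore implements a *mid-level* strategy
with two layers:

1. **Per platform**: extended Canonical Variates Analysis (eCVA)
   compresses each block into `g - 1` class-discriminant score columns.
2. **Across platforms**: the score columns are concatenated — with
   missing entries where a sample was not measured by a block — and
   analysed by a PCA that tolerates missing values, giving global scores
   `T` and super-loadings `P`. Classification, variable importance and
   correlation networks all live in this global space.

## First layer: eCVA

Classical canonical variates analysis seeks directions `w` maximizing
the between-group over within-group variance ratio, equivalently the
eigenproblem of `S_w^{-1} S_b`, where `S_w` is the pooled within-group
covariance (divisor `n - g`) and `S_b` the covariance of group means
about the grand mean (divisor `g - 1`; the directions are invariant to
either divisor convention, which a test asserts). With `p >> n` samples,
`S_w` is singular and the inversion impossible. The eCVA reformulation
replaces it by the regression problem

    S_w B = Y + F

with `Y` holding group-mean differences, solved by an uncentered PLS2
fit of `n_pls` latent variables: the PLS acts as a regularized
pseudo-inversion that works precisely because omics data are strongly
collinear. Concretely, each PLS weight vector is the dominant left
singular vector of the (implicitly deflated) cross-product `S_w' Y` —
the fixed point of the NIPALS inner loop computed directly, so results
are deterministic and fast even at `p = 2000` (the `p x p` predictor is
never copied; deflation is tracked through rank-one updates). With
`n_pls` equal to the rank of `S_w` the solution coincides with the
least-squares one, and on full-rank data the extracted subspace matches
the dense `S_w^{-1} S_b` eigenproblem to numerical precision — both are
asserted in the test suite.

Design choices the method description leaves open, as resolved here:

* **`Y` construction.** All `g(g-1)/2` pairwise group-mean differences
  are used as regression targets, then the coefficient matrix `B` is
  reduced to `g - 1` orthonormal directions by SVD. This is symmetric in
  the group order and reduces to the canonical single-difference
  formulation at `g = 2`.
* **Sign convention.** Each direction is flipped so its
  largest-magnitude coordinate is positive, making output reproducible
  across linear-algebra backends.
* **Inner dimension `n_pls`.** `select_pls_components()` implements the
  method's own stratified venetian-blinds cross-validation (7 splits by
  default; held-out samples classified by nearest class centroid with
  within-class-standardized score columns; ties resolved toward the
  smallest count). At `n ~ 45` the CV error curves are flat-minimal and
  noisy, so the pipeline default is a fixed `n_pls = 8` — in the range
  such analyses typically arrive at — with the CV grid available via
  `fusion_config(n_pls_grid = ...)`.
* **Variable screening.** For a block whose width dwarfs the other
  platform's, `select_top_k_and_refit()` ranks variables by the
  Euclidean norm of their rows of `W`, keeps the top `k` (e.g. 153, to
  match a 153-bin spectral block) and refits both the scaling and the
  model on the reduced table. The refit re-estimates scaling statistics
  on the retained columns.

### Scaling

`fit_scaling()` supports mean-centering, autoscaling, Pareto and vast
scaling (autoscaling weighted by the mean-to-SD ratio, down-weighting
unstable variables), all with the unbiased `n - 1` SD and strict reuse
of training statistics on test samples. Zero-variance columns are
dropped with a warning. Vast scaling is the package default, following
the practice for instrument data whose low-abundance variables are
noise-dominated. On the synthetic studies generated by this package all
variables are equally stable by construction, so the analyses in the
acceptance suite use plain autoscaling: there the extra mean-to-SD
weight would only re-penalize variables whose *total* variance is
inflated by the class effect itself, which degrades the ranking of
truly discriminant variables without any compensating benefit.

## Second layer: PCA with missing values

Concatenating per-block scores gives an `n x sum_b(g-1)` matrix with a
missing block of `g - 1` cells wherever a sample was absent from a
platform. `fit_pca_missing()` performs model-based imputation: missing
cells start at observed column means, then the loop \{re-center,
rank-`r` SVD, replace missing cells by the reconstruction\} runs until
the relative Frobenius change of the imputed cells falls below a
tolerance. Observed cells are never altered, and the observed-cell
reconstruction error is provably nonincreasing (it is an alternating
minimization), which a test checks on every fit.

Two numerical points deserve emphasis:

* The stand-alone default tolerance (`1e-9`) is intentionally strict.
  EM-style PCA imputation contracts only linearly on noisy data, and a
  sample observed in a single block has exactly `r = g - 1` observed
  coordinates — its global position is partly underdetermined, the
  slowest-contracting regime. The fusion layer therefore calls the
  routine with `global_tol = 1e-7` and `global_max_iter = 5000`
  (configurable), at which the retained model is stable far below the
  classification scale. Non-convergence is never silent: the model is
  returned with `converged = FALSE` and a warning.
* **Score-column standardization.** Unit-norm direction vectors (the
  eCVA contract) leave score columns on arbitrary, block-dependent
  scales; a raw PCA of the concatenation would follow whichever
  platform's scores happen to be numerically largest rather than the
  class structure. The fusion layer therefore standardizes every
  concatenated score column to unit pooled within-class SD (training
  samples only) before the global PCA — the classical canonical-variate
  score convention, restored at the layer where the columns are
  compared. This is distinct from the optional scaling of whole feature
  blocks against each other, which remains off by default.

Classification is nearest-centroid in the retained global PC space
(`r_global = g - 1` by default), with Mahalanobis distance under the
pooled within-class score covariance — the closest deterministic
reading of "principal component discriminant analysis" — or plain
Euclidean distance as a sensitivity check. Ties go to the lowest class
index. Test samples are pushed through the stored per-block scaling and
eCVA projections; when a block is absent the global score is the
least-squares solution over the observed coordinates.

## Validation

`kennard_stone_split()` selects `round(0.2 n)` test samples by the
classic max-min rule — seed with the two mutually farthest points, then
repeatedly add the point maximizing the minimal distance to the chosen
set — run per class (stratification guarantees every class appears in
the test set) on the concatenation of autoscaled blocks restricted to
samples present everywhere; samples missing from any block always
train. Ties break toward the lowest row index, so the split is
deterministic. The selected points are *representative* of the data
cloud, and they are also its extremes: accuracies measured on them are
conservative. No training statistic — scaling means, eCVA directions,
PCA loadings, centroids — touches test samples, which an acceptance
test verifies by perturbing test-sample values and asserting the fitted
model is bit-identical. After validation the model is refit on all
samples for interpretation.

## Interpretation

* `global_weights()` back-projects the global loadings to original
  variables: `W_block %*% P_block`, the product of the block's
  canonical directions with the loading rows of its score columns.
* `group_importance()` projects each variable's global-weight row onto
  the unit vector from the grand mean to a class centroid, then
  normalizes jointly over all blocks so the largest absolute importance
  is exactly 1. Positive means up-regulated in the target group; the
  planted-effect simulations confirm the sign semantics.
* `aggregate_peptides()` rolls peptides up to proteins: a protein is
  reported only when at least 3 peptides (configurable) agree on the
  sign of their importance; the protein value is the mean over the
  majority-sign peptides, dissenters excluded, and a sign tie omits the
  protein entirely (no majority behaviour).
* `class_correlations()` + `build_network()` compute all pairwise
  Pearson correlations per class over the selected variables
  (pairwise-complete samples; at least 3 shared samples or the pair is
  recorded as not computable; within-class-constant variables yield a
  flagged 0 so node sets stay stable across classes) and keep edges
  with `|r|` strictly above 0.8. `extract_subnetwork()` expands seed
  variables breadth-first (default two layers), and `export_dot()`
  writes deterministic Graphviz text: boxes for important variables,
  ellipses otherwise, solid edges for the reference class and
  dotted/dashed for the rest.

## The synthetic study generator

No real data ship with the package, so `simulate_study()` is
first-class: it generates the study the method is designed for, with
ground truth for recovery tests.

Defaults (all configurable): `g = 3` balanced classes of 15 samples; a
wide peptide block (2000 variables) with a two-batch mean offset on 20%
of its variables for half the samples; a narrow 153-bin spectral block;
3 and 5 samples dropped per block respectively; 3 shared latent factors
as correlated background; planted class contrasts of 1.2 within-class
SD — a disease-vs-controls axis and a control-split axis, weighted
toward the disease axis in the wide block (30 + 10 planted peptides,
chosen as whole 4-peptide protein groups with one sign per protein, the
way differential proteins actually appear) and toward the control split
in the narrow block (10 + 5 bins).

Two structural choices matter more than any single number:

* **Co-regulation modules.** The variables of one planted contrast
  share a within-class latent factor along their effect signs
  (`module_scale = 1` SD). Analytes responding to a biological process
  covary within groups as well as shifting between them, and this
  within-group collinearity along the effect direction is also a
  mathematical requirement: the PLS solution of `S_w B = Y` lives in
  the range of `S_w`, so with mutually independent variables *no*
  within-covariance-based method can localize the effect. At the
  default share the within-class correlation between two same-module
  variables is about 0.5 — deliberately below the 0.8 network
  threshold, so the default correlation networks are driven by the
  latent background unless the threshold is lowered.
* **Intensity realism with uniform stability.** Every variable's
  stochastic within-class part is normalized to unit SD (so
  `noise_sd`, `latent_scale` and `module_scale` are variance shares and
  effect sizes are exactly in SD units), then each variable is placed
  on an intensity scale via a baseline drawn from 10-30 SD with
  precision proportional to intensity, as in spectral and abundance
  data. Mean-to-SD ratios are therefore comparable across variables —
  the regime in which vast scaling is well-behaved, though (see above)
  not advantageous.

What the generator does *not* emulate: heteroscedastic or non-Gaussian
noise, censoring at the detection limit, peak-alignment or binning
artifacts, nonlinear responses, and class imbalance. Passing tests on
these studies show the pipeline recovers what it is designed to
recover under its own assumptions; they do not certify performance on
data violating them.

## What the acceptance suite establishes

On 20-25 seeded replicates per property: equivalence of the PLS solve
with the dense eigenproblem on full-rank data; the two-class closed
form under exactly isotropic within-class covariance; correctness of
the missing-value PCA in its limiting, low-rank and monotonicity
regimes; exact agreement of Kennard-Stone selection with exhaustive
max-min scans; exact agreement of network edges with brute-force
correlation scans, with a strict threshold; recovery of >= 80% of
planted variables in the top twice-planted-count importance ranks with
>= 90% correct signs (default study); fused test accuracy at least the
best single platform in >= 80% of complementary-design studies (single
one-vs-rest contrast per block, effect 2 SD — the generous-margin
regime); a bit-identical no-leakage audit; the exhaustive peptide
roll-up cases; and byte-identical end-to-end reruns.

Problem sizes in the routine suite are the generator defaults
(45 x 2000 and 45 x 153) for the recovery and fusion-benefit
properties, and smaller matrices wherever the property is
size-independent; the whole suite runs in well under a minute on a
single core.

## Known limitations

* Both layers are linear; nonlinear class structure will be missed, and
  only the part of a batch effect orthogonal to the discriminant
  directions is ignored rather than corrected.
* At `n ~ 45` the eCVA directions generalize imperfectly however large
  the planted separation: test accuracy plateaus around 85-90% even
  when training separation is nearly complete. Validation-set figures,
  not training separation, are the meaningful performance measure.
* The importance back-projection inherits any overfit canonical
  direction; with one genuinely discriminant axis per block, the second
  canonical variate is mostly noise and dilutes the ranking. The
  variable screen plus refit mitigates but does not remove this.
* The outlier screen is classical-PCA-based, exploratory only, and is
  never applied automatically inside the fusion pipeline.
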