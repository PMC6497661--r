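---
title: "Methods: adaptive-zone shift detection for 3D landmark shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-zone shift detection for 3D landmark shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`morphoshift` implements a complete comparative pipeline for 3D geometric
morphometric data on a time-calibrated phylogeny: landmark completion and
superimposition, morphospace construction, disparity-through-time,
morphology-phylogeny tanglegrams, adaptive-zone shift detection under
multi-peak Ornstein-Uhlenbeck (OU) models, and fully multivariate
evolutionary model comparison. This vignette documents the models, the
parameters that matter, the numerical choices, and the known limitations.

## Landmark processing

**Input.** Specimen-level configurations of fixed landmarks and
semilandmarks (points constrained to curves), in device coordinates with
arbitrary position, orientation and scale. The long CSV dialect is
`specimen,species,landmark,x,y,z` with empty coordinate fields for missing
landmarks; curve membership, bilateral pairs and midline landmarks come
from a JSON side file (0-based ids).

**Missing landmarks** (damaged zygomatic arches and auditory bullae are the
typical cause in skull data; observed rates are a few percent) are
completed in two stages. If a missing landmark has a present bilateral
partner, the specimen is mirrored across its midsagittal plane (total least
squares through the present midline landmarks), the mirrored copy is
rigidly superimposed on the original over all shared present landmarks, and
the partner's mirrored position is copied in. This is exact for a perfectly
symmetric specimen; its error on real data is the magnitude of fluctuating
asymmetry, typically far below inter-specimen variation. Remaining cells
fall to an iterative low-rank PCA imputation run in a common orientation
(each specimen similarity-aligned to the consensus of the complete
specimens via its present landmarks; imputed values are mapped back to
device space). The component count is re-selected each iteration as the
number of eigenvalues above the mean eigenvalue — an automatic-relevance
heuristic; a fixed rank can be supplied. Convergence is declared when
imputed values move less than `1e-8`. `validate_missing_inclusion()`
replays this machinery on artificially degraded complete specimens and
compares consensus-shape displacement when degraded specimens are
imputed-and-included versus excluded.

**Superimposition.** Generalized Procrustes analysis: center, scale to unit
centroid size, rotate to the running consensus (rotations only —
determinant +1 — because anatomical landmarks are chirally labeled), update
the consensus, and stop when it moves less than `tol = 1e-8` in Procrustes
distance (`max_iter = 100`). With `slide = TRUE`, semilandmarks slide along
their curve's local tangent (central differences over neighbors) by the
tangential component of their offset from the consensus — the
Procrustes-distance sliding criterion, not bending energy. Sliding has a
near-null direction along each curve (a whole curve can creep indefinitely
while the objective decreases only marginally), so sliding is applied in
the first `slide_iters = 5` iterations only, after which plain GPA runs to
convergence; the total Procrustes sum of squares is monotone
non-increasing throughout. The final orientation is canonicalized to the
consensus principal axes, which makes the alignment invariant to specimen
order. Species consensus shapes are arithmetic means of aligned specimens,
then symmetrized by averaging with the mirrored, pair-relabeled copy.

**Procrustes distance** is the square root of the minimized sum of squared
differences after centering, unit-size scaling and optimal rotation. It is
the disparity metric throughout; the classical mean squared Euclidean
variant is available (`metric = "avg.sq"`).

## Morphospaces

`ppca()` performs PCA of the evolutionary covariance matrix: with `C` the
Brownian-motion tip covariance implied by the tree, the ancestral mean is
the GLS estimate `a = (1'C^-1 1)^-1 1'C^-1 X`, and
`R = (X-1a')' C^-1 (X-1a') / (n-1)` is eigendecomposed (divisor `n-1`,
matching the standard phylogenetic PCA formulation). Scores are
`(X-1a')V`. On a star phylogeny this reduces exactly to ordinary PCA.
Column signs follow a fixed convention (largest-magnitude loading entry
positive) so runs are comparable.

Axis retention uses parallel analysis (Horn's rule): the observed
eigenvalues are compared rank-by-rank against the 0.95 quantile of
eigenvalues of column-permuted data, stopping at the first failure. The
0.95 quantile is our choice of null exceedance level. Under phylogenetic
correction the permutation operates on the
GLS-whitened data (`C^-1/2 (X-1a')`), so the null respects the tree; raw
permutation is available (`permute = "raw"`); both conventions are in
circulation. Because the eigenvalues of a pPCA do not sum to the
data variance, the absolute shape variation per axis is measured by a
Procrustes multiple regression of all coordinates on the retained scores;
the per-axis sequential (type-I) R-squared equals eigenvalue/trace exactly
in the standard-PCA case. Scores are multiplied by 100 before evolutionary
model fitting to keep estimated rates away from numerical underflow; model
rankings are invariant to this factor.

## Disparity through time and the tanglegram

The DTT curve evaluates, at each internal-node age (relative time in
[0,1]), the mean relative disparity of the lineages crossing that age
(singleton lineages contribute 0); it equals 1 at the root. The
morphological disparity index (MDI) is the trapezoid-rule area between a
curve and the median of curves simulated under multivariate BM with the
GLS-estimated rate matrix of the full coordinate set (simulations are run
in the full 3k-dimensional shape space, then reduced with the same
Procrustes-distance disparity). Negative MDI means disparity was
partitioned among, rather than within, early lineages. The one-sided
p-value is the fraction of simulated MDIs at or below the observed one
(ties counted as lower — the conservative convention). MDI integrates the
full [0,1] range by default; `truncate` can exclude the most recent nodes.
The default simulation count is 1000.

The tanglegram contrasts the phylogeny with a UPGMA dendrogram
(average-linkage `hclust`) of pairwise Procrustes distances. Both
structures are co-rotated to minimize the sum of squared differences in
matched tip positions: exhaustive enumeration when the two structures have
at most 14 internal nodes in total, otherwise alternating
lowest-index-first hill-climbing over node flips (each flip swaps two
contiguous tip blocks; the objective never increases). Tip displacement is
the mean absolute rank difference of species between the two tip orders —
the reading under which "same position in both trees" gives exactly zero —
and the crossing count is also reported. The null distribution replays the
identical pipeline on BM-simulated landmark datasets (1000 by default);
the p-value is the fraction of null statistics strictly below the observed
one, so strong morphology-phylogeny concordance gives small p.

## Adaptive-zone shift detection

Each retained axis evolves as an independent OU process with per-trait
attraction `alpha_j` and diffusion `sigma2_j`; the traits share one set of
shift branches, on which the optimum changes by a per-trait amount. (No
cross-trait covariance here — that is the documented trade-off of the
lasso-based search; full trait covariance is handled in the model
comparison below.) The root state equals the root optimum, the standard
stationary-root treatment that removes one unidentifiable parameter on
ultrametric trees; a shift of size `b` on branch `s` then moves every tip
below `s` by `b (1 - exp(-alpha (T - t_start(s))))`.

The search has two phases. Phase 1 fixes a single search attraction (the
geometric mean of the per-trait no-shift ML estimates — the group penalty
of the lasso requires one shared design), whitens data and branch design by
the OU covariance, and runs a glmnet lasso path (family `mgaussian`, so all
traits enter or leave a branch together; 50 path points spanning four
decades) whose supports up to `max_shifts` become candidates. Phase 2
refits every candidate exactly — per trait, optima by GLS and `sigma2`
profiled out at each `alpha`, `alpha` maximized on `[1e-6, 50]/T` (beyond
the upper bound regimes are effectively instantaneous and the likelihood is
flat) — and scores it. Because a lasso path can carry redundant branches
that mask a sparser, better configuration, the leading small candidates are
also refined by backward elimination (dropping one branch at a time while
the score improves). Supports containing both children of a node are
pruned to one (a sister pair is unidentifiable against a root-state
change). The default caps are 50 shifts for a full tree and 20 for a
subclade analysis. The search is deterministic given the data: only the
bootstrap consumes randomness.

**Selection criterion.** The default is a phylogenetic BIC with three
parts: `-2 logL`; a placement charge per shift equal to the extreme-value
scale of the largest of m chi-square(p) statistics
(`2 log m + p + 2 sqrt(2 p log m)`, m = number of branches, p = number of
traits) — the price of choosing each shift as the best of all branches; and
per trait `2 log n` plus the log-determinant of the GLS information of the
0/1 shift-membership design under the correlation form of the OU
covariance. The membership design and correlation form make the criterion
invariant to trait rescaling, keep the zero-shift penalty strictly
positive, and prevent the information term from degenerating when a
candidate's attraction collapses to the lower bound. The reference
implementation of the criterion this emulates was not available for
constant-by-constant validation, so the exact constants are this package's
own, chosen to reproduce the published operating characteristics
(conservative relative to BIC; see the calibration tests: planted 4-sd
shifts on 64 tips recovered in >90% of replicates, no shift reported in
>80% of no-shift replicates). Plain BIC is available
(`criterion = "bic"`).

**Support.** Parametric bootstrap: simulate from the fitted shifted-OU
model, rerun the full search, and report per shift the fraction of
replicates whose configuration contains that branch; 0.7 is the
conventional well-supported cutoff. Default 100 replicates (the published
count is not stated; it is configurable).

## Multivariate model comparison

`fit_bm`, `fit_ou1`, `fit_eb` and `fit_oum` fit fully multivariate models
(all trait covariances retained) by maximum likelihood:

* **BM** — GLS root and full rate matrix, closed form; `k = p + p(p+1)/2`.
* **OU1** — symmetric attraction matrix A and rate matrix R (Cholesky
  parametrizations), fixed root at the single optimum;
  `k = p + p(p+1)`. The covariance uses the eigendecomposition of A with
  `(1-exp(-x))/x` evaluated via `expm1`, so BM is reached smoothly at the
  `A -> 0` boundary and the reported likelihood is never below the BM
  value.
* **EB** — BM after the branch-length transform
  `(exp(r t) - 1)/r` with decay `r` in `[-10/T, 0]` (rates can only slow);
  `k = p + p(p+1)/2 + 1`.
* **OUM** — multi-peak OU on a regime painting, from a detected shift
  configuration (each branch inherits its nearest ancestral shift) or from
  stochastic character maps. Two structures are offered, matching the two
  published parameter-count conventions: `"diagonal"` (independent traits,
  free per-trait root state; `k = regimes*p + 3p`, e.g. 45 for 12 regimes
  at p = 3) and `"symmetric"` (full A and R, root at the basal optimum;
  `k = regimes*p + p(p+1)`, e.g. 21 for 3 regimes at p = 3). The published
  16-regime, p = 4 count (80) does not decompose under either structure
  consistently with the p = 3 counts; we report our own counts rather than
  forcing agreement.

Models are ranked by small-sample corrected AIC with
`n = tips x traits` — the convention validated by reproducing published
log-likelihood/parameter-count/AICc triples for 202-species (p = 3) and
191-species (p = 4) skull-shape analyses to within 0.01. For models fit over a distribution of stochastic character
maps, log-likelihood and AICc are summarized as median (min, max) across
maps. Discrete characters (diet, echolocation emission type) are mapped
with `phytools::make.simmap` behind `simmap()`, model ER by default, root
prior set to the stationary distribution of the fitted rate matrix, 100
maps by convention.

Optimizers: Nelder-Mead with deterministic restarts (5 by default for OU1)
from near-BM and progressively stronger-attraction starts; the best
likelihood is kept.

## The synthetic-data generator

The generator defines the package's reference study conditions; every
downstream stage is validated against its ground truth.

* **Trees** are pure-birth (Yule), rescaled to unit depth (the relative
  time axis of DTT); published analyses use empirical trees, so tree-shape
  realism beyond ultrametricity is not attempted.
* **Traits** evolve by multivariate BM (exact branch-increment simulation)
  or by shifted OU (exact transition sampling), with planted shifts on
  known branches; shift sizes are expressed in stationary standard
  deviations `sqrt(sigma2/(2 alpha))`.
* **Landmarks**: species mean shapes evolve from a bilaterally symmetric
  template (a midline arc plus mirrored side points) by isotropic BM;
  bilateral variation is mirrored left-to-right with a small fluctuating-
  asymmetry residual (10% of the BM scale) — without this, reflected
  relabeling would face unrealistically asymmetric specimens. Specimens
  are randomly rotated (uniform on the rotation group), translated, and
  scaled (log-normal, sd 0.1) to exercise GPA. Missingness is injected
  uniformly over non-paired slots plus one random member of each bilateral
  pair — never both, mirroring the unilateral-damage pattern of real
  specimens and guaranteeing reflected relabeling stays applicable; the
  generator refuses rates of 20% or more (observed rates are at most
  5.5%).
* **Discrete characters** evolve under a continuous-time Markov (Mk)
  process with the root drawn from the stationary distribution.
* `simulate_dataset()` plants the same shifts in the low-dimensional trait
  matrix and, as clade-wise mean displacements along random directions, in
  shape space, so end-to-end runs from raw landmarks can be checked
  against ground truth.

What the generator does **not** emulate: allometry, modular trait
covariance, measurement error correlated with size, fossil tips, and
tree-shape imbalance. Passing tests therefore demonstrate correctness of
the machinery under the stated generating models, not robustness to every
feature of real morphometric data.

## Numerical choices and degenerate inputs

* OU covariance and design entries use `expm1`-based forms, so the
  `alpha -> 0` limit recovers BM to rounding error.
* Rate-matrix estimates are symmetrized and eigenvalue-clipped at zero
  before simulation square roots.
* UPGMA ties follow `hclust`'s deterministic lowest-index merge; untangle
  sweeps are lowest-index-first; the p-value tie convention counts ties as
  "lower" (conservative).
* Degenerate inputs fail loudly: all-coincident configurations, zero total
  disparity, non-ultrametric trees (relative tip-depth spread above 1e-6),
  asymmetric dissimilarity matrices, rank-deficient score matrices.
* Every stochastic routine takes an explicit seed and restores the global
  RNG state.

## Problem sizes used in validation

The distributional checks in the test suite run at these sizes, chosen as
the smallest where the published operating characteristics are
unambiguous: MDI calibration and power, 50 meta-replicates of 64 tips x 30
landmarks with 100-simulation nulls; tanglegram null calibration, 40
meta-replicates; shift recovery and false-positive control, 100 replicates
each at 64 tips with 2 traits; OU1 attraction recovery, 20 replicates at
64 tips; early-burst recovery, 50 replicates at 128 tips. The end-to-end
pipeline check uses 64 species, 16 landmarks and 2 planted shifts; with
parallel-analysis axis retention in the loop, shifts whose displacement
falls mostly outside the retained axes are not recoverable, which bounds
what end-to-end recovery can show.

## Known limitations

* Shift detection assumes ultrametric trees and independent traits given
  the shift set; convergent-regime (collapsed-optima) detection is out of
  scope.
* The pBIC constants emulate, but could not be validated against, the
  reference implementation; criterion choice is configurable.
* Semilandmark sliding is bounded rather than run to convergence (see
  above); patch (surface) semilandmarks and 2D data are unsupported.
* The imputation stage assumes missingness unrelated to shape beyond the
  bilateral-damage pattern.
* Stationary-root OU treatment ties the root state to the root optimum in
  shift detection; the diagonal OUM fit frees it (that is what the
  published parameter counts imply), which can be weakly identified at
  small attraction.
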