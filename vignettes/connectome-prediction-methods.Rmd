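---
title: "Predicting phenotypes from structural connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phenotypes from structural connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpm)
```

## The problem

Whether individual phenotype scores — big-five personality traits measured on
a 0–48 integer scale, or a continuous cognition composite — can be predicted
from a person's structural connectome (SC) is an open question, and the answer
turns out to depend heavily on analysis choices. `cbpm` implements, as a
tested and reusable pipeline, the full benchmarking procedure for this
question: SC construction from streamlines, four feature classes, ridge
regression under repeated nested cross-validation, permutation nulls, a sweep
layer over pipeline conditions, an audit of selection-induced optimism, and
voxelwise prediction brain maps. Because the imaging cohorts this kind of
study uses are access-restricted, the package ships a seeded synthetic-data
generator that emulates the relevant statistical properties of such data and
lets every stage be exercised end to end with *known* ground truth.

## Connectome construction

A parcellation assigns each gray-matter voxel a region label in $1..R$
(background is 0). Given a whole-brain set of streamlines, three weighted
$R \times R$ connectomes are built:

* **NOS** — entry $(i, j)$ counts the streamlines whose endpoints fall in
  regions $i$ and $j$. Counts are *not* normalized by region size: with a
  common parcellation across subjects, every instance of a feature is on the
  same scale, and raw counts preserve the heavy right tail that the later
  log-transform is designed for.
* **FA / MD** — each streamline first gets the mean of the scalar map
  (fractional anisotropy, dimensionless in $[0,1]$; mean diffusivity,
  mm$^2$/s) over the voxels it passes through; entry $(i, j)$ is then the mean
  of those per-streamline values over all streamlines connecting $i$ and $j$.

Three conventions were genuinely open and are fixed as follows. A voxel a
streamline revisits is counted **once** in the per-streamline mean (paths
rarely revisit voxels, but the rule must be deterministic). Streamlines with
an endpoint in background are **discarded** and counted in a
`n_background_dropped` attribute (anatomically constrained tracking makes this
case implicit in real data). Region pairs with no streamline get **0** rather
than a missing-value marker in the FA/MD matrices, matching the downstream
treatment of the SC as a dense feature matrix. Endpoint pairs are pooled
unordered before counting, so symmetry holds by construction rather than by
post-hoc symmetrization, and the diagonal (self-connections) is set to zero.

## Feature classes and normalization

Four feature classes are derived from a connectome:

* **whole-brain** — the vectorized upper triangle, $R(R-1)/2$ edges in fixed
  row-major $(i<j)$ order;
* **corr** — the $k$ edges most correlated with the target across *training*
  subjects;
* **pca** — scores on the $k$ leading principal components fitted on
  *training* subjects;
* **rcp** — one region's full row of the SC (its connectivity profile),
  including the zero self-connection entry (harmless under ridge, and it keeps
  the feature dimension exactly $R$).

NOS features are log10-transformed first (zeros — absent edges — stay zero;
note the collision with $\log_{10}1 = 0$), because raw streamline counts are
heavily right-skewed. Features are then scaled by a **global min–max
normalizer**
$$x_\text{norm} = \frac{x - \text{train}_{\min}}{\text{train}_{\max} - \text{train}_{\min}}$$
where $\text{train}_{\min}, \text{train}_{\max}$ are one *scalar* pair taken
over all entries of the training feature matrix — not per column. A
per-feature variant exists behind the `per_feature_minmax` flag, but the
global scalar pair is the canonical behaviour. Test values outside the
training range are deliberately not clipped: the transform is a pure affine
map, and clipping would discard information.

The order of operations matters and is enforced by `build_features()`: for the
PCA class, normalization (fitted on the training subjects over *all* edges) is
applied to the vectorized SC before the basis is fitted; for the other
classes, features are extracted or selected first and the normalizer is fitted
on the **selected training columns only**. Edge selection ranks by *absolute*
correlation (a strongly negative edge is exactly as informative for a linear
model as a strongly positive one; `rank_by = "signed"` is available), ties are
broken by ascending edge index, and constant training edges get correlation 0
rather than an error. Nothing is ever fitted on test subjects; the test suite
checks bit-identity of all fitted transformer state under mutation of
test-set data.

## Prediction engine

The model is ridge regression with an unpenalized intercept,
$$\hat\beta = \arg\min_\beta \sum_i \left(y_i - \beta^\top x_i - b\right)^2 + \alpha \sum_{k=1}^{K} \beta_k^2,$$
solved in closed form via the SVD of the centered design (one decomposition
serves the whole $\alpha$ grid). Features receive no standardization beyond
the min–max scaling above — that scaling is the pipeline's single, deliberate
normalization step. The penalty grid is
$\alpha \in \{0.001, 0.01, 1, 10, 50, 100, 500, 1000, 5000, 10^4\}$.

Accuracy is Pearson's correlation between predicted and observed scores on
held-out subjects. Under very strong shrinkage predictions can be (near)
constant, leaving the correlation undefined; such folds score 0 and carry a
degeneracy flag so fold averages stay defined.

Evaluation is a nested 5-fold cross-validation: the inner loop (5 folds of the
outer-training subjects; the inner fold count is a design choice) selects
$\alpha$ — and optionally the feature-selection case, see below — by mean
inner-fold Pearson r, chosen to match the outer metric (negative MSE would be
the natural alternative); the outer loop estimates out-of-sample accuracy; the
five outer-fold correlations are averaged into one result; and the whole
procedure is repeated over 100 random splits, yielding a distribution of
results per pipeline. Hyperparameter ties break toward the larger $\alpha$
(the conservative choice) and then the smaller feature parameter. Folds are
plain random partitions with sizes differing by at most one — no
stratification. Inner-loop feature refits happen per inner fold, so no
inner-validation subject influences selection, normalization, or the PCA
basis either.

Split schemes are reproducible objects: per-repeat child seeds come from a
documented splitmix-style arithmetic derivation of the master seed, so
extending the number of repeats never perturbs earlier ones, and one scheme
object shared across pipelines guarantees that all consume identical fold
memberships. Subject groups of different sizes (e.g. single-sex subsets) get
their own schemes from the same master seed. The permutation baseline reuses
the scheme and shuffles targets freshly per repeat (a per-repeat permutation
derived from its own seed) — the natural null for "is this distribution
centered where chance puts it".

## The sweep layer and selection optimism

A configuration space is the Cartesian product of parcellations, weightings
(NOS/MD/FA), subject groups, feature classes, and targets; the full design
with 19 parcellations enumerates to $19 \times 3 \times 3 \times 4 \times 5 =
3420$ pipelines. The corr and pca classes evaluate the fixed feature-count
grid $\{1,\dots,5,10,\dots,100,150,200\}$ with the region count appended — 19
cases, matching the rcp class's feature dimension; when the region count
collides with a fixed grid value the duplicate is evaluated once and marked.
The rcp class has one case per region.

Two protocols turn per-case results into one distribution per feature class:

* **post-hoc best-of** (`best_of_selection()`): take the case with the largest
  100-split mean. Because the choice uses the test results themselves, this is
  an optimistic upper bound, and every output flags it as such. Ties go to the
  smallest case index.
* **in-loop selection**: the feature case is one more hyperparameter of the
  inner CV loop, selected together with $\alpha$.

`optimism_audit()` runs both on identical data and splits and reports the gap
`mean(A) − mean(B)` with a percentile-bootstrap CI (2,000 resamples over the
paired per-split differences, seeded). On null data with 50 regional profiles
the gap is strongly positive — the max of 50 noise means — while the in-loop
protocol stays near zero; with signal concentrated in one profile both
protocols find the same region and the gap collapses (often to exactly zero,
since identical hyperparameter choices give identical folds). This contrast
is the package's central reproducible phenomenon.

Summaries are Cohen's d between condition distributions (pooled-SD form) and
the fraction of results strictly above a threshold, default 0.2 — the
conventional bar for a "promising" brain–behaviour prediction, kept as a named
config constant.

## Prediction brain maps

For the rcp class every region has its own accuracy distribution, so accuracy
can be painted onto the brain: every voxel of region $i$ gets region $i$'s
mean accuracy; background stays unassigned. Maps from parcellations sharing a
grid are averaged voxelwise; a voxel covered by only some parcellations is
averaged over the maps that assign it (excluding it would discard
parcellation-specific coverage). Averaging is unweighted across parcellations
(granularity weighting would be an arbitrary extra choice). Maps are compared
by Pearson correlation over assigned voxels, optionally after setting negative
values in *both* maps to zero — negative accuracies mark failed prediction,
and their relative magnitude carries no meaning. The full design yields
$5 \times 3 \times 3 = 45$ averaged maps (traits × weightings × groups).
Volumetric grids and per-region tables are the output format; cortical-surface
rendering is out of scope.

## The synthetic-data generator

The generator's defaults are study conditions, not tuning knobs:

* **Parcellations** grow $R$ connected regions by nearest-seed (Voronoi)
  assignment inside an ellipsoidal foreground mask (convex, so regions are
  connected by construction).
* **Scalar maps**: FA per voxel from a Beta(2,2); MD as a decreasing affine
  function of FA plus Gaussian noise on the $10^{-3}$ mm$^2$/s scale, giving
  the strongly negative voxelwise FA–MD correlation seen in tissue.
* **Streamlines** are straight-line rasterizations between random labeled
  voxels — curvature is irrelevant to the weighting arithmetic the builder
  implements, which is all these fixtures need to exercise.
* **Connectome populations**: log-normal rounded NOS (log10 mean 1.5, sd 0.5
  across edges, subject noise 0.3 — heavily right-skewed nonnegative
  integers); FA and MD edges share a latent edgewise factor with coupling
  0.95, so per-subject FA–MD edge vectors correlate near 1, as microstructural
  weightings do in practice; both carry stable per-edge population means so
  the population has across-subject structure for the PCA class to find.
* **Cohorts**: per trait, 12 Likert items (0–4) driven by a latent normal
  score; totals are item sums after reversal of the inversely keyed items
  (the instrument itself does not pin down which items those are for a
  synthetic inventory; the mask \{2, 5, 8, 11\} is arbitrary and frozen),
  hence integers in $[0, 48]$. Cognition is continuous on the $100 \pm 15$
  composite scale. Default group sizes mirror the study design (426 mixed,
  213 per sex) but are fully configurable for desk-scale runs.
* **Planted signal**: the target is replaced by a standardized linear
  combination of chosen edges scaled so the population variance explained
  equals `effect_r2`, plus independent noise. For NOS the combination is
  formed on log10 edges — the scale on which the model consumes them, so
  `effect_r2` is interpretable as the linear signal available to the
  pipeline. Trait targets are then mapped affinely to 0–48 and rounded
  (preserving the instrument's granularity; disable with
  `discretize = FALSE`); cognition stays continuous.

What the generator does *not* emulate: spatial autocorrelation of real scalar
maps, realistic fiber geometry, family structure, scanner confounds, or
non-linear brain–behaviour relationships. Green tests therefore demonstrate
that the pipeline's *machinery* is correct and calibrated — not that any
particular real dataset carries signal.

## Numerical choices and degenerate inputs

At $\alpha = 0$ with a rank-deficient design the ridge system is singular;
`fit_ridge()` errors unless `singular_ok = TRUE` selects the minimum-norm
solution (the penalty grid never contains 0, so this only arises in direct
use). Constant prediction or target vectors give a flagged 0 correlation.
Degenerate normalization (all training values equal) is an error rather than
a silent division by zero. All generators draw through an isolated RNG scope,
so they are pure functions of their arguments and never disturb the caller's
RNG state.

## Problem sizes used in the shipped checks

The test and acceptance runs use desk-scale versions of the study conditions,
chosen so each check is statistically decisive: null/permutation calibration
at $n = 200$, $R = 20$, whole-brain NOS over 100 split-runs; signal recovery
at $n = 300$, $R = 10$ over 25 splits per effect size (the family of targets
across effect sizes shares one noise draw, so the monotonicity check is
tightly coupled); the optimism audit at $n = 200$, $R = 50$ over 25 splits.

One calibration subtlety is worth spelling out. For a *single* fixed null
target, the mean of the CV distribution does not converge to zero as splits
accumulate: it retains a dataset-level term (a quadratic form coupling the
target draw with the subject-by-subject feature similarity) whose standard
deviation is about 0.08–0.10 at $n = 200$, $K = 190$ — we verified the same
magnitude with a plain independent ridge-CV implementation on iid Gaussian
data, so it is a property of CV-Pearson at these dimensions, not of this
package. The calibration check therefore estimates the pipeline's *bias* by
pooling runs over 20 independent null target draws (same connectomes, same
splits), which shrinks the Monte-Carlo error to ~0.02 and makes the ±0.05
bound a powered test. The permutation baseline redraws the target every
repeat and needs no such pooling.

## Known limitations

Ridge is the only learner, by design. There is no SC thresholding, no
confound regression beyond the sex-split design, no surface projection, and
no distributed execution. The optimism audit quantifies one specific form of
leakage (post-hoc case selection); it does not certify a pipeline free of
every other analytic flexibility.
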