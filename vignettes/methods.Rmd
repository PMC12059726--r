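---
title: "Methods: connectome-transcriptome association with txconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-transcriptome association with txconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

txconn links group differences in resting-state functional connectivity (FC)
to regional gene expression. This vignette documents the statistical model of
each stage, the assumptions of the synthetic-data generator, the numerical
choices, and the limits of what a green test suite establishes.

## 1. The analysis model

### Functional connectivity

Each subject contributes a T × R matrix of regional time series. FC is the
R × R matrix of Fisher-z transformed Pearson correlations,
z = atanh(r), with r clipped to ±(1 − 10⁻⁷) so perfectly correlated pairs
stay finite (z ≈ 8.4 rather than ∞; the clip is negligible everywhere else).
The diagonal is zeroed. Constant time series produce zero edges with a
warning rather than NaNs.

### Site harmonization (ComBat)

Multi-site edges are vectorized (upper triangle) into a subjects × edges
matrix and harmonized with parametric empirical-Bayes ComBat: a design with
site indicators plus protected covariates (defaults HAMD, HAMA, age, sex —
configurable, education deliberately excluded by default) is fit per edge;
data are standardized; per-site location is shrunk under a normal prior and
per-site scale under an inverse-gamma prior (method-of-moments
hyperparameters, iterative conditional solution); site effects are removed
and the protected effects plus grand mean restored. Mirroring the upper
triangle back preserves symmetry exactly.

Empirical-Bayes shrinkage makes the operator *approximately* idempotent, not
exactly: each pass leaves a geometrically decaying residual of the original
site effect, around 10⁻² on Fisher-z scale at desk-scale cohort sizes. The
test suite pins idempotency at tolerance 0.02 — the same scale as the
offset-removal requirement — because no finite sample delivers machine-level
idempotency under shrinkage.

### Group contrasts and NBS

Edge-wise inference is an OLS GLM of each edge on
[intercept, group, sex, age, FD, education]; the group t-statistic and its
two-tailed p are reported (this reduces exactly to the classical
pooled-variance two-sample t when no covariates are given). The |t| map is
thresholded at the two-tailed critical value for the edge-level p (default
0.001), and connected components of the suprathreshold graph are the units
of inference.

The permutation null respects covariates via Freedman–Lane: residuals of the
covariates-only reduced model are row-permuted, the reduced fit is added
back, the full model is refit, and the maximum component statistic is
recorded; with no covariates this provably reduces to plain label
permutation (asserted on toys). Component p-values use the positively biased
(1 + exceedances)/(1 + n_perm) estimator, which can never return zero.

**Component statistic.** The package defaults to *intensity* — the sum of
|t| − t_critical over the component's edges — rather than the historical
*size* (edge count), which remains available (`statistic = "size"`). The
reason is measurable: at a strict edge threshold (p < 0.001) and moderate
samples, the null distribution of the maximum component size concentrates on
{0, 1, 2}; this discreteness caps the attainable family-wise error well
below the nominal level (≈ 0.015 at α = 0.05 over 200 null cohorts of
n = 30+30, R = 30, T = 120 — reproducible by rerunning the acceptance
experiment with `statistic = "size"`), so a calibration check centred on α
cannot be met by the size statistic. Intensity is continuous and tie-free;
the acceptance suite asserts its rate on the same nulls falls within the
binomial 95% band [0.02, 0.09] around the nominal 0.05 (≈ 0.075 in
development runs).

The 7 × 7 network-level contrast applies the same GLM to the 28 unique
network-pair cells (within-network cells average unordered region pairs) and
controls the family-wise error with the Freedman–Lane permutation null of
the maximum |t| over cells.

### Net t-value

Each region is summarized as the sum of its positive edge t-values minus the
sum of absolute negative ones — algebraically the plain row sum of the t
matrix, and asserted as such. By default all edges contribute; restricting
to edges inside significant NBS components is available
(`edges = "nbs"`) but not the default, since the regional summary in this
methodology is conventionally computed from the full t map.

### SIMPLS partial least squares

Predictors (genes) are z-scored across regions; the response (net t-value,
left hemisphere) is z-scored. SIMPLS extracts components by deflating the
cross-product vector s = Xᵀy directly against the growing orthonormal basis
of X-loadings, which keeps the region scores exactly orthogonal (pinned at
10⁻⁸). For a univariate response the first weight vector is proportional to
Xᵀy — the covariance-maximizing direction, verified against a brute-force
random-search + BFGS oracle. Each component's score is sign-fixed at fit
time to correlate non-negatively with y, resolving the global sign
indeterminacy of PLS; bootstrap z-scores are invariant to flipping the sign
convention of X. The component explaining the most response variance is
selected (ties to the smallest index). K defaults to 5.

### Spatially autocorrelated surrogate maps

Testing the explained variance against plain permutations of y is
anti-conservative when y is spatially smooth, because smooth expression
predictors align with any smooth map. The null therefore uses
variogram-matched surrogates: permute y, smooth with a distance-decay kernel
over the k nearest regions, and affine-rescale so the surrogate's variogram
matches the empirical one.

Numerical choices, each of which proved load-bearing:

* the empirical variogram is a Gaussian-kernel smoothed semivariance cloud
  evaluated at 20 distances up to the 75th distance percentile — hard
  distance bins are noisy at desk-scale region counts and make the affine
  fit unstable;
* the affine fit is weighted by 1/γ̂², i.e. performed on the relative scale,
  because the short-distance bins of a smooth map are near zero and an
  unweighted fit ignores them;
* the kernel grid includes a k = 0 identity candidate so the kernel can
  degenerate: a spatially white map then yields plain permutations, as it
  should;
* surrogates are rank-remapped onto the observed values of y
  (`resample = TRUE`), preserving its histogram exactly. Without this, a
  flat variogram makes the affine coefficients (α, β) unidentifiable and
  surrogates drift toward Gaussian maps, which smooth predictors fit more
  easily than the heavy-tailed observed map — an inflated null;
* the grid search minimizes the *final* surrogate's relative variogram
  error, the same quantity reported as the per-surrogate diagnostic.

The permutation p re-fits the model on each surrogate and *re-selects* the
best component (selection-aware null): the observed statistic embeds a
selection step, so the null must too. p uses the +1 estimator over N
surrogates.

### Bootstrap gene scores and selection

Regions are resampled with replacement (draws with fewer than K + 1 distinct
regions or constant y are redrawn and counted); the model is refit with the
same K; the refit component whose weights correlate maximally in absolute
value with the original selected component is matched — component order can
swap under resampling, and index matching would inflate the SE — and
sign-aligned. The bootstrap SD of each gene's weight is its SE and
z = weight/SE. Genes with |z| strictly greater than 3 are selected and split
by sign.

### Over-representation

One-sided hypergeometric upper-tail tests per GMT term, intersected with the
analysis universe (all genes entering the PLS — not the genome, to avoid
selection-bias inflation; configurable). Terms smaller than 3 or larger than
half the population are skipped by default. BH-FDR is computed by the
step-up rule (q(i) = min over j ≥ i of m·p(j)/j, capped at 1) and
cross-checked against `p.adjust`.

## 2. The synthetic world

The generator emulates the statistical structure the analysis assumes, not
the physiology:

* **Atlas** — 7 canonical networks (SMN, VAN, VN, DAN, DMN, FPN, SC) with
  largest-remainder apportionment (≥ 2 regions each), centroids uniform in a
  brain-sized box, half of each network per hemisphere. No surface geometry,
  no volumes; sample-to-region matching is therefore by centroid distance
  (10 mm default), a documented divergence from volumetric parcel matching.
* **Cohort** — time series are multivariate normal with a block latent
  correlation: within-network r = 0.5, between-network r = 0.1 by default;
  group 2 receives +δ (default 0.3) on the chosen network pairs. These
  values keep the matrix positive definite at all tested sizes; inadmissible
  combinations are repaired by eigenvalue clipping at 10⁻⁶ (or error, with a
  repair hint, when `repair = FALSE`). Site effects are per-site affine maps
  of the latent correlation — this makes the ComBat estimand well defined —
  so an additive offset of 0.2 appears as a Fisher-z grand-mean gap slightly
  above 0.2 (atanh convexity). Clinical scores are drawn so HAMA > 18
  recovers the group labels; HAMD, age, sex, education and FD distributions
  are shaped on the real cohort's descriptive statistics but are
  placeholders, not claims.
* **Donor expression** — planted genes' regional profiles are
  a·z(target map) + squared-exponential Gaussian-process noise (length scale
  30 mm, amplitude 0.3 by default); decoys are independent unit GP fields.
  Samples sit near centroids with Gaussian jitter; only two of six donors
  have right-hemisphere samples; ~10% of probes are flagged below background
  in most samples; ~10% of genes carry a second, attenuated and noisier
  probe. A reference expression matrix (true value + small noise) stands in
  for RNA-seq in probe selection.
* **Gene sets** — one planted term holding every planted gene plus ≤ 25%
  filler, and uniform decoy terms.

What a green suite does *not* establish: hemodynamics, preprocessing
artifacts, realistic gene-gene co-expression (decoys are independent GPs —
real transcriptomes are dominated by a few expression gradients, which makes
the real predictor matrix *less* flexible than the synthetic one),
parcel-volume sample assignment, or anything about the real cohort's effect
sizes.

## 3. Calibration experiments and their design

* **NBS family-wise error** uses 200 null cohorts at the scale n = 30+30,
  R = 30, T = 120 with 200 permutations; the atlas is fixed across
  replicates (the parcellation is study infrastructure, never resampled in
  reality). See the component-statistic note above.
* **Edge-p uniformity** is checked on the *unstructured* null cohort
  (identity latent correlation). Marginal uniformity of the GLM p-values
  holds regardless of the correlation structure, but the Kolmogorov-Smirnov
  test presumes independent draws; edges of a network-structured cohort are
  mutually dependent (they share regions), which makes a nominal-level KS
  anti-conservative even when every marginal p is exactly uniform.
* **Surrogate-test calibration** draws 200 independent white-map worlds and
  checks the permutation p against uniformity (KS); with the k = 0 candidate
  and histogram resampling the surrogates reduce to permutations and the
  test is exact up to the +1 estimator's grid.
* **Planted-gene recovery** runs the full chain — planted cohort → edge GLM
  → net-t map → donor tables → expression processing → PLS → surrogates →
  bootstrap — on the fixed 160-region atlas (~81 left-hemisphere regions,
  matching the real analysis' 81) over 20 seeds, with the prescribed
  20 planted genes among 500, N = 199 surrogates and B = 200 bootstraps.
  Aggregate recovery and decoy rates are reported with a per-seed p-value
  success fraction; a single marginal seed (p ≈ 0.2) in 20 reflects honest
  sampling variability of a weak cohort realization, not a defect.

## 4. Degenerate inputs and tie-breaks

* Correlation of a constant time series: edge set to 0 with a warning.
* Probe above background in exactly 50% of samples: kept (inclusive rule).
* Sample equidistant from two centroids: the smaller region id wins.
* Probe-selection tie on the correlation criterion: lexicographically
  smaller probe id wins.
* Gene constant across samples (IQR = 0): normalized to 0.5.
* Component-selection tie: smallest index.
* |z| = 3 exactly: *not* selected (strict inequality).
* HAMA = 18: ANX−; FD = 0.2: included; both boundaries pinned by tests.
* A bootstrap draw with fewer than K + 1 distinct regions: redrawn, counted.
* Site with a single subject: error; collinear design columns: error naming
  the columns; complete separation in propensity matching: error.

## 5. Known limitations

* ComBat is parametric-EB only (no non-parametric priors, no reference
  batch) and, as noted, only approximately idempotent.
* Surrogates are generative nulls over centroid distances; spherical spin
  tests do not apply to volumetric parcellations and are not provided.
* The PLS path is univariate-response only; no CCA, no multivariate y.
* The bootstrap z measures the stability of each gene's weight, not a
  null-calibrated significance: spatially structured decoys retain a small
  but nonzero selection rate (~0.4% at desk scale), which is inherent to
  the method rather than an implementation artifact.
* Propensity matching is greedy 1:1 nearest-neighbour without replacement —
  order-dependent by construction; the order is randomized by seed.
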