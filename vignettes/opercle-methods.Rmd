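---
title: "Methods: outline morphometrics and comparative analysis of opercle shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline morphometrics and comparative analysis of opercle shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opercle)
```

`opercle` implements a complete workflow for studying the evolution of a
two-dimensional outline trait — the opercle, the flat bone of the gill
cover — across a clade such as a cichlid species flock.  This vignette is
the package's own account of the models and procedures, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate.

## From digitised outlines to shape variables

A specimen enters the pipeline as a closed curve of digitised points (TPS
format, `read_tps()`).  Coordinates are treated as planar with y increasing
upward; any `SCALE=` record multiplies raw coordinates, and no image-origin
flipping is performed — orientation is the digitiser's responsibility.
When a record carries both fixed landmarks (`LM=`) and a traced curve
(`CURVES=`/`POINTS=`), the curve is taken as the outline, because traced
outlines are stored as curves by the digitising software this dialect
comes from.

`resample_outline()` places k equidistant semilandmarks (default k = 100,
the sampling density commonly used for opercle outlines) by arc length
along the piecewise-linear curve, traversing clockwise (signed area
negative) from a homologous start point.  The start point is the vertex of
maximal discrete curvature on the dorsal (upper-y) half of the outline
(`detect_start_point()`), emulating the type II landmark at the dorsal
curvature maximum used to anchor such schemes; discrete curvature is the
exterior turning angle divided by the mean adjacent segment length, ties
resolve to the lowest index, and a degenerate (collinear, near-zero-area)
outline is an error.  A user-supplied index bypasses detection.

Superimposition (`gpa()`) is full generalized Procrustes analysis: each
configuration is centred, scaled to unit centroid size, and rotated onto
the running consensus by the orthogonal solution with reflections
disallowed (all specimens are same-side views, so a reflection would be a
digitising error, not shape variation).  The consensus is re-estimated
until its displacement falls below `tol` (default 1e-10, far below any
biological signal; `max_iter` = 100 with non-convergence flagged rather
than fatal).  Semilandmarks are treated as fixed points after resampling —
no sliding — and the tangent-space projection is the identity, the usual
small-variation assumption for within-clade data.

Ordination is PCA on the covariance (not correlation) of the flattened
aligned coordinates: all coordinates share units, so correlation scaling
would only inflate low-amplitude boundary noise.  Form space appends the
natural logarithm of centroid size to the coordinates, putting size back
into the ordination on a scale where proportional size differences are
additive.  PC signs follow the convention that each axis's
largest-magnitude loading is positive.  The effective shape dimension is
min(n − 1, 2k − 4); trailing numerically-zero eigenvalues are retained but
carry no variance.  `broken_stick()` flags axes whose variance fraction
exceeds the broken-stick expectation b_j = (1/p) Σ_{i=j..p} 1/i, with p
the number of axes supplied — the caller chooses the axis set under
assessment, which keeps the expectation well-defined when trailing exact
zeros are included deliberately.

## Group structure

`cva()` computes canonical variates as eigenvectors of W⁻¹B.  Raw shape
coordinates are first projected onto leading PCs (default
min(n − g, 20)) so the pooled within-group covariance is invertible; CV
scores are invariant (up to sign) to any invertible linear transform of
that retained basis, which the tests verify.  Species means are the
default observations, matching how such ordinations are usually reported.

`procrustes_anova()` partitions squared tangent-space distances
(Goodall-type F) and assesses significance by unrestricted permutation of
group labels with the add-one rule P = (1 + #{F* ≥ F})/(n_perm + 1).  Note
that F carries its degrees of freedom, so duplicating every specimen
rescales F by the df ratio while leaving the SS_B/SS_W partition
unchanged; the permutation P is what should be interpreted.  The analysis
runs separately on shape coordinates and on ln CS, reported as two rows,
since group effects on size and on shape are distinct findings.

## Trait-evolution models

All six models are Gaussian models for a species-level trait x on a
phylogeny with covariance structure V(θ) derived from the BM covariance C
(C_ij = shared root-to-MRCA path length):

* **BM**: V = C.
* **λ (Pagel)**: off-diagonals multiplied by λ ∈ [0, 1]; λ = 0 is a star
  phylogeny, λ = 1 recovers BM.
* **δ (Pagel)**: element-wise power C^δ, rescaled so the maximum diagonal
  equals the tree height T.  On ultrametric trees this is exactly the
  node-depth power transform; the rescaling is our stated convention for
  non-ultrametric inputs.  δ ∈ (0, 100]; δ > 1 concentrates change toward
  the tips.
* **EB/ACDC**: (e^{aC} − 1)/a with the a → 0 limit C; a ∈ [−20/T, 20/T].
  Positive a (acceleration) is deliberately allowed — common library
  defaults forbid it, but tip-ward concentration of change is a real
  hypothesis for radiations and excluding it would bias the comparison.
* **OU**: stationary, root-at-optimum form
  V_ij = e^{−2α(T − C_ij)}(1 − e^{−2αC_ij})/(2α), α ∈ [1e-8, 500]; for
  non-ultrametric trees T is the maximum tip depth.  This matches the
  common comparative-methods implementation and keeps OU exactly nested
  above BM as α → 0.
* **WN**: V = I, iid normal — the α → ∞ limit of OU.

The likelihood is the profiled GLS form: ẑ0 = (1ᵀV⁻¹x)/(1ᵀV⁻¹1),
σ̂² = rᵀV⁻¹r/n, and
lnL = −½[n ln 2π + n ln σ̂² + ln|V| + n], all via Cholesky factors.  ML
(not REML) is used throughout so that the parameter counts (k = 2 for
BM/WN, 3 otherwise) line up with the AICc accounting of a published
model-comparison table.  The single free transform parameter is optimised
by bounded Brent search restarted from five grid points across its bounds
(log-spaced for OU α, whose likelihood varies over orders of magnitude),
with the endpoints checked explicitly because λ̂ = 1 and δ at its ceiling
are common; estimates within 1e-6 of a bound are flagged `at_bound`, not
silently accepted.  Numerically infeasible covariances (failed Cholesky)
receive a large finite penalty so the optimiser simply avoids them.

`aicc()` applies AICc = 2k − 2lnL + 2k(k+1)/(n − k − 1), and
`compare_models()` turns AICc values into ΔAICc and Akaike weights.  The
published table this package ships as example data
(`inst/extdata/cichlid_model_aicc.csv`) prints LogL and AICc rounded to
two decimals; its weights are reproducible from the printed AICc to the
printed three-decimal precision, which is what the acceptance suite
checks.

Blomberg's K is the observed MSE₀/MSE (non-phylogenetic over phylogenetic
mean squared error about the GLS mean) divided by its analytic BM
expectation [tr(C) − n/(1ᵀC⁻¹1)]/(n − 1); K = 1 exactly on a star tree for
any data.  The permutation P uses MSE (not the ratio), counting
permutations with MSE ≤ observed under the add-one rule — the convention
of the common implementation this statistic comes from.  Pagel's λ̂ as a
signal measure is the λ-model ML fit.

`ratematrix()` estimates the multivariate BM rate as the mean outer
product of the standardised independent contrasts (divisor n − 1), which
equals the dense GLS estimator about the phylogenetic mean — the tests
assert that identity on random trees.  `sim_traits()` simulates
multivariate BM by the edge-wise recursion, adding N(0, R·branch length)
increments from one seeded generator per call.

## PGLS

`pgls_fit()` fixes the residual covariance at C (no concurrent λ
estimation): the stated residual model is neutral Brownian motion, and
estimating λ simultaneously would change the estimand.  Species missing
the response or covariate are dropped pairwise and the tree is pruned to
the retained set, so each regression uses the maximal data available to
it.  P values are two-sided (sidedness is an interpretation choice; the
symmetric default is reported).  The reported `correlation` is
sign(β̂) × sqrt(1 − RSS_GLS/TSS_GLS) with TSS about the phylogenetic mean —
a definition chosen because published analyses report a signed
"correlation" alongside the slope without defining it, and the signed
square root of the GLS coefficient of determination is the quantity that
reduces to the ordinary correlation on a star tree, which the tests
verify against OLS.

## Convergence by distance contrast

`distance_contrast_analysis()` compares each species pair's observed
morphological distance (Euclidean in the retained score space; equivalent
to the Procrustes distance between mean shapes when all axes are
retained) with its distribution under neutral BM: the rate matrix is
estimated from the scores, `n_sims` datasets are simulated with the GLS
root state, and each pair receives the bootstrap estimate of the 2.5th
percentile of its own simulated-distance distribution (mean over `n_boot`
joint resamples of the simulation replicates).  Pairs below that
threshold are flagged convergent; the per-pair threshold is essential —
one global cutoff would conflate pairs whose expected distances differ by
orders of magnitude.  Under the null ~2.5% of pairs are flagged, which is
the calibration the acceptance suite measures, and the expected count
0.025 × n(n−1)/2 is reported alongside the observed count.  Known
outliers can be excluded by name before the analysis, mirroring how a
single long-branch taxon would otherwise dominate every pairwise
comparison.

## Disparity through time

`disparity_of()` is the mean squared pairwise Euclidean distance.
`dtt_curve()` evaluates, at each internal-node time, the mean relative
disparity of the lineages crossing that time, where an edge ending
exactly at the divergence counts as one crossing lineage (so the value at
a node time reflects the clades as of that divergence, the root time is
the whole clade and the curve starts at 1, and any time after the last
divergence would be 0).  Node times are relative: 0 = root, 1 = deepest
tip.

`mdi()` simulates BM with the estimated rate matrix, computes every
simulation's curve on the same node-time grid (same tree, so the grid is
shared exactly), and integrates observed − simulation-median over
[0, cutoff] treating the curves as step functions between node times —
the node-wise definition makes a step, not a polygon, the faithful
interpolant.  The default cutoff 0.9 excludes the tip-dense final tenth
of tree height where single-specimen subclades over-disperse the
statistic.  The P value is two-sided (each simulation's own MDI against
the same median, doubled and capped at 1): published analyses report the
sign of the deviation separately from its significance, and a one-sided
test would build the expected sign into the inference.

## The synthetic-data generator

`make_synthetic_dataset()` emulates the structure of the motivating study
design — 54 species on a pure-birth tree (height 1), 416 specimens at 5–10
per species, 100-point outlines, 6 feeding-preference and 7 feeding-mode
labels, 7 covariates — with every ground truth recorded.  Default
conditions, chosen once as a realistic study configuration:

* Template: a superellipse-like closed curve (aspect 0.8) with one sharp
  dorsal bump so the start-point detector has a well-defined anchor; the
  template is constructed as a fixed point of equal-arc resampling, making
  it exactly resample-idempotent.
* Deformation basis: sinusoidal normal-displacement fields of increasing
  frequency, projected off the four similarity-transform directions
  (translations, rotation, scaling) and orthonormalised.  The projection
  matters: an unprojected low-frequency field partly aliases into
  translation/scaling, which GPA then removes, and a planted axis would
  not be recoverable as a principal component.
* Latent dimensions: BM (σ² = 0.004), λ = 0.8 (σ² = 0.002), δ = 3
  (σ² = 0.001), OU α = 2 (σ² = 0.0005) — a dominant neutral axis plus
  progressively weaker axes with distinct phylogenetic structure, giving
  leading shape-variance fractions comparable to published opercle PCAs.
* Specimen noise sd 0.01 (unit-shape scale, ~1% of outline size, a
  plausible digitising error), ln CS Brownian with rate 0.25 around
  ln 50 plus allometric coupling (coefficient 2) to the first latent
  dimension and individual lognormal sd 0.1.
* Covariate slopes: δ15N and mean gill-raker length load on the first
  latent dimension, gut length (GLTL) and elongation (ER, negative) on
  the second; δ13C and both gill-raker counts have slope 0 so the null
  side of PGLS is represented.  Counts are rounded with a floor at 0; ER
  and GLTL stay positive via an exponential link.
* Feeding groups: contiguous blocks of the tip order (clade-structured by
  default) with mean shifts of magnitude 0.06 along the first two fields.

Deformations large enough to risk a self-intersecting outline (pointwise
displacement beyond 45% of the template's RMS radius) are clipped with a
warning rather than producing geometric nonsense.

What passing tests on these data show: that every stage recovers what was
planted — models, slopes, group separation, convergent pairs, disparity
calibration — under its own generating assumptions, and that the full
pipeline is deterministic under a seed.  What they do not show: robustness
to real-data features the generator omits — digitising artefacts and
outline self-overlap, allometric shape change beyond a single linear
coupling, measurement error correlated along the outline, missing
specimens biased by size or rarity, and phylogenetic uncertainty (the
tree is treated as known throughout).

## Problem sizes and numerical conventions

The test and acceptance suites use deliberately scaled simulation sizes —
for example 200 BM replicates at n = 128 for the K calibration, 100
replicates at n = 200 for λ and slope recovery, 500 null regressions for
the type-I rate, 20 replicates of 500 simulations for the convergence
null, and 50 replicates of 500 simulations for MDI — sizes at which the
Monte-Carlo error is comfortably inside each acceptance band while the
whole suite stays fast on a single CPU.  The end-to-end pipeline run in
the acceptance script uses the full study scale (54 species, 416
specimens, k = 100, 1000 simulations).

Numerical conventions, collected: coordinate round trips are exact to
1e-9 (12 significant digits written); GPA tolerance 1e-10; PSD checks
tolerate eigenvalues above −1e-8 relative; covariance transforms clamp
parameters to their bounds at 1e-6 relative resolution; permutation and
simulation P values use the add-one rule, which bounds P below by
1/(n_perm + 1) and keeps it strictly positive; ties in start-point
curvature and in PC sign conventions resolve deterministically (lowest
index, largest-magnitude loading positive).

## Known limitations

Single-optimum OU only (no multi-regime models); no sliding
semilandmarks or bending-energy relaxation; 2-D outlines only; the δ
transform's height-rescaling convention on non-ultrametric trees is a
documented choice rather than a canonical definition; PGLS fixes the BM
residual rather than estimating λ; and the EB bound ±20/T caps how much
acceleration the model can express on short trees.
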