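---
title: "Methods: segmented regionalization of rib shape along the body axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented regionalization of rib shape along the body axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribregions)
```

# The model

`ribregions` treats a ribcage as an ordered series of shapes. Each rib is a
configuration of 3D landmarks (fixed points plus one ordered curve of
semilandmarks along the visceral face). After generalized Procrustes
superimposition — centering, scaling to unit centroid size, and optimal
proper rotation to the iterated consensus — the residual variation is
*shape*, and its projection onto the first principal components gives a
small set of shape variables per rib.

Regionalization is modeled as piecewise linearity of these shape variables
in axial position. A *k*-region model partitions the sampled ribs into *k*
contiguous segments; each segment gets its own slope and intercept per PC,
fit independently by ordinary least squares (no continuity constraint —
regions are discrete morphological units, and continuity is deliberately
not imposed). For each *k* from 1 to `max_regions`, the breakpoint
placement minimizing the total residual sum of squares is found exactly by
dynamic programming over precomputed per-span costs; an M-best variant of
the same recursion supplies the runner-up models used by the stability
rule.

Model comparison uses the small-sample Akaike criterion on the stacked
observations,

$$\mathrm{AICc} = N \ln(\mathrm{RSS}/N) + 2p + \frac{2p(p+1)}{N-p-1},$$

with $N = n_\text{ribs} \times n_\text{PCs}$ and $p = 2kn_\text{PCs} + 1$
(a slope and intercept per segment per PC, plus one pooled error
variance). This counting convention penalizes every per-segment parameter;
it is configurable in the sense that the criterion is exposed directly
(`aicc()`), but the pipeline uses this definition throughout. Akaike
weights over the per-*k* best models give the model probabilities, and
their weighted average region count is the **region score** — a continuous
summary that degrades gracefully when two region counts are nearly tied.

Boundary positions are reported as percentages of the total rib count,
mapping sampled ordinals back to original rib indices in subsampled
series.

## Allometric decomposition

Procrustes superimposition removes size but not *allometry* — the shape
variation predicted by size. The flattened aligned coordinates are
regressed on log centroid size (multivariate OLS, one slope per
coordinate); significance comes from permuting the size vector
(`n_perm` = 999 by default, p = (exceedances + 1)/(n_perm + 1)). The
residual coordinate arrays — not residual PC scores — are fed through the
identical PCA + segmented-regression machinery, because the decomposition
is defined on shape variables, and recomputing the PCA keeps the residual
shape space orthogonal by construction. The number of allometric
boundaries is the signed difference in best-fit region counts,
$A = k_\text{full} - k_\text{residual}$; negative values are reported with
a warning flag rather than clamped, since a residual analysis supporting
*more* regions than the full one signals a pathological fit the user
should see. The region-score drop is likewise
$S_\text{full} - S_\text{residual}$.

One property of this decomposition deserves emphasis: OLS residuals are
orthogonal to the regressor only *globally*. When a genuinely
size-independent boundary shift is correlated with the size profile, the
residuals necessarily contain a compensating component proportional to
log CS, which inherits any kinks or jumps of the size profile and can
surface as spurious residual boundaries. This is intrinsic to the method,
not an implementation artifact; it is weakest when size-independent
boundaries sit where the size profile is flat.

## Heterogeneity and group contrasts

Axial heterogeneity *H* summarizes how different a specimen's ribs are
from one another: the range of partial Procrustes distances over all rib
pairs. Two readings of "range" are defensible; the package computes both
and reports the maximum pairwise distance (the diameter of the shape
scatter) as primary, with max − min of distances to the consensus as the
alternative (`H_consensus_range`). The alternative degenerates toward the
maximum because adjacent ribs are nearly identical, making the minimum
distance effectively zero.

The 4% and 96% ribs are compared to the mid-point rib; on a 4% sampling
grid an exact 50% rib rarely exists, so the mid rib is the sampled rib
whose index is nearest `round(0.5 (n - 1)) + 1` (48% or 52%, anterior on
ties), and the choice is recorded in the output.

Between-species disparity at an axial interval uses one rib per species,
jointly superimposed with a fresh GPA per interval so all distances live
in one shape space; the statistic is the Procrustes variance (mean squared
distance to the interval consensus). Group comparisons use Welch's
unequal-variance *t* with Satterthwaite degrees of freedom, and shape
differences between groups use a permutation Procrustes ANOVA
(F from between/within sums of squares over superimposed coordinates,
labels permuted).

## Comparative phylogenetics

Tree dating uses minimum-branch-length scaling: tip ages are first
appearance dates (Ma) and each node's age is the maximum over children of
child age + `mbl`, applied in post-order, so nodes appear in the order of
their oldest descendant's first appearance and every branch is at least
`mbl` (1 Myr by default, the conventional floor). Polytomies are retained
rather than randomly resolved, since any resolution policy would be
arbitrary.

Ancestral states under Brownian motion solve the weighted least-squares
system minimizing $\sum_\text{branches} (\Delta a)^2/\ell$ — the sparse
Laplacian form of the maximum-likelihood estimator, identical to the
re-rooted GLS estimator. Node variances are the conditional variances of
the internal states given the tips (the inverse of the internal-node
Laplacian block), scaled by the ML rate
$\hat\sigma^2 = (x-\hat\mu)^\top C^{-1}(x-\hat\mu)/n$; 95% CIs use
±1.96 sd. Zero-length branches are perturbed to $10^{-8}$ with a warning.
The variance bookkeeping is validated by simulation (root-CI coverage of a
known root state across replicated Brownian simulations on 64-tip trees)
rather than against any particular reference implementation.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `interval_percent` | 4 | % of axis | 26 sampled ribs for elongate (>50 ribs) specimens, equalizing model parameterization across rib counts |
| `n_retained_pcs` | 6 | — | captures ≈95% of shape variance in rib data |
| `max_regions` | 6 | — | allows species with elevated region counts |
| `min_seg` | 3 | sampled ribs | two points fit a line exactly and would saturate the likelihood |
| `n_perm` | 999 | — | permutation resolution of 0.001 |
| `mbl` | 1 | Myr | conventional minimum branch duration |
| `tol_positions` | 1 | sampled positions | the stability rule's reading of "consistent in boundary position" |

The stability rule compares the best model against the next five models in
the cross-region-count AICc ranking by default (`ranking = "within_k"` is
available). Models with different region counts are compared on shared
boundaries: sorted boundary lists are greedily matched one-to-one within
`tol_positions`, and a runner-up passes when the matched count equals the
smaller list — so an overfit that preserves the best model's boundaries is
consistent, while one that displaces a boundary is not. With fewer than
six ranked models the flag is indeterminate (`NA`) rather than an error.

# Numerical choices

- **Rotations** are proper only (determinant +1): ribs come from one
  bilateral half and chirality is meaningful, so reflections must not be
  absorbed by the superimposition.
- **GPA convergence**: RMS change of the consensus below 1e-9, up to 500
  iterations (near-antipodal shape pairs converge slowly; rib series
  converge in a handful of iterations).
- **Pairwise distances** are partial Procrustes distances (no extra
  scaling step): shapes are already at unit centroid size.
- **Semilandmarks** are treated as fixed points by default — the simplest
  reproducible treatment; tangent-direction sliding is available behind
  `slide = TRUE` and alternates with re-superimposition.
- **Saturated models**: an RSS below 1e-9 of the data's total sum of
  squares is treated as an exact fit; AICc is −∞ and both model selection
  and Akaike weighting then prefer the smallest such region count
  (parsimony), preventing floating-point noise from rewarding overfits on
  noiseless input.
- **AICc ties** break toward smaller *k*.
- **Percent→rib mapping** in subsampling: index = round(p/100·(n−1)) + 1
  with round-half-up, covering both axial extremes symmetrically;
  duplicate indices after rounding (possible just above 50 ribs) keep the
  first occurrence.

# The synthetic-data generator

The generator is the package's ground-truth instrument. A rib template (a
half-ellipse with torsion, sampled at 12 fixed + 18 semilandmark
positions) varies along the axis through three channels:

1. **Allometric channel.** Log centroid size follows a continuous
   piecewise-linear profile that rises toward the mid-axis and falls again
   — a growth-rate change at every size-coupled boundary, plus an optional
   size jump there (`size_step`). Shape tracks size along a single global
   direction with sensitivity `allometry_strength`, so this channel is
   *exactly* linear in log CS and is removed in full by the size
   regression. Size-coupled boundaries therefore exist in the full
   analysis (kinks and jumps in shape at the boundary) and vanish from the
   residual analysis, which is precisely what "allometric boundary" means.
2. **Size-independent channel.** Mean shape shifts of magnitude `shift` in
   their own random directions at the non-allometric boundaries, plus a
   continuous piecewise-linear drift whose direction changes only at
   non-allometric boundaries. This displacement field is orthogonalized
   against centered log CS at generation time, making "size-independent"
   exact in the sample sense.
3. **Noise.** Isotropic Gaussian landmark noise (`noise_sd`), applied
   before scaling to the target centroid size and random rotation +
   translation of each rib (so the superimposition is exercised for real).

Default amplitudes were fixed once, as the package's model of the study
conditions: `noise_sd = 0.002` puts ≈93–98% of shape variance in the first
six PCs, matching the variance-capture regime of real rib data; the
snake-like condition uses a small allometric sensitivity (0.1) with size
jumps, so all three boundaries are size-coupled and heterogeneity is low
(H ≈ 0.13); the limbed condition scales all shape amplitudes by
`amplitude_ratio = 3`, carries size-coupled anterior and posterior
boundaries, and places its size-independent boundary mid-axis where the
size profile is flat (minimizing the intrinsic residual-ghost effect
described above), giving H ≈ 0.16 and larger extreme-versus-mid distances.
At `amplitude_ratio = 1` the groups have comparable amplitudes — the
calibrated null for the heterogeneity contrast.

Two detectability facts shaped these defaults and are worth knowing when
designing simulations. First, in a 90-dimensional landmark space sampled
at 26 ribs, isotropic noise inflates the leading noise eigenvalues
(Marchenko–Pastur edge ≈ $(1+\sqrt{\dim/n})^2\sigma^2$), so a boundary
shift must exceed roughly 6× the per-coordinate noise SD to survive into
the retained PCs — not the 3× a one-dimensional intuition suggests.
Second, exactly size-predicted shape variation is rank-1 (it lives on one
line in shape space), so an all-allometric specimen whose size profile is
*monotone* is statistically close to a single linear trend; detectable
all-allometric regionalization requires a non-monotone size profile, which
is also the biologically realistic case (ribs lengthen toward the
mid-trunk).

What the generator does **not** emulate: intraspecific variation (one
specimen per species); articulated anatomy (templates are smooth curves,
not real rib geometry); sliding-semilandmark error structure; missing
landmarks; and cross-body-type convergence of the mid-axis shape — the two
body types use templates of different torsion, so between-group shape
tests at the mid-axis stay significant on synthetic cohorts, unlike the
mid-axis overlap seen in real squamate data. Passing tests therefore
demonstrate correctness of the machinery and recoverability of known
structure under realistic noise, not biological verisimilitude of the
template.

# Problem sizes in the test suite

The suite exercises the pipeline at the scales the methods are designed
for: 101-rib elongate series subsampled to 26, limbed series of 24–44
ribs, cohorts of 12 + 12 species, 100-seed recovery and contrast
simulations, 200-seed permutation-uniformity and ancestral-state coverage
simulations, 64-tip trees for coverage and ≤8-tip trees for exact GLS
equality. Brute-force segmentation checks run at n ≤ 15 where exhaustive
enumeration over all breakpoint sets is cheap.

# Known limitations

- The stability rule's tolerance (±1 sampled position) and its cross-count
  ranking are conventions; both are exposed as arguments and reported
  alongside results.
- Boundaries within `min_seg` sampled positions of an axial extreme cannot
  be localized more finely than the sampling grid permits; an anterior
  boundary at ~7% of a 26-sample grid is recoverable only to the nearest
  feasible breakpoint.
- The allometric decomposition inherits the global-orthogonality caveat
  above: with strongly size-correlated non-allometric structure, residual
  region counts can exceed the size-independent truth.
- Ancestral-state CIs assume a homogeneous Brownian rate; rate shifts or
  selection will miscalibrate them.
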