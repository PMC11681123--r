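# ribregions

Quantitative regionalization analysis of the dorsal ribcage from 3D
landmarks, for evolutionary morphologists studying axial-skeleton evolution
in squamates and other tetrapods — in particular the question of whether
elongate, limb-reduced ("snake-like") body forms lose axial regions or
merely make them cryptic.

Given per-rib landmark configurations ordered along the cranial–caudal
axis, the package:

1. **Superimposes** the ribs by generalized Procrustes analysis (GPA),
   removing position, orientation and size, and records centroid size
   *CS* = √Σᵢ‖xᵢ − x̄‖².
2. **Reduces** the Procrustes shape variables by PCA, retaining the first
   six components (typically ≈95% of shape variance).
3. **Delimits regions** by segmented linear regression: for each region
   count *k* = 1…6, an exact dynamic-programming search over breakpoint
   placements minimizes the pooled residual sum of squares of independent
   per-segment, per-PC linear fits of score on axial position. Models are
   compared with the small-sample Akaike criterion
   AICc = *N* ln(RSS/*N*) + 2*p* + 2*p*(*p*+1)/(*N*−*p*−1),
   and the Akaike-weight average of *k* is reported as the continuous
   **region score** S = Σₖ wₖ·k. A best-fit model is *accepted* when the
   next five top-ranked models agree with it in boundary position.
4. **Decomposes** boundaries into allometric and size-independent
   components: shape is regressed on log CS (multivariate OLS with a
   permutation test), the segmented analysis is repeated on the residuals,
   and the difference in best-fit region counts is the number of
   **allometric boundaries**.
5. **Quantifies axial heterogeneity** *H* as the range of pairwise partial
   Procrustes distances among a specimen's ribs, compares the 4% and 96%
   ribs to the mid-point rib, and contrasts groups (Welch *t*, Procrustes
   ANOVA with permutation, per-interval between-species disparity).
6. **Maps heterogeneity over a phylogeny**: minimum-branch-length
   time-scaling from first-appearance dates, then maximum-likelihood
   Brownian-motion ancestral-state reconstruction with per-node variances
   and 95% CIs.

A first-class synthetic-data module generates rib series, two-body-type
cohorts and Brownian-motion trees with known ground truth, so every stage
is testable without any scan data.

## Worked example

```r
library(ribregions)

# an elongate specimen with 101 ribs, three region boundaries, all of them
# size-coupled (the snake-like condition), generated with known truth
sim <- generate_rib_series(synthetic_rib_spec(seed = 42))
an  <- analyze_species(sim$series, run_config(seed = 1), fit_perm = 199)

print(an$series)
#> Rib series: synthetic_sp ( snake-like )
#>   26 ribs sampled of 101 total; 30 landmarks per rib ( 12 fixed + 18 semi )
print(an$full)
#> Regionalization: 26 sampled ribs, 6 PCs
#>   best model: k = 4  region score = 4.000  accepted = FALSE
#>   boundaries at 8.9%, 48.5%, 88.1% of the rib count
print(an$allometry)
#> Allometric regression of shape on log centroid size
#>   R^2 = 0.7738, permutation p = 0.005 (199 permutations, seed 1)
print(an)
#> synthetic_sp (snake-like): k = 4 (score 4.00), non-allometric k = 1, A = 3, H = 0.1313
```

Reading the output: the 101-rib series was subsampled to 26 ribs at 4%
axial intervals; the best segmented model has four regions with boundaries
at 8.9%, 48.5% and 88.1% of the rib count (the generating truth was 6.9%,
49.5% and 88.1%). Size explains 77% of shape variation, and after removing
it the best residual model has a single region — all three boundaries are
allometric (A = 3), exactly as constructed. Axial heterogeneity is 0.131
Procrustes units.

Cohort-level contrasts (`generate_cohort()` + `analyze_cohort()`) compare
limbed against snake-like species: region score, anterior/posterior
boundary position, heterogeneity, non-allometric region score, per-interval
disparity, and ancestral heterogeneity on a time-scaled tree.

A command-line front end with `simulate`, `analyze-species`,
`analyze-cohort`, `timescale` and `asr` subcommands is installed at
`inst/scripts/ribregions.R`.

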