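---
title: "Methods: image-based selection experiments with canopysel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based selection experiments with canopysel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopysel` implements a complete early-generation selection experiment
for soybean: canopy coverage is extracted from plot-level RGB imagery,
breeding values for yield, average canopy coverage (ACC), yield adjusted
for ACC (Yield|ACC) and days to maturity (R8) are estimated with a
pedigree-based animal model, lines are advanced by truncation selection
under each category, and the selected material is evaluated in replicated
multi-location trials. This vignette documents the models, the synthetic
data that stands in for field data, and the numerical choices, in that
order.

## 1. Canopy coverage from imagery

Each plot image is reduced to the fraction of pixels classified as
vegetation. Pixels are first chromaticity-normalized, `r = R/(R+G+B)` and
likewise for `g`, `b` (a black pixel is assigned `r = g = b = 1/3`), then
scored with the Excess Green index `ExG = 2g − r − b`, which is high for
green-dominant vegetation, zero for any gray, and bounded in `[−1, 2]`.
Normalization is a deliberate choice: the raw-channel variant of ExG is
sensitive to illumination, while the normalized index is invariant to
uniform brightness changes and gives a fixed range for histogramming.

The vegetation/soil split uses Otsu's criterion: the `n_bins − 1` interior
edges of an equal-width binning of the observed ExG range are candidate
thresholds, and the edge maximizing the between-class variance
`w0*w1*(mu0 − mu1)^2` is chosen; values strictly greater than the
threshold are canopy (ties go conservatively to background). `n_bins`
defaults to 256 (8-bit heritage) and is exposed. Two degenerate regimes
are guarded, because Otsu is undefined on constant input and unstable on
unimodal input: if the maximal between-class variance falls below `1e-4`,
or more than 99% of pixels fall on one side of the fixed cutoff
`ExG > 0.1`, classification falls back to that fixed cutoff. This is what
keeps bare-soil and closed-canopy frames from being split down the middle
of their noise.

Replicate images of the same plot and date (the mosaic extraction process
produces a varying number of them) are aggregated by the median; ACC is
the unweighted mean of the per-date medians over the season's sampling
dates, with missing dates simply left out. Coverage is stored as a
fraction and rendered as percent (1 decimal) in output tables.

## 2. Pedigree relationships

Lines are F4-type inbreds: biparental crosses among founders followed by
selfing, with selfing encoded as `sire = dam = progenitor`. Under that
convention the tabular method (`build_a_matrix()`) accumulates inbreeding
with no special cases; a chain of `t` selfing generations from a
non-inbred F1 gives diagonal `2 − (1/2)^t` (1.875 for an F4). Model
fitting never forms dense `A`: `a_inverse()` assembles the sparse inverse
directly from the pedigree via Henderson's rules with Mendelian-sampling
variances `d_i = 1 − sum_p (1 + F_p)/4`, and inbreeding coefficients come
from a memoized coancestry recursion, so pedigrees with ~10,000
individuals stay cheap. A single known parent is treated as if the
missing parent were an unrelated founder. The tests cross-check the
tabular matrix against an independently written recursive-coancestry
oracle and the sparse inverse against `solve(A)`.

## 3. The animal model

Progeny-row phenotypes are fitted per trait with
`y = Xb + Zg + e`, `g ~ N(0, A sigma_a^2)`, `e ~ N(0, R sigma_e^2)`,
where the fixed part holds an intercept plus optional centered covariates
(ACC for Yield|ACC; one slope per covariate — per-genotype slopes are not
identifiable on unreplicated plots). Replicated checks share one `g`
across their plots and are included as phenotyped lines.

The field correlation `R` implements the neighbor-plot idea: rook
adjacency on the row/column grid, a neighbor correlation estimated as the
Pearson correlation between each plot's phenotype and the mean of its
neighbors, placed on every adjacent pair and scaled back (Gershgorin
bound `|rho| < (1 − 1e-6)/maxdegree`) so the matrix is guaranteed
positive definite. Because the one-line description of neighbor-based
correction admits a second reading, the alternative — the neighbor-average
phenotype as a fixed covariate — is available via
`spatial = "covariate"`; the correlation structure is the default, and
neither is claimed to be the original formulation.

Estimation is single-site Gibbs sampling (Rcpp/Armadillo): normal
conditionals for fixed effects, scalar normal conditionals for each
genetic effect using the sparse `A` inverse, and scaled-inverse-chi-square
conditionals for the two variance components. One extra move matters: a
line-level covariate is confounded with the genetic effects (one plot per
line), and coordinate-wise updates mix arbitrarily slowly along the
direction "shift the slope, shift all g accordingly". The sampler
therefore adds an exact Gibbs update along that direction each iteration
(precision `w'R⁻¹w/sigma_e^2 + a'A⁻¹a/sigma_a^2`, with `a` the line-mean
covariate and `w` its within-line deviation), which was validated against
the exact mixed-model-equation solution with the covariate included.

Chain defaults are 6000 iterations, 1000 burn-in, thinning 5, and a
mandatory seed; chains are bit-reproducible. Convergence is reported as
split-chain R-hat on both variance components. Simulation studies in the
tests use shorter chains (2500/500) at n = 2000 plots, sized so that a
three-level heritability grid with 20 replicate datasets per level runs
in minutes; posterior means at those settings agree with long chains to
within the replicate-to-replicate spread.

**Priors.** Both variance components get proper but diffuse
scaled-inverse-chi-square priors with `nu = 1` and scale `0.1 * var(y)`.
A seemingly harmless "half the phenotypic variance with a few degrees of
freedom" scale prior implicitly centers the prior heritability at 0.5,
and on unreplicated data — where `sigma_a^2` is only weakly identified —
that pull is visible: with true `h² = 0.1` at n = 2000 plots the
posterior-mean estimate rises to about 0.17, versus about 0.13 under the
diffuse default (an exact eigen-rotated ML fit of the same data is
unbiased at 0.11). A residual upward bias of ~0.03 at low heritability
remains; it is the positivity skew of a posterior mean near a boundary,
not a sampler artifact, and shrinks with replication or deeper pedigrees.

Heritability is computed per draw as `sigma_a^2/(sigma_a^2 + sigma_e^2)`
and averaged (ratio-then-average); only the two Eq.-type components enter
even though checks are replicated, faithful to the single-trait model.
Phenotypic-correlation summaries are Pearson correlations among BLUP
vectors over the intersection of lines.

## 4. Selection

Within each category, lines are ranked by BLUP and the top
`floor(fraction * n)` (minimum 1) are kept; the program's intended
fractions were approximate (9% of 2747 progenies, later 7.5% of 4052,
with deviations for seed and logistics), so a deterministic floor rule
with lexicographic tie-breaking is fixed instead of reproducing
deviations. Overlaps among categories are accounted exactly (union,
per-combination counts). Selected lines split into early and late
maturity groups against a check's R8, with boundary ties assigned early;
BLUP-adjusted R8 is used by default since raw single-plot maturity is
noisier. Predicted response uses the breeder's equation
`dG = h^2 i sigma_p / L` with `i = dnorm(qnorm(1 − p))/p`.

## 5. Multi-location trial evaluation

Replicated trials are fitted by REML with independent random effects for
genotype, location, replication within location, incomplete block within
replication, and genotype-by-location interaction. The restricted
log-likelihood is profiled over the residual variance and maximized over
log variance ratios with L-BFGS-B; components shrinking below `1e-7` of
the residual are set to zero and the model refit without them, and when
at most two components remain a cyclic golden-section polish at `1e-11`
tolerance is applied — that is what makes the balanced one-way case agree
with the closed-form ANOVA estimators to `1e-6` rather than to optimizer
slack. Components the design cannot identify (one location, one
replicate, no blocking) are dropped with a warning up front. The fit is
cross-checked against lme4 in the tests (agreement in components, BLUPs
and the REML criterion), and an independent random-point oracle verifies
the returned optimum dominates random admissible ratios.

Genotype enters random for preliminary trials (effects are empirical
BLUPs with prediction-error-variance standard errors) and fixed for
advanced trials (GLS with sum-to-zero contrasts). Adjusted means are
`mu + g_i`, at the mean of any covariate; yield given R8 refits with
centered R8 as a fixed regression. Category comparisons are two-sided
Welch t-tests on per-line adjusted means — Welch because category sizes
and variances differ, per-line means because that is the unit the
distributions are drawn over — with conventional stars and deliberately
no multiple-testing correction across the pairs (each pair is reported on
its own, as trial reports do; noted here so nobody mistakes the stars for
family-wise statements). Early and late trials are analyzed separately,
never pooled. Top-rank attribution sorts the advanced-trial adjusted
means and labels each of the top k lines with every category that had
selected it, summarizing how many came only through the canopy-based
categories versus direct yield selection alone.

## 6. The synthetic-data generator

The generator emulates the experiment's data-generating process with
known truth at every level:

- **Pedigree**: unrelated founders, random biparental crosses, a selfing
  chain per cross (3 selfing generations by default, i.e. F4 lines).
- **Breeding values**: multivariate normal with covariance
  `kron(G, A)`, where trait `t` has additive variance
  `h2_t * sigma_p_t^2` and trait correlations come from the genetic
  correlation matrix. Defaults take the progeny-row estimates of the
  system under study: `h²` 0.23 (yield), 0.06 (ACC), 0.36 (R8);
  phenotypic SDs 600 kg/ha, 0.05, 6 days; means 3500 kg/ha, 0.25, 105
  days; ACC-yield genetic correlation 0.87 (the literature value used as
  a scenario parameter), yield-R8 0.3, ACC-R8 0. Values are drawn
  generatively down the pedigree (parent average plus Mendelian sampling
  scaled by parental inbreeding), which is exact and O(n).
- **Field trial**: a grid layout with every line in one plot and checks
  inserted every `check_spacing` plots (the real check density of the
  modified augmented design is not published, so it is a parameter);
  phenotype = mean + BV + spatial trend + iid residual. The spatial trend
  is a sum of three random-phase 2-D cosines rescaled to `spatial_sd` —
  smooth, cheap, known variance — and is **shared across traits** (scaled
  per trait): fertility patches raise growth, maturity and yield
  together, and that shared environmental signal is exactly what makes
  ACC a useful covariate and produces the characteristic negative
  correlation between ACC BLUPs and Yield|ACC BLUPs. Residual variance is
  `(1 − h2) sigma_p^2 − spatial_sd^2`, floored at `1e-6 sigma_p^2`.
- **Canopy trajectories**: a logistic curve in days after planting,
  rescaled per line so the mean over the sampling schedule equals the
  line's ACC; the default schedule is the eight early-season dates
  15–54 DAP, with a seven-date 20–56 DAP alternative for a fast-canopy
  season (a season's abnormal growth is representable only through these
  curve parameters, not mechanistically).
- **Imagery**: 8-bit RGB rasters at 1.5 cm/pixel by default (the
  50 m-flight resolution), soil brownish with mostly luminance noise
  (R ≥ G), canopy as green-dominant blobs along the row axis with the
  G-over-R margin drawn per plant blob — separable by ExG but not
  trivially so. The exact foreground mask is produced by thresholding a
  smooth blob field at the k-th largest pixel, so the mask fraction
  matches the requested cover to within half a pixel and is stored as
  ground truth. Replicates re-draw blob placement and illumination, not
  the target cover.
- **Replicated trials**: genotype effects plus location, replication,
  incomplete block (size `block_size`), genotype-by-location and residual
  draws, with an optional maturity trait and a plot-level maturity slope
  on the response.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data — includes lodging, weeds,
shadows and soil-moisture color variation in imagery; photogrammetric
artifacts of mosaic extraction; non-normal yield errors, harvest errors
and spatial structure beyond a smooth trend; genotype-by-year effects;
and any deviation of the real program's selections from the nominal
fractions.

## 7. Validation design and problem sizes

Every operation is checked against an independent route: Otsu against
exhaustive search over all bin edges; the tabular `A` against a recursive
coancestry oracle (20 random 50-individual pedigrees, `1e-12`); the Gibbs
sampler with fixed variances against the direct mixed-model-equation
solve (200 lines; correlation above 0.999); REML against lme4, closed-form
ANOVA and random-restart dominance; Welch statistics against the textbook
formula. Parameter-recovery studies use 2000-plot unreplicated datasets
(20 per heritability level in the test suite) and 100-genotype,
two-location, two-replicate trials (50 fits); the correlated-response law
is checked at 50 replicates of n = 2000 with the 0.87 scenario
correlation, where the realized indirect/direct yield response ratio
should approach `r_g * h_ACC / h_yield`. The full pipeline is additionally
required to be byte-identical when rerun from the same configuration and
seed.

## 8. Known limitations

- The posterior-mean heritability carries a small positive bias (~0.03)
  at low true heritability on unreplicated data; report posterior
  intervals, not just the mean, when that regime matters.
- The residual-correlation spatial model inverts a dense `n x n` matrix;
  it is intended for trials up to a few thousand plots.
- The Yield|ACC model fits one covariate slope; genotype-specific
  responses to canopy are out of scope.
- Image analysis assumes weed-free plots (as the underlying trials were
  maintained); green weeds would be counted as canopy.
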