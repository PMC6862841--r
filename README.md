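# canopysel

Image-based selection experiments for early-generation soybean breeding.

In the first stage of a line-breeding program (progeny rows, PR), thousands
of candidate lines are grown in single, unreplicated one-row plots, and the
yield measured there is a poor guide for selection. Canopy coverage
extracted from aerial RGB imagery is cheap to collect many times per
season, heritable, and genetically correlated with yield, which makes it a
candidate secondary trait: select on **average canopy coverage (ACC)**, or
on **yield adjusted for ACC (Yield|ACC)**, instead of (or alongside) yield
itself, and check in later replicated trials which selection route actually
delivered the better lines.

`canopysel` implements that whole experiment as reusable, tested R code,
plus a synthetic-data generator with pixel- and allele-level ground truth
so every stage can be validated without any proprietary field data:

1. **Imaging** — per-plot canopy coverage from RGB images via the Excess
   Green index on chromaticity-normalized channels, `ExG = 2g − r − b`,
   thresholded by Otsu's between-class-variance criterion; per-date
   coverage is the median over replicate plot images, and ACC is the mean
   of the per-date medians.
2. **Pedigree** — the numerator relationship matrix `A` by the tabular
   method, and its sparse inverse by Henderson's rules with inbreeding
   (selfing encoded as sire = dam).
3. **Animal model** — single-trait pedigree BLUP by Gibbs sampling,
   `y = Xβ + Zg + e` with `g ~ N(0, A σ²ₐ)` and `e ~ N(0, R σ²ₑ)`, where
   `R` is an optional field-correlation matrix built from rook-neighbor
   plots; narrow-sense heritability is the posterior mean of
   `h² = σ²ₐ / (σ²ₐ + σ²ₑ)`. Yield|ACC adds the centered covariate as a
   fixed regression.
4. **Selection** — truncation selection on BLUP rankings per category
   with overlap accounting, an early/late maturity split against a check,
   selection intensity `i = φ(z_p)/p`, and the predicted response
   `ΔG = h² i σ_p / L`.
5. **Trials** — multi-location alpha-lattice evaluation by REML
   (`y = μ + g + loc + rep(loc) + block(rep) + g×loc + e`), adjusted
   genotype means `μ + gᵢ` (optionally adjusted for maturity R8), Welch
   t-tests comparing the selection categories, and attribution of
   top-ranked advanced-trial lines to the PR category that found them.

## Worked example

```r
library(canopysel)

ped  <- simulate_pedigree(n_founders = 20, n_crosses = 300,
                          selfing_generations = 3, seed = 11)
arch <- genetic_architecture()          # yield / ACC / R8 defaults
bv   <- simulate_breeding_values(ped, arch, seed = 12)
lay  <- field_layout(attr(ped, "line_ids"),
                     check_ids = c("FND0001", "FND0002"),
                     n_cols = 20, check_spacing = 15)
pr   <- simulate_trial(lay, bv, arch, spatial_sd = c(120, 0.005, 0.5),
                       seed = 13)

img  <- simulate_plot_image(0.35, seed = 14)   # one 35%-cover plot image
coverage_from_image(img)
#> estimated cover: 0.35 | true mask fraction: 0.35

fit  <- animal_model(yield ~ 1, pr, a_inverse(ped),
                     niter = 3000, burnin = 600, seed = 15)
fit
#> Animal model (Gibbs): yield
#>   340 plots, 302 phenotyped lines; chain 3000/600/5
#>   sigma_a2 = 1.424e+05  sigma_e2 = 2.648e+05  h2 = 0.354

sel <- select_top(blup(fit)[attr(ped, "line_ids")], fraction = 0.09)
length(sel)
#> 27
predicted_gain(h2 = heritability(fit), fraction = 0.09,
               sigma_p = sd(pr$yield))
#> Predicted response: dG = h2 * i * sigma_p / L = 449 (i = 1.804, p = 0.09)
```

The estimated coverage equals the ground-truth mask fraction because the
generator stores the exact canopy mask for every rendered image; the
animal model then recovers heritability and ranks lines for selection.
`run_selection_experiment()` chains all five stages (imaging through
advanced-trial attribution) from a single YAML-configurable scenario and
writes every stage's output tables; reruns with the same config and seed
are byte-identical. A thin CLI wrapper lives in `inst/scripts/canopysel.R`.

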