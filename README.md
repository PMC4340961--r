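# skerrydiv

Grid-based analysis of coastal breeding-bird diversity along archipelago
gradients, for community ecologists and conservation planners working
with presence/absence survey grids.

In post-glacial archipelagos, land uplift sorts islands by size: large,
forested islands near the mainland, bare skerries towards the open sea.
`skerrydiv` asks how the species richness (α) and community composition
(β) of *specialist* (obligate coastal) and *generalist* (facultative
coastal) breeding birds respond to four per-square gradients — distance
to open sea, archipelago width, shoreline length and land area — on a
1 km² grid, and ships a synthetic archipelago generator that stands in
for survey and GIS data.

## The statistics at its core

* **α diversity** — per-square richness by group, modelled as

  ln(S + 1) = β₀ + Σₖ βₖ zₖ + Σ_{k<l} β_{kl} zₖ z_l + ε,
  Cov(εᵢ, εⱼ) = σ² [(1 − ν)·exp(−d_ij/ρ) + ν·1(i = j)],

  with mean-standardised covariates zₖ, all two-way interactions (the
  generalist model drops land_area × width), and an exponential spatial
  error with range ρ and nugget ν chosen by profile maximum likelihood.
  Residual autocorrelation is screened with Moran's I (binary weights,
  1000 m lag, normality-assumption test), covariate collinearity with
  the |r| < 0.7 rule.

* **β diversity** — pairwise Sørensen dissimilarity
  β_S = 1 − 2w/(a + b), and the null-model Raup–Crick dissimilarity
  β_RC = P(w_null > w_obs) + ½·P(w_null = w_obs), where the null draws
  assemble both squares at their observed richness by occupancy-weighted
  sampling without replacement from the regional pool (with an exact
  enumeration oracle for small pools). Composition–environment
  association is tested by partial Mantel tests on Manhattan covariate
  distances (method of residuals, 10,000 permutations by default,
  two-sided p with the +1 correction).

## Worked example

```r
library(skerrydiv)

ds  <- generate_survey(
  landscape_params(nx = 10, ny = 40, n_islands = 240, seed = 20260928),
  simulation_params(seed = 20260929))
dsf <- apply_inclusion_rules(ds)$dataset   # >= 25 m shoreline, land + water
rt  <- richness(dsf)

fit <- fit_spatial_gls(rt, dsf$grid, model_spec("specialist"))
fit$coefficients[fit$coefficients$term == "dist_sea", ]
#>       term   estimate        se       lo95       hi95
#> 2 dist_sea -0.6659685 0.1310917 -0.9229082 -0.4090289
```

The negative `dist_sea` coefficient says specialist richness *rises*
towards the open sea (the covariate is distance to open sea, on the
standardized scale): one standard deviation further from the sea costs
about exp(0.67) ≈ 2-fold in S + 1, all else equal. The matching
generalist fit gives a positive coefficient — the published opposing
pattern the simulator encodes.

```r
beta <- sorensen_matrix(dsf, "specialist")
env  <- manhattan_matrix(standardise(dsf$grid$land_area), dsf$grid$square_id)
ctrl <- lapply(c("dist_sea", "shoreline", "width"), function(v)
  manhattan_matrix(standardise(dsf$grid[[v]]), dsf$grid$square_id))
partial_mantel(beta, env, ctrl, n_perm = 9999, seed = 1)
#> partial Mantel: r = 0.5902, p = 0.0001 (9999 permutations)
```

Squares that differ more in land area also host more dissimilar
specialist communities, after controlling for the other three
gradients.

The numbered scripts under `analysis/` run the full study shape —
`01_simulate.R` through `05_report.R` (simulation, α summaries, spatial
regressions, β/Mantel tables, markdown report) — writing their outputs
under `results/`.

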