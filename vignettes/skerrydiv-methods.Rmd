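---
title: "Methods: archipelago gradients, richness models and null-model beta diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archipelago gradients, richness models and null-model beta diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Coastal breeding birds in post-glacial archipelagos sort along strong
physical gradients: land uplift makes islands large and forested near
the mainland and leaves small, bare skerries towards the open sea.
`skerrydiv` implements a grid-based analysis of how the species richness
(alpha diversity) and community composition (beta diversity) of two
ecological groups — *specialists* (obligate coastal breeders) and
*generalists* (species that also breed in inland wetlands) — respond to
four per-square covariates measured on a 1 km² grid:

* `dist_sea` — Euclidean distance from the square midpoint to the open
  sea (m),
* `width` — archipelago width: `dist_sea` plus the distance from the
  midpoint to the nearest mainland (m),
* `shoreline` — total shoreline length inside the square (m),
* `land_area` — land surface inside the square (m², at most 10⁶).

Because no survey of this kind ships with the package, a synthetic
archipelago generator stands in for the field data. Its defaults encode
the study conditions the analysis was designed for: a 48-species
community (19 specialists, 29 generalists, 14 red-listed, seven per
group) whose occupancy responds to the gradients with the published
sign pattern — specialist richness falls with `dist_sea` and
`land_area` and rises with `shoreline` and `width`; generalists respond
oppositely to `dist_sea` and `width`; the positive shoreline effect is
damped by land area (a negative `shoreline × land_area` interaction).

## Square inclusion and record reassignment

A square enters the analysis only if it has at least 25 m of shoreline
(inclusive: "minimum" names the smallest admissible value) and contains
both land and water, operationalised as `0 < land_area < 10⁶ m²`
because no separate water field exists. Bird records from excluded
squares are not discarded: each species present in an excluded square
is marked present in the retained square with the nearest centroid
(Euclidean distance, ties broken by the lexicographically smallest
square id for determinism). Merging is a set union — the data are
presence/absence, so there is nothing to add up. Reassignment applies
pure nearest-centroid matching; it does not ask whether the target
square offers suitable habitat, because the inclusion rules carry no
habitat information beyond shoreline and land area.

## The synthetic archipelago

`generate_landscape()` rasterises a coastal strip (default 10 × 40 km
at 50 m cells; 1000 must be divisible by the cell size) with

* a western mainland belt whose eastward extent follows a smoothed
  random walk (`roughness`, default SD 150 m),
* islands whose expected radius decays exponentially with distance
  from the mainland coast (`radius = base · exp(−decay · d)`, defaults
  300 m and 3·10⁻⁴ per m), reproducing the land-uplift size gradient;
  every island is at least one cell — a bare skerry.

`derive_environment()` then measures the four covariates per square:

* `land_area` = land-cell count × cell area;
* `shoreline` = land/water 4-neighbour cell-edge count × cell size, each
  edge attributed to the land cell's square. This raster estimator is
  deterministic and resolution-controlled; it underestimates true
  geometric shoreline length, which is acceptable here because only
  relative gradients enter the analysis. Beyond the western raster edge
  the mainland continues and the coast is mirrored north–south, so the
  raster boundary contributes no phantom shoreline; open water lies
  east.
* the open-sea boundary is the per-row easternmost land cell offset
  150 m seaward, with its north–south slope limited to 45° so the line
  wraps around the outermost islands instead of dipping into gaps
  between them. `dist_sea` is the distance from the square midpoint to
  that line (0 beyond it). Alternative hull constructions would shift
  `dist_sea` by a bounded constant without changing its ordering.
* `width` = `dist_sea` + distance to the nearest mainland cell.

`simulate_occurrences()` draws per-species logit-scale coefficient
profiles around the group means (between-species SD 0.25 for gradient
coefficients, 0.7 for intercepts so commonness varies), computes
occurrence probabilities from the *standardized* covariates plus the
shoreline × land-area product, optionally adds a spatially
autocorrelated Gaussian logit field with exponential correlation
(disabled by default; its `amplitude`/`range` knobs create the residual
autocorrelation that Moran's I is meant to detect), and samples
independent Bernoulli presences. The true profiles are returned for
parameter-recovery checks. With the default 19 + 29 species the
community borrows the bundled survey's species names and red-list
statuses, so red-list summaries exercise realistic tallies.

What the generator does *not* emulate: detectability and observer
error, vegetation and predator covariates, abundances, and real
cartography. The default intercept (−0.8 on the logit scale) also makes
the synthetic community more saturated than a field survey — baseline
occupancy near 30% against the ~13% mean occupancy typical of coastal
surveys — a deliberate choice that gives desk-scale runs of a few
hundred squares enough per-square richness for the beta-diversity and
regression machinery to be exercised away from their sparse-data edge
cases. Tests passing on synthetic data therefore demonstrate the
correctness of the statistical machinery under the stated model, not
the field validity of any ecological conclusion.

## Alpha diversity

`richness()` counts species per square for the six groups (total,
specialist, generalist, and their red-listed subsets; the group pairs
are additive partitions and are tested as such). `occupancy_table()`
reports per-species occupancy counts and percentages rounded to one
decimal. `standardise()` implements "mean-standardised" as a z-score
(centre and scale): the gradient-profile axes of the analysis show
values of order ±0.25, which centring alone could not produce for
covariates whose raw ranges are metres; a centre-only mode
(`scale = FALSE`) is available. `bin_by_gradient()` groups squares into
half-open bins `[c − 0.25, c + 0.25)` centred at multiples of 0.5 of
the standardized covariate, ties going to the upper bin so the bins
partition the squares.

## Beta diversity

Sorensen dissimilarity is `β_S = 1 − 2w/(a + b)` with `a`, `b` the
species counts of the two squares and `w` the shared count. Pairs of
two empty squares are undefined and recorded `NA`; they are dropped
listwise from all matrices before Mantel vectorisation.

The Raup-Crick dissimilarity `β_RC` asks how surprising the observed
sharing is given the two squares' richness: each null draw assembles
the two squares by sequential weighted sampling without replacement
(draw, remove, renormalise) from the regional pool, with species
weighted by their empirical occupancy; the statistic is
`P(w_null > w_obs) + ½·P(w_null = w_obs)`. The half-weight tie rule
keeps the null expectation at 0.5, and high values mean fewer shared
species than richness alone predicts. Design choices made where the
protocol leaves room:

* the probability scale `[0, 1]` is the default; the affine rescale to
  `[−1, 1]` is available via `raup_crick_config(rescale_minus1_1 =)`.
* pool weights are group-specific (the pool of an analysis of
  specialists is the specialist species), via `pool_weights(ds, group)`;
  an all-species pool is one keyword away.
* the default 999 draws per richness pair is common null-model
  practice; the exact enumeration oracle `raup_crick_exact()` (which
  sums sequential-draw probabilities over all ordered outcomes of small
  pools) guards the Monte-Carlo implementation in the tests.
* the null distribution depends only on the richness pair `(n1, n2)`
  given fixed weights, so `raup_crick_matrix()` simulates it once per
  unique pair and reuses it — cost grows with the number of distinct
  richness pairs, not with the number of square pairs, which is what
  makes thousands of squares feasible. Each pair's stream is seeded by
  the richness-pair key so enumeration order is irrelevant.

## Mantel tests

Environmental distances are Manhattan (absolute differences of the
covariate). The simple Mantel statistic is the Pearson correlation of
the strictly-upper-triangle vectors; the partial test uses the method
of residuals: both the composition matrix and the focal covariate
matrix are residualised (OLS with intercept) on the control matrices'
triangle vectors, and `r` is the correlation of the residuals.
Inference jointly permutes rows and columns of the raw composition
matrix, re-residualises, and applies the `(exceedances + 1)/(n_perm +
1)` rule. P-values are two-sided on `|r|` by default — both negative
and positive correlations are interpreted as signal — with a one-sided
option. Pairs flagged `NA` are dropped listwise; if a permutation moves
an `NA` into the kept set, that permutation is re-restricted on the
fly.

## Spatial statistics and the gradient regression

`morans_i()` is the classical statistic with binary weights at an
inclusive 1000 m lag (rook neighbours on the 1 km grid), expectation
`−1/(n − 1)`, and the normality-assumption variance via S0/S1/S2. It is
computed on the residuals of the preliminary *non-spatial* fit (the
pure-nugget model), since the question is whether autocorrelation
remains after the covariates.

The gradient regression is a Gaussian model of `ln(richness + 1)` (the
natural log; some squares hold zero species) on the four standardized
covariates and their two-way interactions; the generalist model drops
`land_area × width`, mirroring the convergence behaviour of the
original hierarchical fit. The error covariance is
`σ²[(1 − ν)·exp(−d/ρ) + ν·1(i = j)]`: an exponential spatial
correlation with range `ρ` plus a nugget proportion `ν` that plays the
role of the square-identity random effect in the quasi-likelihood
formulation this model replaces — with one observation per square the
two are the same estimand, and an exact-likelihood GLS is simpler and
better behaved at desk scale. `(ρ, ν)` are chosen by profile maximum
likelihood on a 25-point log-spaced `ρ` grid spanning 0.1–50 km
(bracketing the 1 km square scale through the study-extent analogue)
crossed with `ν ∈ {0, 0.25, 0.5, 0.75, 1}`, refined by golden-section
in each coordinate (the grid point is kept if refinement does not
improve the likelihood, so the OLS submodel `ν = 1` is never beaten by
numerical accident). `β` and `σ²` are closed-form at each candidate via
Cholesky factorisation; fixing `ν = 1` reduces the fit to OLS exactly,
and both `ρ` and `ν` can be pinned for closed-form checks. Wald 95%
intervals are `±1.96·SE` with the residual variance on `n − p` degrees
of freedom (the profile likelihood itself uses the ML divisor `n`).

The collinearity screen reports all six pairwise Pearson correlations
of the covariates and flags `|r| ≥ 0.7`, the conventional threshold
below which gradient regressions are not considered collinearity-
impaired.

## The pipeline and determinism

`run_pipeline()` chains the stages — inclusion rules and reassignment,
richness and occupancy, collinearity screen, spatial fits with residual
Moran's I, beta matrices, and a partial Mantel test per (index ×
covariate × group) with the other three covariates controlled — and is
fully deterministic under one master seed: every random stage derives
its own seed from the master seed *keyed by stage name*, so reordering
stages cannot silently shift another stage's stream. Default problem
sizes are desk scale (a few hundred squares, 999 null draws, and the
analysis scripts use 9999 Mantel permutations against the package
default of 10000-permutation significance at p < 0.05); the
richness-pair cache and the O(unique pairs) design keep the full
4646-square scale supported.

Problem sizes used by the shipped checks, chosen as representative desk
scale: the regression recovery study uses 200 replicates of 400 squares
with main effects ±0.3, σ = 0.3, range 3000 m and nugget 0.3 (the
recovery protocol states no truth nugget; 0.3 leaves two thirds of the
residual variance spatially structured, a clearly spatial regime);
Raup-Crick correctness uses 50,000 draws against exact enumeration on a
five-species unequal-weight pool, and calibration uses 2000 null pairs;
Mantel size uses 500 null datasets of 15 squares at 199 permutations.

## Known limitations

* The raster shoreline estimator is biased low relative to vector
  shorelines; only relative gradients matter downstream.
* The open-sea boundary is a per-row envelope at raster precision, not
  a geometric hull.
* Wald intervals with an estimated `(ρ, ν)` are mildly optimistic; the
  recovery study's ≥90% coverage criterion accounts for that.
* `β_RC` inherits the usual null-model caveat: it conditions on
  observed richness and occupancy, so it cannot detect structure those
  margins already absorb.
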