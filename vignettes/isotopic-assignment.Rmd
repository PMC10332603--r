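---
title: "Isoscape calibration and probabilistic assignment of origin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoscape calibration and probabilistic assignment of origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isorigin)
```

## The problem

Migratory birds cannot tell us where they grew their feathers, but their
feathers can. Hydrogen isotope ratios in precipitation (δ²Hₚ) vary
predictably across continents, and because feathers are metabolically inert
after growth, the non-exchangeable hydrogen in a feather (δ²H_f) preserves
the isotopic signal of the food web where it was grown. Given a gridded
prediction of δ²Hₚ (an *isoscape*) and a *calibration* (transfer function)
linking δ²Hₚ to δ²H_f for the taxon at hand, a single feather measurement
can be converted into a map of how likely each grid cell is to be the
individual's moult or natal origin. This package implements that workflow:
calibration on known-origin individuals, likelihood-based assignment with
propagated error, odds-ratio regions of likely origin, and split-half
cross-validation of the whole chain. It is aimed at waterfowl-style
applications (multi-species datasets pooled by foraging guild, continental
masks) but contains nothing waterfowl-specific.

## The model

**Calibration.** For known-origin birds at sites with isoscape value
δ²Hₚ(s), we fit ordinary least squares

  δ²H_f = a + b·δ²Hₚ + ε,  ε ~ N(0, σ²)

The residual scatter is summarized by `sd_resid`, the sample standard
deviation of the residuals (divisor n−1). `sd_resid` absorbs measurement
error, intra- and inter-individual variability, and local hydrology the
isoscape cannot see; it is the tissue-level error term carried into
assignment. We report adjusted r² as the fit statistic. Before fitting,
records are screened per *site* with Tukey fences: values outside
[Q1 − 1.5·IQR, Q3 + 1.5·IQR] of their site's δ²H_f distribution are removed
in a single pass (fences computed once on the full site, type-7
linear-interpolation quantiles). Wholesale exclusion of a known-bad site
(e.g. one with strong evaporative enrichment) is a separate mechanism,
`exclude_sites`, not the fence rule. Age effects are deliberately not
modeled: feathers of juveniles and adults differ by a few permil, but that
difference is small relative to `sd_resid` and known-origin archives rarely
carry reliable age data.

**Assignment.** The isoscape is converted to feather space,
μ_c = a + b·δ²Hₚ(c), and each cell receives the normal density

  f(y | c) = (1 / (σ_c √(2π))) · exp(−(y − μ_c)² / (2σ_c²))

where y is the measured feather value and σ_c combines calibration and
isoscape error in quadrature: σ_c = √(sd_resid² + (b·σ_iso(c))²). The
isoscape SD is scaled by |b| because the calibration maps precipitation
space into feather space; an isoscape published without an uncertainty grid
contributes zero, collapsing σ_c to the calibration error (both behaviours
are available via `scale_by_slope` and `unc = NULL`). Densities are
normalized over the working domain — cells that are non-nodata and inside
every mask (continent of sampling, optional species range) — to a
probability-of-origin surface summing to 1.

**Odds-ratio region.** The binary "likely origin" region at odds 2:1 is the
smallest set of highest-probability cells whose cumulative probability
reaches 2/3. Ties are broken by row-major cell index — a stable, documented
rule that avoids including an entire plateau of tied cells on flat
surfaces. The region is minimal by construction: dropping its
smallest-probability cell falls below the threshold.

**Cross-validation.** Calibration quality is evaluated by repeated
split-half cross-validation: per iteration, a random half of the records
refits the calibration, every held-out bird is assigned, and we score

* *accuracy* — fraction of held-out birds whose true sampling cell falls
  inside their region (expected ≈ the odds fraction, 0.66 for 2:1, when the
  error model is honest);
* *precision* — region cells / domain cells (smaller = sharper);
* *minimum distance* — for inaccurate birds only, the great-circle distance
  (haversine, R = 6371 km) from the sampling point to the nearest region
  cell. An all-birds variant (zeros included) is available behind
  `min_dist_all_birds`; the inaccurate-only mean is the default because a
  distance of zero is not an error magnitude, it is the absence of one.

Iterations are seeded `base_seed + i`; a degenerate calibration half (all
δ²Hₚ equal, possible when few sites exist) is redrawn under a logged
replacement seed so the iteration count stays fixed. Held-out birds whose
sampling point falls on a masked or nodata working cell are dropped with a
logged id rather than counted inaccurate — non-overlap is missingness, not
failure.

## Grids without a GIS stack

All computation happens in geographic lon/lat on north-up, cell-center
registered rasters. The package deliberately carries its own minimal raster
container (`geo_grid`) and a self-contained plain-text grid format instead
of depending on a GIS stack, which keeps the full workflow testable from
code alone. The geometric operations an isoscape workflow needs are
provided: tile mosaicking on a shared lattice, bilinear resampling (used to
degrade high-resolution grids to a workable cell size), extent/polygon/grid
masks (GeoJSON polygons supported, even-odd rule), and nearest-cell point
extraction. Conventions worth knowing:

* cell footprints are half-open, `[W, E) × (S, N]`, so every point —
  including points on shared edges — has exactly one owning cell;
* bilinear resampling emits nodata whenever a contributing source center is
  nodata (no partial-weight renormalization) — conservative at coastlines,
  at the cost of a one-cell nodata fringe;
* longitudes live in [−180, 180); there is no antimeridian wrap-around,
  which the target use cases (the Americas, Europe) never need;
* map projections are out of scope — published assignment maps reprojected
  for display are a cartography concern, not an analysis one.

## The synthetic world

Real isoscapes and known-origin feather archives are large downloads, so
the package generates both, with the statistical structure the analysis
assumes, under explicit seeds.

The synthetic isoscape is a linear north–south gradient in cell-center
latitude plus optional iid Gaussian noise smoothed by a box filter, with a
constant or latitude-linear 1-SD uncertainty surface. Defaults state the
reference world used throughout the tests: 100×100 cells of 0.5°
(latitudes 10–60 N, a continental window), gradient −160 ‰ in the north to
−20 ‰ in the south, 6 ‰ noise smoothed over a 2-cell radius, 8 ‰
uncertainty — magnitudes in line with published continental δ²Hₚ surfaces
and their SD grids.

Cohorts are site-clustered: sites are drawn uniformly (without replacement)
over non-nodata cells — *not* area-weighted by latitude, so high-latitude
rows are very slightly over-represented per km²; the simplification is
accepted and documented. Each bird's value is
a\* + b\*·δ²Hₚ(site) + site_effect + N(0, residual_sd), with defaults
a\* = −69.9 ‰, b\* = 0.7 (a published combined-dabbler transfer function)
and residual_sd = 15 ‰, inside the 10–22 ‰ range reported for waterfowl
datasets. A configurable fraction of birds receives a one-sided positive
contamination shift (+60 ‰ by default), mimicking evaporatively enriched
sites; the generator records which birds were contaminated, so truth-based
checks read the bookkeeping instead of re-deriving it.

What a green test on this world establishes: the estimator recovers the
generative calibration, the error propagation is honest (coverage at the
odds fraction), and the whole pipeline is deterministic under seeds. What
it does not establish: anything about real hydrology — snowmelt mixing,
evapotranspiration gradients, interpolation artifacts in real isoscapes, or
taxon-specific discrimination. Those require real known-origin data.

## Numerical choices and edge cases

* Probability surfaces renormalize in the log domain if every cell's
  density underflows (a feather value absurdly far from the domain).
* `sd_resid` uses divisor n−1 (a residual *standard deviation*) rather than
  the regression standard error with n−2; at calibration sample sizes in
  the hundreds the difference is < 0.1 ‰. The choice follows the field's
  naming; the alternative is a one-line change.
* Sites of 1–3 records get fences from their own quantiles; a single-valued
  site has IQR 0 and can never flag itself.
* Tile mosaics require agreement within 1e−6 on overlaps; lattice offsets
  beyond 1e−6 of a cell are an error, not a snap.
* Odds fraction 1 includes *all* domain cells by definition, bypassing the
  1e−12 cumulative-sum guard used for smaller fractions.
* Region centroids are computed on the unit sphere (3-D mean, renormalized)
  — the centroid of an arc of a parallel therefore sits very slightly
  poleward of it, which is the geodesically honest answer.

## Open choices made here

* Whether the reported r² of published calibration tables is multiple or
  adjusted r² is ambiguous in the field's summaries; this package computes
  adjusted r², matching the stated methods of the work it follows.
* Records that fail to overlap *any* configured isoscape are excluded from
  all pairings (global exclusion), before outlier flagging, so every
  dataset × isoscape calibration sees the same record set.
* Whether the isoscape SD should be slope-scaled before entering σ_c is not
  settled in the literature; quadrature with slope scaling is the default
  on unit-consistency grounds, with the unscaled variant behind a flag.

## A worked run

```{r, eval = FALSE}
world <- world_config(seed = 1)
iso <- make_synthetic_isoscape(world)
records <- simulate_known_origin(cohort_config(seed = 2), iso$mean)

pairs <- pair_with_isoscape(records, iso$mean)
model <- fit_calibration(pairs)

feather <- predict_feather_isoscape(iso$mean, model)
sigma <- combined_sigma(model, geometry = iso$mean$geometry)
surf <- probability_surface(records$d2h_f[1], feather, sigma,
                            id = records$id[1])
region <- odds_region(surf, "2:1")

cv <- cross_validate(records, iso$mean, iterations = 25, base_seed = 3)
attr(cv, "grand")$mean_accuracy
```

The same pipeline is scriptable end to end through `run_pipeline()` /
`inst/cli/isorigin.R` with flat key = value configs; every run writes its
resolved configuration and a log of seeds and exclusions next to its
outputs.

## Known limitations

Uniform site sampling (no area weighting); no mixed-effects calibrations
(species or year random effects); no continuous odds-level validation
curves (a single conservative odds ratio is scored instead); no abundance
priors or band-recovery integration on the assignment surfaces; no
antimeridian support; GeoTIFF I/O is not built in — convert external
isoscapes to the text grid format (any GIS or scripting stack can) before
loading.
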