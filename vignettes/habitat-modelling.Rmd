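---
title: "Landscape habitat modelling with pantherscape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape habitat modelling with pantherscape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantherscape)
```

## The modelling problem

`pantherscape` estimates, for every 1-km² cell of a study landscape, the
probability *P* that resident breeding Florida panthers use the cell. The
design is presence–absence: a cell is labelled *present* when at least one
filtered telemetry fix falls inside it, and *absent* otherwise. This
treats non-detections as true absences, which is defensible only under
intensive, long-duration monitoring of a population whose overlapping
home ranges blanket the occupied area; the synthetic generator emulates
exactly that regime, and users applying the package to sparser telemetry
should treat absences as pseudo-absences and interpret *P* accordingly.

The classifier is a random forest (500 classification trees, 3 variables
tried per split) over 15 covariates: ten land-cover fractions, forest
edge, wet- and dry-season water depth, human population density, and road
density. A forest rather than a parametric model because the responses
are non-linear and interacting (the depth response is peaked, the human
density response saturating), and because prediction, not inference, is
the goal. The tree inducer is delegated to the `randomForest` package;
everything around it — out-of-bag bookkeeping, thresholding, accuracy
metrics, cross validation, permutation importance — is implemented here
and tested against brute-force oracles.

## The covariates

**Cover fractions.** Cover polygons carry raw class codes mapped through
a total many-to-10 category map (unmapped codes are rejected at load).
The fraction of cell *c* in category *k* is area(c ∩ polygons of k) /
1 km². Fractions are stored in `[0, 1]`; percent formatting is an output
concern.

**Forest edge** (km per cell) is the length of shared boundary between a
forest polygon (upland or wetland forest) and an edge-forming polygon
(grassland, open fresh water, upland shrub, wet shrub, open freshwater
wetland), plus upland-forest/wetland-forest contacts. Urban, agriculture,
and saltwater wetland never form edge, and boundaries between two
polygons of the same category never count. The quantity is a prey
(white-tailed deer) availability proxy: deer are an edge species, and
forest edges provide the structure pumas hunt from.

**Seasonal water depths.** Depth = interpolated stage − ground elevation,
positive above ground. Daily stages are interpolated by inverse-distance
weighting (power 2, exact at stations, stations missing a day are
dropped for that day, no gap-filling); depths are sampled at a 3×3
subgrid per cell and averaged over all in-season days. The wet season is
June–October, the dry season November–May; a dry season spans the year
boundary and is labelled by its ending year, and the averaging period
clips partial seasons. The interpolator is deliberately pluggable (power
and sample density are arguments): IDW was chosen because it is
deterministic, exact at data points, and needs no covariance fitting,
not because it is uniquely correct.

**Human density** is the area-weighted census-block density; **road
density** the clipped length of roads per cell, excluding four-wheel
drive tracks, bike trails, and pedestrian trails, which do not represent
meaningful disturbance.

## Grid conventions and geometry

Cells are half-open axis-aligned squares. Points and segments falling
exactly on a shared cell boundary are assigned to the cell with the
smaller (column, row) index — a deterministic tie-break that counts every
quantity exactly once and makes per-cell totals add up to layer totals
(tested to 1e-6). Cell membership in the study area, in home ranges, and
in zones is decided by the cell center, so cell counts approximate
polygon areas in km².

The package implements its own planar geometry: shoelace areas,
Sutherland–Hodgman polygon-vs-rectangle clipping (exact in area for
simple rings, holes subtracted), Liang–Barsky segment clipping,
ray-casting point-in-polygon with explicit boundary handling, and
collinear shared-boundary extraction for edge measurement. All of it is
validated against 10⁵-point Monte-Carlo oracles and hand-computable
layouts in the test suite. Layers are read and written as GeoJSON,
rasters as ESRI ASCII grids — plain-text formats without further
dependencies.

## Threshold, validation, importance

The habitat threshold t\* minimizes |sensitivity − specificity| over the
sorted unique predicted probabilities, with ties broken toward the
smaller threshold (favouring sensitivity). Such a cutoff approximates the
observed prevalence on well-separated data. t\* is derived from
out-of-bag probabilities: resubstitution probabilities are
near-degenerate for a forest (most training rows are predicted almost
perfectly), which would push the threshold to an uninformative extreme.

Ten-fold cross validation partitions the cells into seeded near-equal
folds; each fold is predicted by a forest trained on the rest, so every
cell is predicted exactly once. The threshold is re-derived inside each
training set to avoid leakage; pooled held-out metrics use the per-fold
thresholds, and a pooled threshold is also reported. Folds whose training
part loses a class are redrawn (seeded, logged).

Permutation importance is the mean loss in out-of-bag accuracy over
seeded permutations of one covariate at a time, evaluated with
out-of-bag rows and majority votes only over the trees that did not see
the row; Gini importance is the forest's mean impurity decrease. Both
are standardized so the top variable scores 1, and variables are ranked
by the sum of the two standardized scores. Both water-depth covariates
stay in the model despite their near-collinearity (R² ≈ 0.98 between
seasons): dropping one measurably costs accuracy, and a forest is not
harmed by collinear predictors the way a parametric model is.

## Stratified sensitivity analysis

Classical one-at-a-time partial dependence fixes the other covariates at
medians, but no real cell has all covariates at their central tendency
simultaneously: in good habitat the beneficial covariates run high and
the detrimental ones low. The analysis is therefore stratified: cells
are grouped by predicted *P* into excellent (0.85–0.95), medium
(0.45–0.55), and poor (0.05–0.15) strata (closed bounds), covariate
means are computed within each stratum, and each covariate is swept over
its observed range (50 equally spaced points, not extrapolated) with the
other covariates pinned at the stratum means. The per-curve summary
reports ΔP, the direction of the trend, the location of the maximum, and
the stratum of maximal effect. Two caveats are inherent to the design:
swept cover fractions are not renormalized against their sibling
fractions, so sweep rows can be compositionally impossible; and strata
can be empty when the model's probability range is narrow (all three
empty is an error).

## The synthetic landscape and what it does (not) show

The generator builds a 60-km square landscape of 1-km² cells at the
study system's real composition: about a third open freshwater wetland,
with wetland forest, agriculture, saltwater wetland along one edge, an
urban corner, and the remaining categories at realistic fractions. Cover
is synthesized by seeded Voronoi agglomeration on a 250-m subgrid (patch
scale ≈ 3 km²) with a greedy patch-reassignment pass that brings realized
fractions within 2 percentage points of target. Elevation is a smooth
corner-gradient-plus-undulation surface scaled so that true mean depths
span about −5.2 to +2.6 m; stages at 12 gauges (two outside the extent,
buffering edge effects) carry a 0.3-m wet-season offset and 5-cm daily
noise. Census density decays from the urban corner (peak ≈ 8000
people/km²); roads combine highways crossing the interior, a dense urban
grid, and excluded-class trails.

Utilization follows a logistic model on standardized covariates,
`w = plogis(-3.5 + 4.5 Wet_For + 4.5 For_Edge - 5 Pop_Dens - 4 Ag -
3 Rd_Dens - 1.5 (dry_depth + 0.6)²)` (the depth term on raw meters),
with grassland and upland shrub as designed null covariates (effect
exactly zero) for importance-recovery tests. Twenty animals receive
home-range centers drawn proportional to `w` and 330 fixes each, drawn
independently proportional to `w` within an 18-km movement radius —
independent weighted sampling, not a correlated walk, because presence
labelling at the 1-km cell scale is insensitive to path autocorrelation.
The effect magnitudes were calibrated once, at design time, so that the
planted signal is as strong as the real system's (the monitored
population's out-of-bag discrimination reaches AUC ≈ 0.95); presence
labels remain stochastic functions of `w`, so recovery tests exercise a
noisy, not a rigged, target.

What passing tests show: the pipeline recovers planted effect signs, the
depth optimum to within ±0.5 m, ranks designed nulls below planted
drivers across seeds, and reproduces the resubstitution ≫ out-of-bag ≈
cross-validation accuracy pattern. What they do not show: performance
under telemetry bias (habitat-dependent detectability), under
pseudo-absence contamination, with autocorrelated movement, or with the
topological messiness of real GIS layers (slivers, gaps, invalid rings) —
the generator's tessellations are exact.

## Numerical choices and degenerate inputs

- Random-forest, fold, and permutation randomness all derive from one
  integer seed; identical configurations reproduce identical outputs.
- Threshold candidates are data values only; `which.min` takes the first
  (smallest) candidate on ties.
- Wilcoxon rank-sum comparisons of home-range mean *P* between sexes use
  the exact distribution when the combined sample is ≤ 20 and untied,
  else the tie-corrected normal approximation without continuity
  correction; identical groups return p = 1.
- Overlapping cover polygons of different categories are an error
  ("ambiguous boundary"), as are overlapping zones; unmapped cover codes
  are rejected; elevation nodata under a cell yields a flagged missing
  depth, never a silent zero; animals whose home range contains no cell
  center are excluded from group medians with a warning.
- Age at fix uses continuous years (365.25 d) — the stricter reading of
  a "≥ 3 years old" filter, applied at fix time rather than at capture.
- Habitat classification uses P ≥ t\* by default; strict inequality is
  available and differs only for cells exactly at the threshold.

## Problem sizes

The shipped tests and the acceptance script run the default 60×60-km
landscape (3600 cells, 20 animals, 6600 fixes) for recovery checks, a
20×20-km landscape for smoke tests, and 10⁵-point Monte-Carlo oracles
for geometry; the multi-seed importance-recovery check uses 10
landscape replicates with 3 permutations per variable. These sizes were
chosen to give stable statistics while keeping a full run in minutes on
one core; all of them scale through `synthetic_config()`.

## Known limitations

- The MCP home range is the field's convention for this analysis but is
  area-inflating for irregular ranges; kernel estimators are out of
  scope.
- IDW stage interpolation ignores hydrologic barriers (levees, canals)
  that structure real water surfaces.
- The sensitivity design quantifies local, conditional responses; it is
  not a causal decomposition, and correlated covariates (the two depth
  variables; population and roads) share their signal.
- Zone and ownership accounting assume exhaustive, disjoint zone
  polygons; partial cells are attributed by center.
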