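---
title: "Delineating significant concentrations of benthic indicator taxa from trawl-survey biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating significant concentrations of benthic indicator taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmekde)
```

## The problem

Bottom-trawl research surveys record, for every trawl set, a start position
and the catch weight of each benthic taxon. For structure-forming taxa --
large sponges, sea pens, small and large gorgonian corals -- conservation
practice distinguishes the *significant concentrations* that form habitat
(sponge grounds, sea pen fields, coral forests; candidate vulnerable marine
ecosystems, VMEs) from the diffuse tail of the species' distribution. A
single catch, or the full range of a taxon, is not a VME; a dense
aggregation is. `vmekde` turns that distinction into an explicit, auditable
computation on point-biomass records.

The workflow has four stages: survey harmonization, kernel density surface,
threshold-area curve, and threshold selection. A fifth component -- a
seeded synthetic scene generator -- exists so the whole chain can be
validated against known ground truth, because real survey series of this
kind are rarely redistributable.

## Harmonization: when are surveys combinable?

Surveys differ in gear and tow duration, which mostly affects *small*
catches (retention in different mesh liners, short vs. long tows); large
catches of aggregating taxa reflect the aggregation rather than the gear.
`harmonize_surveys()` therefore runs a *ladder* of two-sample
Kolmogorov-Smirnov tests: at each catch-weight level $t$ of an ascending
grid it compares the two groups restricted to $\{x \ge t\}$, first across
tow durations within the dominant gear, then pooled against the other
gear. The decision rule takes the lowest level that is non-significant
*and* has no significant level above it; the combinable threshold is the
larger of the duration and gear thresholds. Records below it are dropped
before density estimation.

Numerical choices, all exposed as arguments:

* `alpha = 0.05` per level, with *no* multiple-testing correction across
  ladder levels -- the ladder is a harmonization device, not a family of
  inferences, and correcting would bias it toward pooling. The decision
  note records this.
* p-values are exact for `min(n) <= 25` and asymptotic otherwise; survey
  comparisons involve hundreds of records, squarely the asymptotic regime.
  Restricted samples smaller than `min_n = 5` are reported but excluded
  from the decision.
* A level of 0 compares strictly positive catches: a zero is an absence,
  not a weight.
* When pooling would strand fewer than 10% of the positive records, the
  result recommends separate per-region models instead -- with few
  records a pooled surface is dominated by the search radius, not the
  data.

## The density surface

`kde()` places a quadratic (Epanechnikov-type) kernel over each
positive-catch position and sums them on a raster evaluated at cell
centers. The kernel profile is $(1-(d/h)^2)^2$ for $d < h$, exactly zero
beyond the search radius $h$, so each record influences a circular
neighbourhood. Defaults follow the conventional GIS kernel-density tool:
$h = \min(\mathrm{width},\mathrm{height})/30$ of the point extent and a
cell size of $\min(\mathrm{width},\mathrm{height})/250$. On a ~680 km-wide
continental-margin footprint that gives $h \approx 22.6$ km and ~2.7 km
cells.

Kernels are weighted by catch biomass -- the surface is a biomass surface,
and the area enclosed at a biomass level is the quantity the method
thresholds. Two scalings are provided:

* **peak** (default): each kernel's maximum equals its catch weight, so an
  isolated 7.3 kg catch peaks at 7.3 and surface values are directly
  comparable to catch-weight thresholds ("the 75 kg polygons");
* **density**: each kernel integrates to its catch weight (kg m$^{-2}$),
  so the surface integral recovers total biomass -- the scaling used by
  the mass-conservation checks.

The two differ by the exact scalar $\pi h^2/3$ cell-wise, so polygon
geometry at a given curve level is scaling-invariant. The raster is grown
by $h$ on every side (snapped outward to whole cells) so kernels are never
clipped; clipping would silently destroy mass and bias edge polygons.
Values are evaluated at cell centers, matching standard raster semantics.

## The threshold-area curve

`polygonize()` contours the superlevel set $\{v \ge t\}$ by marching
squares with linear interpolation on the cell-center grid, classifies
rings as boundaries or holes by even-odd nesting, and reports area in
km². `build_curve()` repeats this for a strictly decreasing threshold
sequence and tracks, per step:

* total area and the successive **area ratio** $A(t_{k+1})/A(t_k)$;
* the **new points**: records with catch weight in $[t_{k+1}, t_k)$ --
  the observations newly entering the mapped weight class, the counts a
  threshold-area histogram prints above each bar;
* how many of those fall **in new areas**, outside the previous step's
  polygons (a new point inside an existing polygon corroborates an
  aggregation; one outside extends the map);
* **merge events** -- a region whose interior joins two or more previous
  polygons -- detected on the raster's 4-connected components, together
  with the merge's area growth and its *bridging support* (new points
  inside the merged region but outside its predecessors);
* newly created polygons with no predecessor.

Enclosure of individual records is read from the bilinear interpolant
whose contours the polygons are, so point accounting and polygon geometry
cannot disagree. Vector contour areas and raster cell-count areas are both
reported and cross-checked (they converge as the cell size shrinks; the
discrepancy is bounded by the boundary-cell count times the cell area).

The default threshold grid (`threshold_levels()`) is geometric with ratio
2, spanning from just below the surface maximum down to the smallest
positive catch. Catch weights of aggregating taxa are lognormal-like over
3-4 orders of magnitude; a geometric grid gives each decade equal
resolution, and a coarse step keeps the area jump at the
aggregation/background transition concentrated in one step rather than
smeared over many (the kernel's radial profile already spreads each
point's area contribution over a ~4-fold range of levels).

## Threshold selection

On such a curve the area initially establishes (the aggregation cores and
their flanks are being mapped), then is relatively constant, then inflates
sharply when the thresholds drop into the catch-weight range of dispersed
individuals: each new small catch contributes a whole new $h$-disk.
`select_threshold()` operationalizes this reading:

1. **Establishment**: after the first non-empty step, the first step whose
   area ratio is within `plateau_tol = 0.10` of 1 marks the end of the
   establishment phase. Steps before it are never candidates -- with a
   geometric grid anchored at the surface maximum the leading ratios are
   always large, and treating them as jumps would select the core of the
   densest aggregation rather than its boundary.
2. **Candidates**: later steps with area ratio at least `jump_min = 1.2`,
   taken in decreasing ratio order.
3. **Vetoes** (`apply_rejection_rules()`): `single-point-jump` (fewer than
   `min_new_points = 3` new observations); `merge-without-support` (more
   than half the step's growth from merges whose bridging regions hold
   fewer than `min_spread = 2` new points); `low-density-new-area` (mean
   density of the newly added area below `low_density_fraction = 0.5` of
   the candidate level). A curve that never flattens is flagged
   `gradual-increase` (no aggregation signal); one with no qualifying jump,
   `no-large-jump`.
4. The **selected threshold is the upper level** of the first unflagged
   candidate: the catch weight whose polygons still delimit aggregations,
   just before the curve inflates.

All constants live in `selection_criteria()` and every decision is written
to a narrative audit trail; a rejected curve returns `NA`, never a silent
guess. The published procedure these rules encode was expert judgment with
criteria "considered simultaneously"; making the constants explicit is the
package's design choice, and the defaults are declared rather than derived.

`summarize_enclosure()` reports the selected polygons' share of total
recorded biomass and of the sampled area; the sampled area defaults to the
convex hull of all trawl positions (including null sets) because survey
footprints are rarely available as masks -- pass an explicit
`sampled_area_km2` when one is.

## The synthetic scene generator

`generate_scene()` draws a Thomas cluster process -- Poisson parents,
Poisson-many offspring per parent displaced by an isotropic Gaussian --
over a uniform Poisson background, with lognormal catch weights and
zero-inflation for null sets. The defaults define the package's reference
study conditions:

| parameter | default | reading |
|---|---|---|
| window | 300 x 360 km | continental-margin survey footprint; default $h$ = 10 km |
| parents | 8 expected | distinct aggregations |
| offspring per parent | 40 expected, sd 8 km | sets hitting each aggregation |
| background | 250 expected sets | diffuse distribution |
| cluster catches | lognormal(log 50, 1) kg | dense-aggregation catches |
| background catches | lognormal(log 0.5, 0.6) kg | scattered individuals |
| zero inflation | 0.3 | null sets |

These emulate the right-skewed catch-weight histograms and tightly
co-occurring large catches characteristic of aggregating benthic
megafauna. They deliberately do *not* emulate depth stratification,
bathymetric barriers, gear geometry, or spatially varying catchability --
so passing recovery tests demonstrate that the machinery identifies the
intended transition under clean aggregation structure, not that it is
robust to every survey artefact.

The scene's ground-truth boundary level is defined as the background
catch-weight median `exp(meanlog)`: under peak scaling an isolated set's
surface peak equals its catch, so background sets enter the mapped
superlevel sets at their own catch scale. Recovery is measured as the
selected level landing within one geometric-grid step of the grid level
nearest that boundary.

`make_multisurvey()` splits a scene into spatial strata with per-gear
catch multipliers acting only *below* a cutoff -- the situation the
harmonization ladder exists to detect. The packaged recovery study uses a
background-only scene (~700 sets, lognormal(log 0.15, 1) catches, 10%
null), a multiplier of 0.5 below 0.2 kg, and the ladder
(0, 0.05, 0.1, 0.2, 0.5). Two deliberate design points: clusters are
omitted because random cluster placement would give the two strata
different catch mixtures *above* the cutoff, confounding the gear
comparison -- exactly the confounding that worried the original survey
comparisons; and the ladder brackets the examined scale because every
level above the true cutoff adds an $\alpha$-sized chance of pushing the
decision one level up (with $k$ levels above, exact recovery cannot exceed
roughly $(1-\alpha)^k$ even at full power).

## Worked example

```{r example}
spec <- scene_spec(seed = 42)
scene <- generate_scene(spec)
scene

records <- scene$records
positive <- records[records$biomass > 0, ]
surface <- kde(positive, default_config(data_extent(positive)))
surface

levels <- threshold_levels(surface)
curve <- build_curve(surface, levels = levels)
selection <- select_threshold(curve)
selection

truth_boundary_level(spec)

polys <- polygonize(surface, selection$selected_threshold)
enc <- summarize_enclosure(surface, polys, records)
round(c(biomass_pct = 100 * enc$biomass_fraction,
        area_pct = 100 * enc$area_fraction), 2)
```

The selected level sits at the grid level nearest the generator's 0.5 kg
boundary, and the polygons concentrate essentially all recorded biomass in
a small fraction of the sampled area -- the signature of a significant
concentration.

## Numerical choices and degenerate inputs

* Coordinates must arrive projected (planar meters); the declared CRS is
  carried as metadata and never used for computation. Reprojection is a
  pre-step, out of scope.
* Zero-biomass sets are retained in collections, excluded from KDE input,
  and counted in diagnostics; biomass values are stored as-is (survey
  series differ in recording resolution; the package does not round).
* Coincident records simply stack kernels. An all-coincident collection
  has no extent and is refused.
* A contour level above the surface maximum is an empty polygon set, not
  an error; non-monotone threshold grids are errors.
* Points exactly on a contour count as enclosed (thresholds are "at or
  above"); enclosure is evaluated on the same bilinear interpolant the
  contours are drawn from, so ties resolve consistently.
* Polygon merges are only recognized through genuine level-set
  connectivity (shared raster components), never by proximity.
* Polygons touching the raster edge carry an `edge_contact` flag; with
  the $h$-buffer this can only happen for surfaces built with overridden,
  tighter extents.

## Problem sizes used in the packaged studies

The validation suites run on the reference conditions above: 100 seeded
scenes for threshold recovery, 100 replicates for harmonization recovery,
100 random scenes for the contour/cell-count cross-check, 200 sample pairs
for the KS oracle, and ~95k-cell rasters (default cell size) per scene.
These sizes give binomial standard errors of ~3 percentage points on the
recovery rates, adequate for the >= 90% checks.

## Known limitations

* The outer boundary of a selected polygon is a kernel artefact as much as
  a biological one: it can extend up to $h$ beyond the outermost
  supporting catch. Refining boundaries (targeted survey, bathymetry,
  species distribution models) is downstream of this package; retaining
  the halo as a precautionary buffer is a defensible management reading.
* Selection among candidates is ratio-ordered with vetoes; when the true
  transition is smeared across several grid steps the argmax can move one
  step between replicates. The packaged recovery criterion (within one
  step) reflects that granularity.
* KS harmonization compares distributions, not spatial fields; strata
  with genuinely different biomass regimes can defeat pooling for reasons
  that are ecological, not instrumental. The decision note surfaces the
  <10% situation but the regional-split modelling itself is left to the
  analyst.
* No adaptive bandwidth, barrier-aware kernels, swept-area standardization
  or catch-per-unit-effort correction: the method pools raw catch weights
  above the harmonization cut by design.
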