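# vmekde

Delineation of **significant concentrations** of aggregating benthic taxa
— sponge grounds, sea pen fields, gorgonian coral forests; candidate
vulnerable marine ecosystems (VMEs) — from research-vessel bottom-trawl
point-biomass records.

Trawl surveys yield one geo-referenced catch weight per set. For
structure-forming taxa the conservation object is not the species' full
range but the dense aggregations that function as habitat. `vmekde` makes
that distinction computable and auditable:

1. **Harmonization** — ladders of two-sample Kolmogorov–Smirnov tests
   decide the minimum catch weight *t* above which surveys with different
   gears and tow durations share a catch-weight distribution
   (comparing the groups restricted to {x ≥ t} for an ascending grid of
   t) and may be pooled.
2. **Density surface** — a biomass-weighted quadratic (Epanechnikov)
   kernel surface, K(d) ∝ (1 − (d/h)²)² for d < h, summed per raster
   cell; default search radius h = (shortest extent)/30, cell size
   (shortest extent)/250. Under the default *peak* scaling an isolated
   catch's surface maximum equals its weight, so surface levels are
   directly comparable to catch-weight thresholds.
3. **Threshold–area curve** — the surface is polygonized (marching
   squares) at successively decreasing thresholds t₁ > t₂ > …; each step
   records the enclosed area A(t), the area ratio A(t_{k+1})/A(t_k), the
   new observations in [t_{k+1}, t_k), how many fall outside the previous
   polygons, and polygon merge topology.
4. **Selection** — after the curve flattens (aggregations established),
   the step with the largest qualifying area jump (ratio ≥ 1.2) marks the
   transition from aggregations to dispersed individuals; explicit vetoes
   reject jumps driven by a single datum, by polygon merges without
   bridging observations, or by new area of very low density. The
   selected threshold is the *upper* level of the accepted jump, and every
   decision lands in a narrative audit trail.

A seeded Thomas-process scene generator with lognormal catch weights
(`generate_scene()`) provides ground-truthed synthetic surveys, so the
entire chain is testable without restricted survey data.

## Worked example

```r
library(vmekde)

spec  <- scene_spec(seed = 42)          # reference synthetic conditions
scene <- generate_scene(spec)
scene
#> <vme_scene> 697 records (430 cluster, 267 background, 181 null sets), 16 parents

records  <- scene$records
positive <- records[records$biomass > 0, ]
surface  <- kde(positive, default_config(data_extent(positive)))
surface
#> <vme_surface> 319 x 267 cells of 1193.01 m, peak scaling, h = 9941.74 m
#>   values in [0, 1429], 516 input points

curve     <- build_curve(surface, levels = threshold_levels(surface))
selection <- select_threshold(curve)
selection
#> <vme_selection>
#>   aggregations established by the 5.58 threshold (area change within 10%)
#>   candidate 0.6975 -> 0.3488: area x1.31 on 87 new points (57 in new areas, 7 merges) ACCEPTED
#>   candidate 0.3488 -> 0.1744: area x1.26 on 50 new points (26 in new areas, 8 merges) ACCEPTED
#>   selected threshold: 0.6975 (upper level of the accepted jump)

polys <- polygonize(surface, selection$selected_threshold)
enc   <- summarize_enclosure(surface, polys, records)
round(c(biomass_pct = 100 * enc$biomass_fraction,
        area_pct    = 100 * enc$area_fraction), 2)
#> biomass_pct    area_pct
#>       99.86       22.40
```

Reading the output: the curve flattens once thresholds drop below the
aggregation cores (5.58 kg-equivalent); the largest subsequent jump is the
0.70 → 0.35 step, where dozens of scattered background sets enter the map
— so 0.70 is selected, one grid step from the generator's true
cluster/background boundary of 0.5 kg (`truth_boundary_level(spec)`). The
selected polygons enclose 99.9% of all recorded biomass on 22.4% of the
sampled area: a significant concentration.

Artifacts (ESRI ASCII raster, GeoJSON polygons with per-polygon
attributes, CSV curve and harmonization tables, JSON selection +
provenance) are written by the `cmd_*` drivers or the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/vmekde.R", package="vmekde"))')" \
    run-all --out results/demo --seed 42
```

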