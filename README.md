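# ecocircuit

Circuit-theory ecological networks on raster landscapes.

`ecocircuit` is for landscape and movement ecologists who need to map
where animals are likely to move between habitat patches — and where
that movement is dangerously funneled — from nothing more than an
elevation model, a land-use raster, and patch outlines. It implements
the full "ecological patch → resistance surface → ecological network"
workflow:

1. **Resistance surface.** Four movement-resistance factors (elevation,
   slope from Horn's 3×3 operator, terrain roughness `1/cos(slope)`,
   land use) are classified into fixed resistance values and combined by
   equal-weight superposition (the arithmetic mean), giving each cell a
   cost in `[10, 10000]`.
2. **Circuit solve.** The landscape becomes a resistive network (cells =
   nodes, edge resistance = mean of the two cell resistances, diagonals
   ×√2, patches contracted to supernodes). For every patch pair, 1 A is
   injected and the sparse graph Laplacian is solved: `I = V / R_eff`
   gives the pair's effective resistance, and per-cell current density
   is proportional to the passage probability of a random walker
   considering *all* possible paths.
3. **Corridors and pinch points.** Cumulative current density is
   classified with exact Fisher–Jenks natural breaks (k = 10); dropping
   the negligible-current classes yields the corridor mask and its
   land-use composition. Within a 10 km buffer of the focal (type-I)
   patches, a 3-level classification marks the highest level as pinch
   points, and observation points are validated against them with a
   seeded Monte-Carlo null.

A deterministic synthetic-landscape generator (smooth random-field DEM,
contiguous land-use mosaics, disjoint habitat patches, current-biased
observation points, and a planted channel-with-bottleneck fixture) makes
the entire pipeline testable without any GIS downloads. Rasters are
read and written as plain-text ESRI ASCII grids and vector products as
GeoJSON.

## Worked example

The channel preset plants a known corridor (a 3-cell-wide permeable
channel through a hostile matrix, narrowing to one cell) between a
type-I and a type-II patch, runs every stage, and reports what was
recovered:

```r
library(ecocircuit)
report <- run_pipeline(pipeline_config(preset = "channel", seed = 1))
report
#> <pipeline_report>
#>   patches: 2 (2.32 km2)
#>   R_eff over 1 pair(s): 162.34
#>   corridor: 354 cells in 1 group(s), threshold 0.003227
#>   pinch points: 3 cells, 0.12 km2
#>   validation: fraction 0.060 vs null q95 0.010 (p = 0.000999)
```

Reading the numbers: the two patches (2.32 km² of habitat) are
separated by an effective resistance of 162.3 network units; the
corridor mask (current density above the Jenks break 0.0032, i.e. above
the two negligible-current classes) contains 354 cells forming one
connected corridor group — the planted channel plus its immediate halo;
the pinch points (top of three current levels inside the 10 km type-I
buffer) are 3 cells sitting exactly on the channel's one-cell-wide
narrowing; and warning points sampled proportional to current overlap
the pinch area six times more often than the 95th percentile of a
1000-draw uniform null (empirical p ≈ 0.001).

Each stage is also available on its own — `generate_dem()`,
`generate_landuse()`, `compute_slope()`, `compute_roughness()`,
`classify_factor()`, `superpose()`, `build_graph()`, `solve_pair()`,
`accumulate_current()`, `jenks_breaks()`, `extract_corridors()`,
`zonal_composition()`, `buffer_patches()`, `extract_pinch_points()`,
`validate_points()` — and a thin command-line front end lives in
`inst/cli/ecocircuit.R` (`simulate` and `run` subcommands). The methods
vignette (`vignettes/circuit-connectivity.Rmd`) documents the model,
every tunable parameter, and the design decisions.

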