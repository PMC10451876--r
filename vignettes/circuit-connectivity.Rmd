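---
title: "Circuit-theory connectivity: models, parameters, and design choices"
author: "ecocircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit-theory connectivity: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecocircuit)
```

## The model

`ecocircuit` implements the circuit-theory model of landscape
connectivity. The landscape raster becomes a resistive electrical
network: each cell is a node, neighbouring cells are joined by a
resistor, and habitat patches are contracted to zero-internal-resistance
supernodes that act as terminals. A random-walking animal moving between
two patches is statistically equivalent to electrical current flowing
between the corresponding terminals, so

* the **effective resistance** `R_eff` between two patches (Ohm's law,
  `I = V / R_eff`, with a nominal 1 A injected) measures their isolation
  integrating *all* parallel pathways, not just the single best route;
* the **per-cell current density** is proportional to the expected
  number of passages of a random walker through that cell, considering
  every possible path;
* summing current maps over all unordered patch pairs gives a cumulative
  movement-intensity surface from which corridors and pinch points are
  extracted.

The model's key assumptions: movement is a memoryless random walk
(no perceptual range, no attraction to distant habitat), resistance is
isotropic and static, and patches are internally costless. These are the
standard assumptions of circuit-theory connectivity tools; results
should be read as *potential* movement patterns under those assumptions.

## The resistance surface

Movement resistance is built from four factors — elevation, slope,
terrain roughness, and land use — each classified into a small number of
classes with fixed resistance values (10, 50, 100, 200, 400, 10000
dimensionless cost units), then combined by **equal-weight
superposition**, which this package implements as the arithmetic mean of
the four classified values. With the default rules the combined value is
bounded in `[10, 10000]`; its attainable extremes are 10 (every factor
in its most permeable class) and 7600 (three terrain factors at 10000
plus the 400-valued land-use group), which the test suite asserts.

Defaults, chosen for a large terrestrial herbivore that avoids steep,
high, rugged terrain and human-dominated cover:

| factor | classes (lower-closed) | values |
|---|---|---|
| elevation (m) | <1000, 1000–1500, 1500–2000, ≥2000 | 10, 50, 100, 10000 |
| slope (degrees) | <10, 10–15, 15–30, ≥30 | 10, 50, 100, 10000 |
| roughness (ratio) | <1.1, 1.1–1.2, 1.2–1.3, ≥1.3 | 10, 50, 100, 10000 |
| land use | shrub/grass; forest/dry; swamp/rural; other woodland/paddy; urban/water | 10, 100, 200, 400, 10000 |

Design choices worth spelling out:

* **Slope** uses Horn's 3×3 finite-difference operator in degrees, the
  GIS default; class bounds of 10/15/30 only make sense in degrees.
  Border cells use replicated-edge padding so no grid shrinkage occurs;
  consequently the analytic inclined-plane identities hold for interior
  cells only, and the tests check them there.
* **Terrain roughness** is defined as the surface-to-planar area ratio
  `1 / cos(slope)`, a dimensionless quantity ≥ 1 whose natural working
  range (1–1.4 on all but cliff-like terrain) matches the class bounds
  1.1–1.3. Note that with this definition the top roughness class
  (>1.3) engages only above `acos(1/1.3) ≈ 39.7°` of slope.
* **Interval convention** is lower-closed (`[a, b)`): a slope of
  exactly 15 falls in the 15–30 class. The bound set is configurable via
  `resistance_rules()`.
* **Capping.** Some resistance-surface workflows cap factor values
  (e.g. at 1000) for numerical convenience. The default here is *no*
  cap — the reported extremes above are only consistent with uncapped
  table values — but `resistance_surface(cap = )` applies one for
  sensitivity analysis.

## The solver

`build_graph()` connects orthogonal neighbours with an edge resistance
equal to the mean of the two cell resistances; in the default
8-neighbourhood, diagonal edges are scaled by √2 for the longer
center-to-center distance (the dominant convention in published
circuit-theory software; the series/parallel closed-form tests use the
4-neighbourhood, where a uniform chain of n cells gives exactly
`(n−1)·r`). Parallel edges created by patch contraction merge by
conductance summation. `solve_pair()` grounds the target supernode and
solves the reduced sparse Laplacian by Cholesky factorization (`Matrix`)
— a direct solve, so accuracy is at machine precision and the Kirchhoff
residual at non-terminal nodes is asserted below 1e−8 of the injected
current on every solved instance. Per-cell current density is half the
sum of absolute currents on the cell's incident edges; terminal
supernode cells display the full injected current. Disconnected pairs
return `R_eff = Inf` with a zero current map and are reported, not
raised. Pair maps are accumulated as a raw sum without per-pair
normalization; correctness of the solver is additionally pinned by a
dense Laplacian-pseudoinverse oracle on random small graphs and by
Rayleigh monotonicity (raising any cell resistance never lowers any
`R_eff`).

## Corridors and pinch points

Corridor extraction classifies the positive current densities into
`k = 10` Jenks natural-breaks categories. The shipped Jenks is the exact
Fisher dynamic program on distinct values with multiplicity weights
(ties can never straddle a break); its objective is verified against
exhaustive partition enumeration on small samples. Samples beyond
`sample_cap = 2000` values are reduced to that many evenly spaced order
statistics — a deterministic stratified subsample, flagged in the
result — before the exact algorithm runs.

**Threshold semantics.** Two readings of "use the first categories of a
ten-class classification as the corridor threshold" exist, and the
package supports both:

* `drop_classes = 2` (default): discard the two *lowest* classes —
  cells whose current density is so low that passage is negligible —
  and keep everything above their upper break. The reported threshold is
  that break.
* `top_classes = n`: keep only the n *highest* classes.

The default was chosen on the evidence of the planted-structure
experiment below: on a scene with a known corridor, the top-N reading is
structurally unable to recover the full corridor, because distributed
leakage gives the corridor an internal current continuum
(transmission-line sag along its length) whose within-class variance
always exceeds that of a hostile matrix, so the exact DP spends most
classes subdividing the corridor itself and a top-2 cut lands inside it.
Dropping the negligible-current classes recovers the planted corridor
completely (coverage 1.00, false positives ≈ 1%) and yields a threshold
of the same order (≈ 0.003 on the channel scene) as fixed cuts used in
applied corridor studies. An absolute `threshold` override reproduces
fixed-cut workflows exactly. Patch interiors are excluded from
classification by default: terminal cells carry injection current, which
is not passage. Corridor "groups" are 8-connected components of the
mask.

Pinch points — narrow funnels with no alternative route, the places of
highest conservation irreplaceability — are extracted inside a 10 km
buffer of the type-I (focal-species) patches: current densities of
buffered non-patch cells are divided into `k = 3` Jenks levels and the
top level is the pinch mask. The three levels are computed *within* the
buffer (a `--global-breaks`-style alternative would classify globally;
the scoped reading keeps the pinch definition local to the focal
neighbourhood, which is where mitigation would be sited). Buffer
membership is planar Euclidean cell-center distance, computed by an
exact distance transform; the synthetic coordinate system is planar, so
no geodesic machinery is involved. A buffer whose current is too uniform
to classify returns an empty mask with a warning.

`validate_points()` quantifies the qualitative practice of overlaying
observation records on the pinch map: it reports the fraction of points
within a cell tolerance of a pinch cell together with a seeded
Monte-Carlo uniform null (default 1000 draws) and an empirical p-value,
so a visual "aligns well" claim becomes a testable quantity.

## The synthetic-landscape generator

Because the pipeline's real inputs (land-use and elevation rasters,
reserve polygons, wildlife warning points) are restricted-distribution
GIS layers, every stage is exercised on synthetic scenes:

* `generate_dem()`: Gaussian-filtered white noise rescaled to
  `[base, base + relief]`. Defaults (relief 2500 m on a 500 m base,
  correlation length 10 cells) give terrain spanning all four elevation
  and slope classes at the default 200 m cell size — mountainous
  subtropical relief. The smoothness parameter monotonically increases
  spatial autocorrelation (tested via lag-1 correlation).
* `generate_landuse()`: an independent smooth field sliced at rank
  quantiles, producing contiguous class mosaics with *exactly* the
  requested area fractions (up to rounding). Default weights
  (shrub/grass 0.30, forest/dry 0.35, swamp/rural 0.10, woodland/paddy
  0.15, urban/water 0.10) describe a vegetated rural region with
  scattered settlement.
* `generate_patches()`: rejection-sampled disjoint disks, type I then
  type II; placement failure is an error naming the patch, never a
  silent overlap.
* `generate_warning_points()`: points sampled proportional to current
  density — a planted signal of known strength for the validation
  stage. Avoidance behaviour (animals shunning high-traffic funnels) is
  deliberately not modelled; the generator assumes proportional
  sampling only.
* `channel_scene()`: the canonical planted-structure fixture — two
  patches (one of each type) in a hostile urban matrix, joined by a
  single 3-cell-wide shrub channel that narrows to one cell over a
  5-column stretch placed inside the type-I buffer. The channel is the
  known corridor; the narrow stretch is the known pinch.

Passing tests on these scenes demonstrate that the machinery recovers
planted structure under its own assumptions. They do not demonstrate
that any particular real landscape's corridors are correct: synthetic
mosaics lack roads, rivers as linear barriers, anisotropy, seasonal
change, and the spatial autocorrelation structure of real land-cover
products, and the warning-point generator bakes in exactly the
proportionality the validation then detects.

## Problem sizes and numerical notes

The test suite and the acceptance analyses run on 100×100-cell scenes
(10^4 nodes, ~4·10^4 edges), where a pairwise solve takes well under a
second; the solver is a direct sparse factorization, so the practical
ceiling on one CPU is a few hundred thousand cells per solve.
Deterministic ordering (column-major node numbering, seeded generators,
fixed subsampling) makes every pipeline product bit-reproducible for a
fixed configuration. Degenerate inputs are first-class: all-nodata
rasters, all-zero current maps, patches that rasterize to no cell,
fewer distinct values than classes, and empty point lists each raise a
specific error or a warning-plus-empty-result, as documented on each
function.

## Known limitations

* No least-cost-path or randomized-shortest-path variants; the random
  walk model only.
* No geodesic distances or map projections; coordinates are planar.
* The land-use legend is a five-group simplification bound by integer
  codes; finer legends must be mapped onto the five groups via
  `resistance_rules()`.
* `R_eff` and current are reported in network units (cell resistances
  are dimensionless costs); only comparisons within one analysis are
  meaningful.
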