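Package: ecocircuit
Title: Circuit-Theory Ecological Networks on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds ecological networks for landscape connectivity analysis
    with the circuit-theory (random walk) model. Constructs movement
    resistance surfaces from terrain (elevation, slope, surface roughness)
    and land-use factors by classified equal-weight superposition, treats
    habitat patches as terminals of a resistive grid, solves the graph
    Laplacian for pairwise effective resistance and per-cell current
    density, and extracts ecological corridors and pinch points with exact
    Fisher-Jenks natural-breaks classification and zonal land-use
    composition statistics. Includes a deterministic synthetic-landscape
    generator (smooth random-field elevation, contiguous land-use mosaics,
    disjoint habitat patches, current-biased observation points) so the
    whole pipeline can be exercised and validated without external GIS
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
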