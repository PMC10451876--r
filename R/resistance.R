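#' Land-use legend
#'
#' The default legend groups land-cover classes of a CNLUCC-style
#' classification into the five resistance groups used for large-herbivore
#' movement, from most permeable (shrubland, grassland, sparse woodland)
#' to impassable (construction land and open water). Integer codes are the
#' raster encoding; any legend with the same five groups can be bound by
#' remapping codes.
#'
#' @return Data frame `code`, `group`, `description`, `resistance`.
#' @export
landuse_legend <- function() {
  data.frame(
    code = 1:5,
    group = c("shrub_grass", "forest_dry", "swamp_rural",
              "woodland_paddy", "urban_water"),
    description = c("shrubbery, grassland, sparse woodland",
                    "forest, bare land, dry land",
                    "swamp, river beach, rural settlement",
                    "other woodland, paddy field, bare rock land",
                    "urban land, other construction land, river canal, lake, reservoir, glacier/snow"),
    resistance = c(10, 100, 200, 400, 10000))
}

# Integer code of a land-use group name.
landuse_code <- function(group) {
  leg <- landuse_legend()
  i <- match(group, leg$group)
  if (any(is.na(i))) stop("unknown land-use group: ", group[is.na(i)][1])
  leg$code[i]
}

#' Movement-resistance classification rules
#'
#' The default rule set assigns each of the four resistance factors —
#' elevation, slope, terrain roughness, and land use — a resistance value
#' per class. Continuous factors use lower-closed, upper-open intervals
#' (`[a, b)`), so a value exactly on a bound falls in the upper class.
#' Defaults (resistance in dimensionless cost units):
#'
#' * elevation (m): `<1000` → 10, `1000–1500` → 50, `1500–2000` → 100,
#'   `>=2000` → 10000
#' * slope (degrees): `<10` → 10, `10–15` → 50, `15–30` → 100,
#'   `>=30` → 10000
#' * roughness (ratio): `<1.1` → 10, `1.1–1.2` → 50, `1.2–1.3` → 100,
#'   `>=1.3` → 10000
#' * land use: per [landuse_legend()] group (10 / 100 / 200 / 400 / 10000)
#'
#' @param elevation,slope,roughness Each a list with `breaks` (interior
#'   class bounds, ascending) and `values` (length `length(breaks) + 1`).
#' @param landuse Data frame with columns `code` and `resistance`.
#' @return A `resistance_rules` object.
#' @export
resistance_rules <- function(
    elevation = list(breaks = c(1000, 1500, 2000),
                     values = c(10, 50, 100, 10000)),
    slope = list(breaks = c(10, 15, 30),
                 values = c(10, 50, 100, 10000)),
    roughness = list(breaks = c(1.1, 1.2, 1.3),
                     values = c(10, 50, 100, 10000)),
    landuse = landuse_legend()[, c("code", "resistance")]) {
  for (f in list(elevation, slope, roughness)) {
    if (is.unsorted(f$breaks, strictly = TRUE))
      stop("class breaks must be strictly ascending")
    if (length(f$values) != length(f$breaks) + 1L)
      stop("need one resistance value per class (length(breaks) + 1)")
  }
  structure(list(elevation = elevation, slope = slope,
                 roughness = roughness, landuse = landuse),
            class = "resistance_rules")
}

#' Classify a factor raster into resistance values
#'
#' Continuous factors are binned into lower-closed intervals; the land-use
#' factor is looked up by integer code. A land-use code absent from the
#' rules is a classification error listing the offending codes.
#'
#' @param x Factor `eco_raster` (elevation m, slope degrees, roughness
#'   ratio, or land-use codes).
#' @param rules A [resistance_rules()] object.
#' @param factor One of `"elevation"`, `"slope"`, `"roughness"`,
#'   `"landuse"`.
#' @return Resistance-value `eco_raster`.
#' @export
classify_factor <- function(x, rules = resistance_rules(),
                            factor = c("elevation", "slope", "roughness",
                                       "landuse")) {
  factor <- match.arg(factor)
  g <- raster_grid(x)
  v <- as.vector(as.matrix(x))
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  if (factor == "landuse") {
    map <- rules$landuse
    i <- match(v[ok], map$code)
    if (any(is.na(i))) {
      bad <- sort(unique(v[ok][is.na(i)]))
      stop("land-use code(s) with no resistance mapping: ",
           paste(bad, collapse = ", "))
    }
    out[ok] <- map$resistance[i]
  } else {
    rl <- rules[[factor]]
    cls <- findInterval(v[ok], rl$breaks) + 1L  # lower-closed bins
    out[ok] <- rl$values[cls]
  }
  eco_raster(matrix(out, g$nrows, g$ncols), g)
}

#' Combine factor resistances by equal-weight superposition
#'
#' The combined per-cell movement resistance is the arithmetic mean of the
#' four classified factor values; a nodata cell in any factor is nodata in
#' the result. With the default rules every valid cell lies in
#' `[10, 10000]`; the extremes are 10 (all factors in their most permeable
#' class) and 7600 (three terrain factors at 10000 plus the 400-valued
#' land-use group).
#'
#' @param elevation_r,slope_r,roughness_r,landuse_r Classified
#'   resistance-value rasters on one grid.
#' @return Combined resistance `eco_raster`.
#' @export
superpose <- function(elevation_r, slope_r, roughness_r, landuse_r) {
  stop_if_grid_mismatch(elevation_r, slope_r, roughness_r, landuse_r,
                        what = "classified factor rasters")
  g <- raster_grid(elevation_r)
  m <- (as.matrix(elevation_r) + as.matrix(slope_r) +
          as.matrix(roughness_r) + as.matrix(landuse_r)) / 4
  eco_raster(m, g)
}

#' Build the full resistance surface from elevation and land use
#'
#' Convenience chain: slope and roughness are derived from the elevation
#' model, all four factors are classified with `rules`, and the classified
#' values are combined by equal-weight superposition. `cap` optionally
#' truncates factor values before averaging (sensitivity analysis for
#' workflows that bound extreme resistances); the default is no cap.
#'
#' @param dem Elevation `eco_raster`, metres.
#' @param landuse Land-use code `eco_raster` on the same grid.
#' @param rules A [resistance_rules()] object.
#' @param cap Upper bound applied to the classified factor values
#'   (default `Inf`, i.e. table values used as printed).
#' @return List with `resistance` (combined `eco_raster`) and `factors`
#'   (the four classified rasters).
#' @export
resistance_surface <- function(dem, landuse, rules = resistance_rules(),
                               cap = Inf) {
  stop_if_grid_mismatch(dem, landuse)
  slope <- compute_slope(dem)
  rough <- compute_roughness(slope)
  fr <- list(elevation = classify_factor(dem, rules, "elevation"),
             slope = classify_factor(slope, rules, "slope"),
             roughness = classify_factor(rough, rules, "roughness"),
             landuse = classify_factor(landuse, rules, "landuse"))
  if (is.finite(cap)) {
    g <- raster_grid(dem)
    fr <- lapply(fr, function(r) eco_raster(pmin(as.matrix(r), cap), g))
  }
  list(resistance = superpose(fr$elevation, fr$slope, fr$roughness,
                              fr$landuse),
       factors = fr)
}
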