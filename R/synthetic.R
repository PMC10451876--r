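#' @title Synthetic landscapes for connectivity analysis
#' @description Deterministic, seeded generators of study areas with the
#'   statistical structure the pipeline assumes — a smooth elevation
#'   surface, a contiguous land-use mosaic covering the five resistance
#'   groups, disjoint habitat patches of types I and II, and observation
#'   points biased toward high current density — so every downstream stage
#'   can be exercised and tested without external GIS data.
#' @name synthetic_landscape
NULL

# Run expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched, making every generator a pure function of
# (spec, parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Gaussian-smoothed white noise on an nrows x ncols grid. `smoothness` is
# the kernel standard deviation in cells; larger values give longer
# spatial correlation lengths. Edges are handled by replication padding so
# the field keeps full size and stationary variance near the border.
smooth_field <- function(nrows, ncols, smoothness) {
  z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  if (smoothness <= 0) return(z)
  r <- max(1L, ceiling(3 * smoothness))
  k <- stats::dnorm(seq(-r, r), sd = smoothness)
  k <- k / sum(k)
  # band operator B: (n x (n + 2r)) mapping replication-padded rows to rows
  band <- function(n) {
    B <- matrix(0, n, n + 2L * r)
    for (i in seq_len(n)) B[i, i:(i + 2L * r)] <- k
    B
  }
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  zp <- z[pad_idx(nrows), pad_idx(ncols)]
  band(nrows) %*% zp %*% t(band(ncols))
}

#' Generate a synthetic elevation model
#'
#' A Gaussian-filtered random field rescaled to
#' `[base_elevation, base_elevation + relief]`. `smoothness` (kernel sd in
#' cells) controls spatial autocorrelation monotonically: neighbouring-cell
#' elevation differences shrink relative to the relief as it grows.
#'
#' @param spec A [grid_spec()].
#' @param relief Total elevation range, metres (`>= 0`).
#' @param base_elevation Elevation of the lowest cell, metres.
#' @param smoothness Correlation length in cells (`>= 1`).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return Elevation `eco_raster` in metres.
#' @export
generate_dem <- function(spec, relief = 2500, base_elevation = 500,
                         smoothness = 10, seed = 1) {
  stopifnot(inherits(spec, "grid_spec"))
  if (relief < 0) stop("relief must be >= 0")
  if (smoothness < 1) stop("smoothness must be >= 1")
  f <- with_seed(seed, smooth_field(spec$nrows, spec$ncols, smoothness))
  rng <- range(f)
  z <- if (relief == 0 || rng[1] == rng[2]) {
    matrix(base_elevation, spec$nrows, spec$ncols)
  } else {
    base_elevation + relief * (f - rng[1]) / (rng[2] - rng[1])
  }
  eco_raster(z, spec)
}

#' Generate a synthetic land-use mosaic
#'
#' An independent smooth random field (optionally blended with elevation)
#' is sliced at rank quantiles matching `class_weights`, which yields
#' contiguous single-class blobs with empirical class frequencies equal to
#' the weights up to rounding — not i.i.d. salt-and-pepper noise.
#'
#' @param spec A [grid_spec()].
#' @param dem Optional elevation raster; with `elevation_weight > 0`
#'   higher ground preferentially receives later-listed classes.
#' @param class_weights Named numeric vector of target area fractions;
#'   names must be land-use group names from [landuse_legend()]; must sum
#'   to 1.
#' @param smoothness Correlation length of the mosaic field, cells.
#' @param elevation_weight Blend factor in `[0, 1)` for the standardized
#'   DEM.
#' @param seed Integer seed.
#' @return Categorical `eco_raster` of integer group codes.
#' @export
generate_landuse <- function(spec, dem = NULL,
                             class_weights = c(shrub_grass = 0.30,
                                               forest_dry = 0.35,
                                               swamp_rural = 0.10,
                                               woodland_paddy = 0.15,
                                               urban_water = 0.10),
                             smoothness = 8, elevation_weight = 0, seed = 1) {
  stopifnot(inherits(spec, "grid_spec"))
  leg <- landuse_legend()
  unknown <- setdiff(names(class_weights), leg$group)
  if (length(unknown))
    stop("unknown land-use group(s): ", paste(unknown, collapse = ", "))
  if (abs(sum(class_weights) - 1) > 1e-9)
    stop("class_weights must sum to 1")
  f <- with_seed(seed, smooth_field(spec$nrows, spec$ncols, smoothness))
  if (!is.null(dem) && elevation_weight > 0) {
    stop_if_grid_mismatch(spec, dem)
    zs <- scale(as.vector(as.matrix(dem)))
    f <- (1 - elevation_weight) * scale(as.vector(f)) + elevation_weight * zs
    f <- matrix(f, spec$nrows, spec$ncols)
  }
  n <- spec$nrows * spec$ncols
  rk <- rank(as.vector(f), ties.method = "first")
  cuts <- c(0, round(cumsum(class_weights) * n))
  cuts[length(cuts)] <- n
  grp <- cut(rk, breaks = cuts, labels = FALSE)
  codes <- leg$code[match(names(class_weights), leg$group)]
  eco_raster(matrix(codes[grp], spec$nrows, spec$ncols), spec)
}

# Cells whose centers lie within `radius` cells of (row, col).
disk_cells <- function(row, col, radius, nrows, ncols) {
  r <- floor(radius)
  dr <- rep(-r:r, times = 2L * r + 1L)
  dc <- rep(-r:r, each = 2L * r + 1L)
  keep <- dr * dr + dc * dc <= radius * radius
  rw <- row + dr[keep]; cl <- col + dc[keep]
  ok <- rw >= 1L & rw <= nrows & cl >= 1L & cl <= ncols
  cbind(row = rw[ok], col = cl[ok])
}

#' Generate disjoint near-circular habitat patches
#'
#' Rejection sampling of disk-shaped patches of `radius_cells` cells;
#' the first `n_type1` placed are labeled type I. Failure to place a patch
#' within `max_attempts` draws raises an error naming it (no silent
#' overlaps).
#'
#' @param spec A [grid_spec()].
#' @param n_type1,n_type2 Patch counts per type (`n_type1 >= 1`).
#' @param radius_cells Patch radius in cells.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget per patch.
#' @return A [patch_set()] with cell-set geometries.
#' @export
generate_patches <- function(spec, n_type1 = 1, n_type2 = 1, radius_cells = 3,
                             seed = 1, max_attempts = 500) {
  stopifnot(inherits(spec, "grid_spec"))
  if (n_type1 < 1) stop("at least one type-I patch is required")
  n <- n_type1 + n_type2
  disk_area <- nrow(disk_cells(spec$nrows %/% 2L, spec$ncols %/% 2L,
                               radius_cells, spec$nrows, spec$ncols))
  if (n * disk_area >= 0.25 * spec$nrows * spec$ncols)
    stop("infeasible placement: requested patches would cover >= 25% of the grid")
  r <- floor(radius_cells)
  if (spec$nrows < 2L * r + 2L || spec$ncols < 2L * r + 2L)
    stop("infeasible placement: grid too small for the requested patch radius")
  occupied <- matrix(FALSE, spec$nrows, spec$ncols)
  geoms <- vector("list", n)
  with_seed(seed, {
    for (p in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        # keep the full disk inside the grid so patches stay near-circular
        rw <- r + sample.int(spec$nrows - 2L * r, 1L)
        cl <- r + sample.int(spec$ncols - 2L * r, 1L)
        cells <- disk_cells(rw, cl, radius_cells, spec$nrows, spec$ncols)
        if (!any(occupied[cells])) {
          occupied[cells] <- TRUE
          geoms[[p]] <- cells
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place patch %d after %d attempts", p, max_attempts))
    }
  })
  patch_set(seq_len(n), rep(c("I", "II"), c(n_type1, n_type2)), geoms)
}

#' Sample observation points proportional to current density
#'
#' Emulates species observation records concentrating where simulated
#' movement is dense: cells are drawn with probability proportional to
#' their current density and each point is placed at the cell center.
#'
#' @param current Non-negative current-density `eco_raster`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return Data frame `x`, `y`, `row`, `col`.
#' @export
generate_warning_points <- function(current, n, seed = 1) {
  g <- raster_grid(current)
  v <- as.vector(as.matrix(current))
  v[is.na(v)] <- 0
  if (any(v < 0)) stop("current map must be non-negative")
  if (sum(v) <= 0) stop("cannot sample points from an all-zero current map")
  idx <- with_seed(seed, sample.int(length(v), n, replace = TRUE, prob = v))
  rw <- ((idx - 1L) %% g$nrows) + 1L
  cl <- ((idx - 1L) %/% g$nrows) + 1L
  cc <- cell_centers(g, rw, cl)
  cc[, c("x", "y", "row", "col")]
}

#' Canonical channel scene
#'
#' Two habitat patches on opposite sides of a hostile (high-resistance)
#' matrix, joined by a single low-resistance channel a few cells wide that
#' narrows to one cell over a short stretch. The channel is the planted
#' corridor and the narrow stretch the planted pinch point, which makes
#' this the reference fixture for corridor and pinch-point recovery. The
#' elevation surface is flat lowland so that terrain contributes minimal
#' resistance and land use alone shapes the contrast.
#'
#' @param nrows,ncols Grid size (default 100 x 100).
#' @param cell_size Metres per cell (default 200, so a 10 km buffer spans
#'   50 cells).
#' @param channel_halfwidth Channel half-width in cells (width
#'   `2 * halfwidth + 1`).
#' @param narrow_cols Columns over which the channel narrows to one cell;
#'   default a 5-column stretch centered at 40% of the grid width, inside
#'   the type-I patch buffer.
#' @param seed Integer seed (kept for interface symmetry; the scene is
#'   deterministic).
#' @return A `synthetic_scene` list: `spec`, `dem`, `landuse`, `patches`,
#'   `channel_mask`, `narrow_cells`, `seed`.
#' @export
channel_scene <- function(nrows = 100, ncols = 100, cell_size = 200,
                          channel_halfwidth = 1, narrow_cols = NULL, seed = 1) {
  spec <- grid_spec(nrows, ncols, cell_size)
  mid <- nrows %/% 2L
  if (is.null(narrow_cols)) {
    ctr <- round(0.4 * ncols)
    narrow_cols <- (ctr - 2L):(ctr + 2L)
  }
  dem <- eco_raster(matrix(700, nrows, ncols), spec)
  lu <- matrix(landuse_code("urban_water"), nrows, ncols)
  prad <- 3
  left <- disk_cells(mid, 6L, prad, nrows, ncols)
  right <- disk_cells(mid, ncols - 5L, prad, nrows, ncols)
  ch <- matrix(FALSE, nrows, ncols)
  span <- (max(left[, 2]) + 1L):(min(right[, 2]) - 1L)
  for (cl in span) {
    hw <- if (cl %in% narrow_cols) 0L else as.integer(channel_halfwidth)
    ch[(mid - hw):(mid + hw), cl] <- TRUE
  }
  lu[ch] <- landuse_code("shrub_grass")
  patches <- patch_set(1:2, c("I", "II"), list(left, right))
  lab <- rasterize_patches(patches, spec)
  lu[as.matrix(lab) > 0] <- landuse_code("shrub_grass")
  structure(list(spec = spec, dem = dem,
                 landuse = eco_raster(lu, spec),
                 patches = patches, channel_mask = eco_raster(ch, spec),
                 narrow_cells = cbind(row = rep(mid, length(narrow_cols)),
                                      col = narrow_cols),
                 seed = seed),
            class = "synthetic_scene")
}

#' Generic mosaic scene
#'
#' A full synthetic study area: autocorrelated elevation, a five-class
#' land-use mosaic, and randomly placed disjoint patches of both types.
#'
#' @inheritParams channel_scene
#' @param relief,base_elevation,smoothness Passed to [generate_dem()].
#' @param n_type1,n_type2,radius_cells Passed to [generate_patches()].
#' @return A `synthetic_scene` (without planted channel structure).
#' @export
mosaic_scene <- function(nrows = 100, ncols = 100, cell_size = 200,
                         relief = 2500, base_elevation = 500, smoothness = 10,
                         n_type1 = 2, n_type2 = 2, radius_cells = 3, seed = 1) {
  spec <- grid_spec(nrows, ncols, cell_size)
  dem <- generate_dem(spec, relief, base_elevation, smoothness, seed = seed)
  lu <- generate_landuse(spec, dem, elevation_weight = 0.3, seed = seed + 1L)
  patches <- generate_patches(spec, n_type1, n_type2, radius_cells,
                              seed = seed + 2L)
  structure(list(spec = spec, dem = dem, landuse = lu, patches = patches,
                 channel_mask = NULL, narrow_cells = NULL, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d cells, %d patches%s\n",
              x$spec$nrows, x$spec$ncols, length(x$patches),
              if (!is.null(x$channel_mask)) ", planted channel" else ""))
  invisible(x)
}
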