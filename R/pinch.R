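#' Buffer habitat patches of a given type
#'
#' A cell belongs to the buffer when its center lies within `radius_m`
#' (planar Euclidean, center-to-center) of any cell of a patch of the
#' requested type(s); patch cells themselves are included. Distances come
#' from an exact Euclidean distance transform.
#'
#' @param patch_labels Labeled patch raster from [rasterize_patches()].
#' @param patches The [patch_set()] carrying the type attribute.
#' @param radius_m Buffer radius in metres (default 10 km).
#' @param types Patch types buffered (default `"I"`, the focal-species
#'   reserves).
#' @return Logical buffer `eco_raster`.
#' @export
buffer_patches <- function(patch_labels, patches, radius_m = 10000,
                           types = "I") {
  g <- raster_grid(patch_labels)
  ids <- patches$info$id[patches$info$type %in% types]
  if (length(ids) == 0L)
    stop("no patch of type ", paste(types, collapse = "/"), " to buffer")
  inpatch <- matrix(as.matrix(patch_labels) %in% ids, g$nrows, g$ncols)
  if (!any(inpatch)) stop("selected patches cover no cells")
  # distmap: per-cell distance (in cells) to the nearest zero pixel
  d <- EBImage::distmap(matrix(as.numeric(!inpatch), g$nrows, g$ncols))
  eco_raster(matrix(as.numeric(d) * g$cell_size <= radius_m,
                    g$nrows, g$ncols), g)
}

#' Identify ecological pinch points
#'
#' Within the buffer of the focal patches, positive current densities are
#' divided into `k` (default 3) Jenks natural-break levels and the
#' highest level is the pinch-point mask: the narrow, irreplaceable
#' places where movement is funneled. Patch-interior cells are excluded
#' (terminal injection currents are not passage). A buffer whose current
#' is too uniform to classify yields an empty mask with a warning rather
#' than an error.
#'
#' @param current Cumulative current `eco_raster` (or
#'   `current_map_result`).
#' @param buffer Logical buffer `eco_raster` from [buffer_patches()].
#' @param patch_labels Optional labeled patch raster for the exclusion.
#' @param k Number of Jenks levels within the buffer (default 3).
#' @param landuse Optional land-use raster; when given, the land-use
#'   composition of the mask is reported via [zonal_composition()].
#' @param legend Legend for the composition table.
#' @return A `pinch_points` object: `mask` (logical `eco_raster`),
#'   `total_area_km2`, `breaks`, `buffer_radius_m` attribute of the call,
#'   and `composition` (or `NULL`).
#' @export
extract_pinch_points <- function(current, buffer, patch_labels = NULL,
                                 k = 3, landuse = NULL,
                                 legend = landuse_legend()) {
  if (inherits(current, "current_map_result")) current <- current$current
  stop_if_grid_mismatch(current, buffer)
  g <- raster_grid(current)
  cur <- as.matrix(current)
  cand <- as.matrix(buffer) & !is.na(cur) & cur > 0
  if (!is.null(patch_labels)) {
    stop_if_grid_mismatch(current, patch_labels)
    cand <- cand & as.matrix(patch_labels) == 0L
  }
  empty <- function(msg) {
    warning(msg)
    structure(list(mask = eco_raster(matrix(FALSE, g$nrows, g$ncols), g),
                   total_area_km2 = 0, breaks = NULL, composition = NULL),
              class = "pinch_points")
  }
  if (!any(cand))
    return(empty("no positive current density inside the buffer"))
  vals <- cur[cand]
  if (length(unique(vals)) < k)
    return(empty(sprintf(
      "current density in the buffer has fewer than %d distinct values; no pinch points", k)))
  jb <- jenks_breaks(vals, k)
  mask <- cand & cur >= jb$breaks[k - 1]
  comp <- if (!is.null(landuse))
    zonal_composition(eco_raster(mask, g), landuse, legend) else NULL
  structure(list(mask = eco_raster(mask, g),
                 total_area_km2 = sum(mask) * g$cell_size^2 / 1e6,
                 breaks = jb, composition = comp),
            class = "pinch_points")
}

#' @export
print.pinch_points <- function(x, ...) {
  cat(sprintf("<pinch_points> %d cells, %.4g km2\n",
              sum(as.matrix(x$mask)), x$total_area_km2))
  invisible(x)
}

#' Validate pinch points against observation points
#'
#' Measures how strongly observed points (e.g. wildlife warning records)
#' coincide with the pinch-point mask: the fraction of points within
#' `tolerance_cells` (Euclidean, in cells) of a pinch cell, compared with
#' the same fraction for `n_null` seeded uniform-random point sets of the
#' same size over the valid grid, giving an empirical p-value.
#'
#' @param pinch A `pinch_points` object (or logical mask `eco_raster`).
#' @param points Data frame with planar `x`, `y` columns inside the grid
#'   extent.
#' @param tolerance_cells Match tolerance in cells (default 0: on a pinch
#'   cell).
#' @param n_null Number of Monte-Carlo null draws (default 1000).
#' @param seed Seed for the null draws.
#' @return List: `fraction`, `null_mean`, `null_q95`, `p_value`,
#'   `n_points`, `n_null`.
#' @export
validate_points <- function(pinch, points, tolerance_cells = 0,
                            n_null = 1000, seed = 1) {
  mask <- if (inherits(pinch, "pinch_points")) pinch$mask else pinch
  g <- raster_grid(mask)
  if (nrow(points) == 0L)
    stop("empty point list: the overlap fraction is undefined")
  pc <- cells_of_points(g, points$x, points$y)
  if (anyNA(pc$row)) stop("point(s) outside the grid extent")
  m <- as.matrix(mask)
  if (!any(m)) stop("empty pinch mask")
  # distance (cells) from every cell to the nearest pinch cell
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(!m), g$nrows, g$ncols)))
  near <- d <= tolerance_cells
  obs <- mean(near[cbind(pc$row, pc$col)])
  n <- nrow(points)
  nullfrac <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      idx <- sample.int(g$nrows * g$ncols, n, replace = TRUE)
      mean(near[idx])
    }, numeric(1))
  })
  list(fraction = obs,
       null_mean = mean(nullfrac),
       null_q95 = stats::quantile(nullfrac, 0.95, names = FALSE),
       p_value = (1 + sum(nullfrac >= obs)) / (n_null + 1),
       n_points = n, n_null = n_null)
}
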