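#' Construct a set of ecological patches
#'
#' Patches are the habitat regions the network connects: type I holds the
#' focal species (here they also seed the pinch-point buffer), type II is
#' suitable alternative habitat. Both types are solver terminals with equal
#' standing. A patch geometry is either an explicit set of grid cells or a
#' planar polygon (rasterized by the cell-center rule).
#'
#' @param ids Integer vector of unique patch ids.
#' @param types Character vector, each `"I"` or `"II"`.
#' @param geometries List, one entry per patch: either a two-column
#'   `(row, col)` integer matrix of cells, or a list with element `xy`, a
#'   closed-or-open two-column `(x, y)` polygon ring.
#' @return A `patch_set`: list with `info` (data frame `id`, `type`) and
#'   `geometry`.
#' @seealso [rasterize_patches()], [patch_areas()], [generate_patches()]
#' @export
patch_set <- function(ids, types, geometries) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("patch ids must be unique")
  if (!all(types %in% c("I", "II")))
    stop("patch types must be \"I\" or \"II\"")
  if (length(ids) != length(types) || length(ids) != length(geometries))
    stop("ids, types and geometries must have equal length")
  structure(list(info = data.frame(id = ids, type = as.character(types)),
                 geometry = geometries),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d type I, %d type II)\n",
              nrow(x$info), sum(x$info$type == "I"), sum(x$info$type == "II")))
  invisible(x)
}

#' @export
length.patch_set <- function(x) nrow(x$info)

# Even-odd ray-casting point-in-polygon; xy is an (x, y) ring, open or closed.
# Written here because no polygon geometry package ships with the image.
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1L }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize patches onto the analysis grid
#'
#' A cell receives a patch id when its center falls inside the patch
#' polygon (or when it is listed explicitly for cell-set geometries);
#' cells outside every patch are 0. Patches must stay disjoint on the
#' grid, and a patch that covers no cell center is an error rather than a
#' silent drop.
#'
#' @param patches A [patch_set()].
#' @param spec A [grid_spec()].
#' @return Integer `eco_raster` of patch labels (0 = background).
#' @export
rasterize_patches <- function(patches, spec) {
  stopifnot(inherits(patches, "patch_set"), inherits(spec, "grid_spec"))
  lab <- matrix(0L, spec$nrows, spec$ncols)
  for (p in seq_len(nrow(patches$info))) {
    id <- patches$info$id[p]
    geom <- patches$geometry[[p]]
    if (is.matrix(geom)) {
      rw <- geom[, 1]; cl <- geom[, 2]
      if (any(rw < 1L | rw > spec$nrows | cl < 1L | cl > spec$ncols))
        stop(sprintf("patch %d has cells outside the grid extent", id))
      idx <- cbind(rw, cl)
    } else {
      cc <- cell_centers(spec)
      hit <- point_in_polygon(cc$x, cc$y, geom$xy)
      if (!any(hit))
        stop(sprintf("degenerate patch %d: polygon covers no cell center", id))
      idx <- cbind(cc$row[hit], cc$col[hit])
    }
    if (nrow(idx) == 0L)
      stop(sprintf("degenerate patch %d: no cells", id))
    if (any(lab[idx] != 0L))
      stop(sprintf("patch %d overlaps patch %d on the grid",
                   id, lab[idx][lab[idx] != 0L][1]))
    lab[idx] <- id
  }
  eco_raster(lab, spec)
}

#' Tabulate patch areas
#'
#' @param labels Labeled patch raster from [rasterize_patches()].
#' @param patches Optional [patch_set()] supplying the type column.
#' @return Data frame `id`, `type` (if available), `cells`, `area_km2`,
#'   with `area_km2 = cells * cell_size^2 / 1e6`.
#' @export
patch_areas <- function(labels, patches = NULL) {
  g <- raster_grid(labels)
  v <- as.vector(as.matrix(labels))
  v <- v[!is.na(v) & v > 0]
  if (length(v) == 0L)
    return(data.frame(id = integer(), type = character(),
                      cells = integer(), area_km2 = numeric()))
  tab <- table(v)
  out <- data.frame(id = as.integer(names(tab)),
                    cells = as.integer(tab))
  out$area_km2 <- out$cells * g$cell_size^2 / 1e6
  if (!is.null(patches))
    out$type <- patches$info$type[match(out$id, patches$info$id)]
  out[, intersect(c("id", "type", "cells", "area_km2"), names(out))]
}

#' Write patches or points as GeoJSON
#'
#' Cell-set patches are exported as a MultiPolygon of their cell squares;
#' polygon patches keep their ring. Points become Point features.
#'
#' @param patches A [patch_set()].
#' @param spec A [grid_spec()] (needed to place cell squares).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_patches_geojson <- function(patches, spec, path) {
  cs <- spec$cell_size
  feat <- lapply(seq_len(nrow(patches$info)), function(p) {
    geom <- patches$geometry[[p]]
    if (is.matrix(geom)) {
      rings <- lapply(seq_len(nrow(geom)), function(i) {
        x0 <- spec$origin[1] + (geom[i, 2] - 1) * cs
        y0 <- spec$origin[2] - (geom[i, 1] - 1) * cs
        list(list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 - cs),
                  c(x0, y0 - cs), c(x0, y0)))
      })
      g <- list(type = "MultiPolygon", coordinates = rings)
    } else {
      ring <- lapply(seq_len(nrow(geom$xy)), function(i) as.numeric(geom$xy[i, ]))
      if (!identical(ring[[1]], ring[[length(ring)]])) ring <- c(ring, ring[1])
      g <- list(type = "Polygon", coordinates = list(ring))
    }
    list(type = "Feature",
         properties = list(id = patches$info$id[p], type = patches$info$type[p]),
         geometry = g)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patches_geojson
#' @param points Data frame with columns `x` and `y`.
#' @export
write_points_geojson <- function(points, path) {
  feat <- lapply(seq_len(nrow(points)), function(i)
    list(type = "Feature", properties = list(id = i),
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
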