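# Connected components of a logical mask under 8-connectivity, via an
# explicit neighbour graph in igraph. Returns list(n, labels matrix).
mask_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(list(n = 0L, labels = lab))
  id_of <- matrix(NA_integer_, nrow(mask), ncol(mask))
  id_of[idx] <- seq_along(idx)
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- list()
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    ia <- as.matrix(expand.grid(r1, c1))
    ib <- cbind(ia[, 1] + dr, ia[, 2] + dc)
    ok <- mask[ia] & mask[ib]
    edges[[length(edges) + 1L]] <- cbind(id_of[ia[ok, , drop = FALSE]],
                                         id_of[ib[ok, , drop = FALSE]])
  }
  e <- do.call(rbind, edges)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e[, 1], to = e[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_along(idx)))
  memb <- igraph::components(ig)$membership
  lab[idx] <- as.integer(memb)
  list(n = max(memb), labels = lab)
}

#' Extract ecological corridors from a cumulative current map
#'
#' Positive current densities are classified into `k` Jenks natural-break
#' categories and, by default, the `drop_classes` lowest categories — the
#' areas whose current density is so low that passage is negligible — are
#' discarded: the corridor mask is every cell at or above the upper bound
#' of the dropped classes (that break is the reported extraction
#' threshold). Alternatively, `top_classes` keeps only the N highest
#' categories, and `threshold` applies an absolute cut. Cells inside
#' focal patches are excluded by default — their terminal currents
#' reflect injection, not passage. Corridor groups are the 8-connected
#' components of the mask.
#'
#' @param current Cumulative current `eco_raster` (or a
#'   `current_map_result`).
#' @param patch_labels Optional labeled patch raster; used to exclude
#'   patch interiors when `exclude_patches` is `TRUE`.
#' @param k Number of Jenks classes (default 10).
#' @param drop_classes How many of the lowest classes to discard
#'   (default 2); ignored when `top_classes` or `threshold` is given.
#' @param top_classes Alternative semantics: keep only the `top_classes`
#'   highest classes (threshold = lower bound of the lowest kept class).
#' @param exclude_patches Exclude patch-interior cells from
#'   classification and mask (default `TRUE`).
#' @param threshold Optional absolute current cut overriding the
#'   Jenks-derived threshold (fixed-cut workflows).
#' @return A `corridor_mask`: `mask` (logical `eco_raster`),
#'   `threshold_used`, `breaks` (the `jenks_breaks`, or `NULL` under an
#'   absolute threshold), `n_groups`, `group_labels` (`eco_raster`).
#' @export
extract_corridors <- function(current, patch_labels = NULL, k = 10,
                              drop_classes = 2, top_classes = NULL,
                              exclude_patches = TRUE, threshold = NULL) {
  if (inherits(current, "current_map_result")) current <- current$current
  g <- raster_grid(current)
  cur <- as.matrix(current)
  cand <- !is.na(cur) & cur > 0
  if (!is.null(patch_labels) && exclude_patches) {
    stop_if_grid_mismatch(current, patch_labels)
    cand <- cand & as.matrix(patch_labels) == 0L
  }
  if (!any(cand)) stop("empty corridor: no positive current density")
  jb <- NULL
  if (is.null(threshold)) {
    jb <- jenks_breaks(cur[cand], k)
    if (!is.null(top_classes)) {
      if (top_classes < 1 || top_classes > k)
        stop("top_classes must be in 1..k")
      threshold <- if (top_classes == k) min(cur[cand]) else
        jb$breaks[k - top_classes]
    } else {
      if (drop_classes < 0 || drop_classes >= k)
        stop("drop_classes must be in 0..k-1")
      threshold <- if (drop_classes == 0) min(cur[cand]) else
        jb$breaks[drop_classes]
    }
  }
  mask <- cand & cur >= threshold
  comp <- mask_components(mask)
  structure(list(mask = eco_raster(mask, g), threshold_used = threshold,
                 breaks = jb, n_groups = comp$n,
                 group_labels = eco_raster(comp$labels, g)),
            class = "corridor_mask")
}

#' @export
print.corridor_mask <- function(x, ...) {
  cat(sprintf("<corridor_mask> %d cells in %d group(s), threshold %.6g\n",
              sum(as.matrix(x$mask)), x$n_groups, x$threshold_used))
  invisible(x)
}

#' Zonal land-use composition of a mask
#'
#' Per land-use class inside the mask: cell count, area, and percent of
#' the mask area, plus one aggregate row pooling the forest and grassland
#' groups (the vegetated cover types that make corridors viable).
#'
#' @param mask Logical `eco_raster` (or `corridor_mask` /
#'   `pinch_points`).
#' @param landuse Land-use code `eco_raster` on the same grid.
#' @param legend Legend data frame (default [landuse_legend()]).
#' @param aggregate_groups Group names pooled into the aggregate row.
#' @return Data frame `code`, `group`, `cells`, `area_km2`, `percent`
#'   (summing to 100 over the non-aggregate rows), with the aggregate row
#'   labeled `forest_grassland` (`code = NA`).
#' @export
zonal_composition <- function(mask, landuse, legend = landuse_legend(),
                              aggregate_groups = c("shrub_grass",
                                                   "forest_dry")) {
  if (inherits(mask, "corridor_mask")) mask <- mask$mask
  if (inherits(mask, "pinch_points")) mask <- mask$mask
  stop_if_grid_mismatch(mask, landuse)
  g <- raster_grid(mask)
  m <- as.matrix(mask) & !is.na(as.matrix(landuse))
  codes <- as.matrix(landuse)[m]
  if (length(codes) == 0L) {
    warning("empty mask: no cells to compose")
    return(data.frame(code = integer(), group = character(),
                      cells = integer(), area_km2 = numeric(),
                      percent = numeric()))
  }
  tab <- table(codes)
  out <- data.frame(code = as.integer(names(tab)),
                    cells = as.integer(tab))
  out$group <- legend$group[match(out$code, legend$code)]
  out$group[is.na(out$group)] <- "unmapped"
  out$area_km2 <- out$cells * g$cell_size^2 / 1e6
  out$percent <- 100 * out$cells / sum(out$cells)
  agg <- out$group %in% aggregate_groups
  out <- rbind(out[, c("code", "group", "cells", "area_km2", "percent")],
               data.frame(code = NA_integer_, group = "forest_grassland",
                          cells = sum(out$cells[agg]),
                          area_km2 = sum(out$area_km2[agg]),
                          percent = sum(out$percent[agg])))
  rownames(out) <- NULL
  out
}
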