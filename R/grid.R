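#' Define a raster grid
#'
#' A grid specification fixes the geometry shared by every raster in an
#' analysis: dimensions, cell size, and the planar coordinate of the
#' top-left corner. All layers of one analysis (elevation, land use,
#' resistance, current) must carry an identical spec.
#'
#' @param nrows,ncols Grid dimensions; both must be at least 2.
#' @param cell_size Edge length of a (square) cell, in metres.
#' @param origin Numeric length-2, planar `(x, y)` of the top-left corner
#'   of the top-left cell. Rows run south (decreasing y), columns east.
#' @param nodata_value Sentinel written to file for masked cells.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(100, 100, cell_size = 200)
#' @export
grid_spec <- function(nrows, ncols, cell_size, origin = c(0, nrows * cell_size),
                      nodata_value = -9999) {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (is.na(nrows) || is.na(ncols) || nrows < 2L || ncols < 2L)
    stop("invalid grid spec: nrows and ncols must both be >= 2")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("invalid grid spec: cell_size must be a positive scalar (metres)")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("invalid grid spec: origin must be finite (x, y)")
  structure(list(nrows = nrows, ncols = ncols, cell_size = cell_size,
                 origin = as.numeric(origin), nodata_value = nodata_value),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g m/cell, origin (%.6g, %.6g)\n",
              x$nrows, x$ncols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Wrap a matrix as a georeferenced raster layer
#'
#' @param values Numeric matrix with `spec$nrows` rows and `spec$ncols`
#'   columns; `NA` marks nodata cells.
#' @param spec A [grid_spec()].
#' @return An `eco_raster`: the matrix with the spec attached.
#' @export
eco_raster <- function(values, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$nrows || ncol(values) != spec$ncols)
    stop(sprintf("raster is %d x %d but the grid spec says %d x %d",
                 nrow(values), ncol(values), spec$nrows, spec$ncols))
  structure(values, grid = spec, class = c("eco_raster", class(values)))
}

#' @export
print.eco_raster <- function(x, ...) {
  g <- raster_grid(x)
  v <- as.vector(x)
  cat(sprintf("<eco_raster> %d x %d, %.6g m/cell | range [%.6g, %.6g], %d NA\n",
              g$nrows, g$ncols, g$cell_size,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Retrieve the grid spec of a raster
#' @param x An `eco_raster`.
#' @return The attached [grid_spec()].
#' @export
raster_grid <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("not an eco_raster: no grid spec attached")
  g
}

#' @rdname eco_raster
#' @param x An `eco_raster`.
#' @param ... Unused.
#' @export
as.matrix.eco_raster <- function(x, ...) {
  attr(x, "grid") <- NULL
  class(x) <- "matrix"
  unclass(x)
}

# TRUE if two rasters (or a raster and a spec) share an identical grid.
same_grid <- function(a, b) {
  ga <- if (inherits(a, "grid_spec")) a else raster_grid(a)
  gb <- if (inherits(b, "grid_spec")) b else raster_grid(b)
  isTRUE(all.equal(unclass(ga), unclass(gb)))
}

stop_if_grid_mismatch <- function(..., what = "rasters") {
  layers <- list(...)
  for (i in seq_along(layers)[-1])
    if (!same_grid(layers[[1]], layers[[i]]))
      stop(sprintf("grid mismatch: %s must share an identical grid spec", what))
  invisible(TRUE)
}

#' Planar coordinates of cell centers
#'
#' @param spec A [grid_spec()].
#' @param rows,cols Integer vectors of equal length (recycled); defaults to
#'   every cell in row-major order.
#' @return Data frame with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(spec, rows = NULL, cols = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(rows)) {
    rows <- rep(seq_len(spec$nrows), times = spec$ncols)
    cols <- rep(seq_len(spec$ncols), each = spec$nrows)
  }
  data.frame(row = rows, col = cols,
             x = spec$origin[1] + (cols - 0.5) * spec$cell_size,
             y = spec$origin[2] - (rows - 0.5) * spec$cell_size)
}

# Inverse of cell_centers: point coordinates -> (row, col); NA outside extent.
cells_of_points <- function(spec, x, y) {
  col <- as.integer(floor((x - spec$origin[1]) / spec$cell_size)) + 1L
  row <- as.integer(floor((spec$origin[2] - y) / spec$cell_size)) + 1L
  bad <- row < 1L | row > spec$nrows | col < 1L | col > spec$ncols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text `.asc` interchange format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by the cell values, top row first.
#'
#' @param x An `eco_raster`.
#' @param path File path.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns an
#'   `eco_raster`.
#' @export
write_asc <- function(x, path) {
  g <- raster_grid(x)
  m <- as.matrix(x)
  m[is.na(m)] <- g$nodata_value
  hdr <- c(sprintf("ncols %d", g$ncols),
           sprintf("nrows %d", g$nrows),
           sprintf("xllcorner %.10g", g$origin[1]),
           sprintf("yllcorner %.10g", g$origin[2] - g$nrows * g$cell_size),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", g$nodata_value))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  spec <- grid_spec(val[["nrows"]], val[["ncols"]], val[["cellsize"]],
                    origin = c(val[["xllcorner"]],
                               val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]]),
                    nodata_value = val[["nodata_value"]])
  m[m == val[["nodata_value"]]] <- NA
  eco_raster(m, spec)
}
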