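#' Slope from an elevation model (Horn's method)
#'
#' Finite-difference slope on the 3 x 3 neighbourhood with Horn's
#' weighting, the standard GIS operator. Border cells use
#' nearest-neighbour (replicated) padding so the output keeps the full
#' grid. Output is in degrees, in `[0, 90)`; a flat surface gives 0
#' everywhere and an inclined plane of gradient magnitude g gives
#' `atan(g)` degrees.
#'
#' @param dem Elevation `eco_raster`, metres.
#' @param cell_size Metres per cell; defaults to the raster's grid spec.
#' @return Slope `eco_raster`, degrees.
#' @export
compute_slope <- function(dem, cell_size = NULL) {
  g <- raster_grid(dem)
  if (is.null(cell_size)) cell_size <- g$cell_size
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("invalid cell_size: must be positive")
  z <- as.matrix(dem)
  nr <- nrow(z); nc <- ncol(z)
  p <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  ri <- 1L + seq_len(nr); ci <- 1L + seq_len(nc)
  a <- p[ri - 1L, ci - 1L]; b <- p[ri - 1L, ci]; cc <- p[ri - 1L, ci + 1L]
  d <- p[ri, ci - 1L];                           f <- p[ri, ci + 1L]
  gg <- p[ri + 1L, ci - 1L]; h <- p[ri + 1L, ci]; i2 <- p[ri + 1L, ci + 1L]
  dzdx <- ((cc + 2 * f + i2) - (a + 2 * d + gg)) / (8 * cell_size)
  dzdy <- ((gg + 2 * h + i2) - (a + 2 * b + cc)) / (8 * cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  eco_raster(slope, g)
}

#' Terrain roughness as the surface-to-planar area ratio
#'
#' `roughness = 1 / cos(slope)`: the factor by which true surface area
#' exceeds its planar projection. Dimensionless, `>= 1`, equal to 1 on
#' flat ground; strictly increasing in slope.
#'
#' @param slope Slope `eco_raster` in degrees (from [compute_slope()]).
#' @return Roughness `eco_raster`.
#' @export
compute_roughness <- function(slope) {
  g <- raster_grid(slope)
  s <- as.matrix(slope)
  if (any(s >= 90, na.rm = TRUE))
    stop("slope >= 90 degrees is outside the roughness domain")
  if (any(s < 0, na.rm = TRUE))
    stop("negative slope")
  eco_raster(1 / cos(s * pi / 180), g)
}
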