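#' Jenks natural-breaks classification (exact Fisher dynamic programming)
#'
#' Partitions a numeric sample into `k` ordered classes minimizing the
#' total within-class sum of squared deviations. The dynamic program runs
#' on the distinct values with multiplicity weights, which is exact and
#' guarantees that tied values never straddle a break. Samples larger
#' than `sample_cap` are reduced to `sample_cap` evenly spaced order
#' statistics (a deterministic stratified subsample, recorded in the
#' result) before the exact algorithm runs; the fitted breaks still
#' classify the full sample.
#'
#' @param x Numeric sample (length `>= k`, at least `k` distinct values).
#' @param k Number of classes (`>= 2`).
#' @param sample_cap Largest sample solved exactly without subsampling.
#' @return A `jenks_breaks` object: `k`, `breaks` (the `k - 1` class
#'   minima of classes `2..k`, strictly ascending), `ssd` (within-class
#'   sum of squares on the fitted sample), `gvf` (goodness of variance
#'   fit, `1 - ssd/total_ss`), `subsampled`, `sample_size`.
#' @seealso [jenks_classify()] to apply the fitted breaks.
#' @export
jenks_breaks <- function(x, k, sample_cap = 2000) {
  x <- x[!is.na(x)]
  if (k < 2) stop("k must be >= 2")
  n0 <- length(x)
  subsampled <- FALSE
  if (n0 > sample_cap) {
    x <- sort(x)[round(seq(1, n0, length.out = sample_cap))]
    subsampled <- TRUE
  }
  xs <- sort(x)
  u <- unique(xs)
  if (length(u) < k)
    stop(sprintf("cannot form %d classes from %d distinct value(s)",
                 k, length(u)))
  w <- as.vector(table(match(xs, u)))
  m <- length(u)
  cw <- cumsum(w)
  cs <- cumsum(w * u)
  cs2 <- cumsum(w * u^2)
  # weighted SSQ of distinct-value segment a..b (vectorized over a)
  seg_ssq <- function(a, b) {
    sw <- cw[b] - ifelse(a > 1L, cw[a - 1L], 0)
    s1 <- cs[b] - ifelse(a > 1L, cs[a - 1L], 0)
    s2 <- cs2[b] - ifelse(a > 1L, cs2[a - 1L], 0)
    pmax(s2 - s1^2 / sw, 0)
  }
  D <- matrix(Inf, k, m)   # D[c, i]: best SSD of u[1..i] in c classes
  B <- matrix(0L, k, m)    # first index of the last class at the optimum
  D[1, ] <- seg_ssq(rep(1L, m), seq_len(m))
  B[1, ] <- 1L
  for (cl in 2:k) {
    for (i in cl:m) {
      j <- cl:i  # candidate first index of class cl
      tot <- D[cl - 1L, j - 1L] + seg_ssq(j, i)
      best <- which.min(tot)
      D[cl, i] <- tot[best]
      B[cl, i] <- j[best]
    }
  }
  starts <- integer(k)
  i <- m
  for (cl in k:1) {
    starts[cl] <- B[cl, i]
    i <- starts[cl] - 1L
  }
  ssd <- D[k, m]
  tss <- seg_ssq(1L, m)
  structure(list(k = k, breaks = u[starts[-1]], ssd = ssd,
                 gvf = if (tss > 0) 1 - ssd / tss else 1,
                 subsampled = subsampled,
                 sample_size = length(xs)),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(sprintf("<jenks_breaks> k = %d, gvf = %.4f%s\n  breaks: %s\n",
              x$k, x$gvf, if (x$subsampled) " (fit on subsample)" else "",
              paste(signif(x$breaks, 6), collapse = ", ")))
  invisible(x)
}

#' Assign class indices from fitted Jenks breaks
#'
#' Classes are lower-closed at each break: value `v` falls in class
#' `m + 1` when `breaks[m] <= v < breaks[m + 1]`.
#'
#' @param x Numeric vector (or `eco_raster`).
#' @param breaks A `jenks_breaks` object or a numeric vector of ascending
#'   cut values.
#' @return Integer classes `1..k` in the shape of `x`.
#' @export
jenks_classify <- function(x, breaks) {
  b <- if (inherits(breaks, "jenks_breaks")) breaks$breaks else breaks
  cls <- findInterval(as.vector(as.matrix(x)), b) + 1L
  if (inherits(x, "eco_raster")) {
    g <- raster_grid(x)
    eco_raster(matrix(cls, g$nrows, g$ncols), g)
  } else cls
}
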