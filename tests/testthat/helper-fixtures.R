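# Shared fixtures and independent oracles, built in code at test time.

# A 1 x n chain of uniform resistance r, realized as the middle row of a
# 3 x n raster (the rest nodata), with single-cell patches at both ends.
chain_fixture <- function(n, r = 10) {
  spec <- grid_spec(3, n, 100)
  m <- matrix(NA_real_, 3, n)
  m[2, ] <- r
  lab <- matrix(0L, 3, n)
  lab[2, 1] <- 1L
  lab[2, n] <- 2L
  list(resistance = eco_raster(m, spec),
       labels = eco_raster(lab, spec), spec = spec)
}

# Two disjoint 1-cell-wide channels of equal length between shared
# terminals: rows 1 and 5 of a 5 x n raster carry resistance r, terminals
# span the full first/last column so both channels connect them.
parallel_fixture <- function(n, r = 10) {
  spec <- grid_spec(5, n, 100)
  m <- matrix(NA_real_, 5, n)
  m[1, ] <- r
  m[5, ] <- r
  m[, 1] <- r
  m[, n] <- r
  lab <- matrix(0L, 5, n)
  lab[, 1] <- 1L
  lab[, n] <- 2L
  list(resistance = eco_raster(m, spec),
       labels = eco_raster(lab, spec), spec = spec)
}

# Random small raster graph with two random single-cell patches.
random_graph_fixture <- function(nr, nc, seed, neighborhood = 8) {
  set.seed(seed)
  spec <- grid_spec(nr, nc, 100)
  m <- matrix(stats::runif(nr * nc, 5, 500), nr, nc)
  lab <- matrix(0L, nr, nc)
  cells <- sample.int(nr * nc, 2)
  lab[cells[1]] <- 1L
  lab[cells[2]] <- 2L
  build_graph(eco_raster(m, spec), eco_raster(lab, spec),
              neighborhood = neighborhood)
}

# Independent effective-resistance oracle: dense Laplacian pseudoinverse,
# R_eff = L+[s,s] + L+[t,t] - 2 L+[s,t].
reff_dense_oracle <- function(graph, source, target) {
  n <- graph$n_nodes
  L <- matrix(0, n, n)
  e <- graph$edges
  for (q in seq_len(nrow(e))) {
    i <- e$i[q]; j <- e$j[q]; c <- e$conductance[q]
    L[i, j] <- L[i, j] - c
    L[j, i] <- L[j, i] - c
    L[i, i] <- L[i, i] + c
    L[j, j] <- L[j, j] + c
  }
  Lp <- MASS::ginv(L)
  s <- graph$patch_node[as.character(source)]
  t <- graph$patch_node[as.character(target)]
  Lp[s, s] + Lp[t, t] - 2 * Lp[s, t]
}

# Exhaustive-partition oracle for the Jenks objective: minimum within-class
# SSD over every contiguous partition of the sorted sample into k classes.
jenks_brute_ssd <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ssq <- function(v) sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(n - 1L, k - 1L)
  for (q in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, q], n)
    tot <- 0
    for (cl in seq_len(k))
      tot <- tot + ssq(xs[(b[cl] + 1L):b[cl + 1L]])
    best <- min(best, tot)
  }
  best
}
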