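#' Build the conductance graph of a resistance raster
#'
#' The landscape becomes a resistive electrical network: every valid cell
#' is a node, neighbouring cells are joined by a resistor equal to the
#' mean of their two cell resistances (scaled by `sqrt(2)` on diagonals in
#' 8-neighbour mode), and all cells of one habitat patch are contracted
#' into a single zero-internal-resistance supernode, merging parallel
#' edges by conductance summation. Random-walking animals on this graph
#' behave like electrical current, which is what the pairwise solver
#' exploits.
#'
#' @param resistance Combined resistance `eco_raster` (positive; `NA` =
#'   nodata).
#' @param patch_labels Integer labeled raster from [rasterize_patches()]
#'   (0 = background), or `NULL` for a graph without terminals.
#' @param neighborhood 4 (rook) or 8 (queen, default).
#' @return A `conductance_graph`: node/edge structure, sparse Laplacian,
#'   cell-to-node index, patch supernode ids, and connected-component
#'   membership.
#' @export
build_graph <- function(resistance, patch_labels = NULL, neighborhood = 8) {
  g <- raster_grid(resistance)
  if (!neighborhood %in% c(4, 8)) stop("neighborhood must be 4 or 8")
  R <- as.matrix(resistance)
  if (any(R <= 0, na.rm = TRUE)) stop("resistances must be positive")
  if (is.null(patch_labels)) {
    lab <- matrix(0L, g$nrows, g$ncols)
  } else {
    stop_if_grid_mismatch(resistance, patch_labels)
    lab <- as.matrix(patch_labels)
    lab[is.na(lab)] <- 0L
  }
  valid <- !is.na(R)
  if (!any(valid)) stop("empty graph: the resistance raster is fully masked")
  patch_ids <- sort(unique(lab[valid & lab > 0L]))
  is_cell_node <- valid & lab == 0L
  node_of_cell <- matrix(NA_integer_, g$nrows, g$ncols)
  n_cell <- sum(is_cell_node)
  node_of_cell[is_cell_node] <- seq_len(n_cell)  # column-major, deterministic
  patch_node <- stats::setNames(n_cell + seq_along(patch_ids),
                                as.character(patch_ids))
  node_of_cell[valid & lab > 0L] <-
    patch_node[as.character(lab[valid & lab > 0L])]
  n_nodes <- n_cell + length(patch_ids)

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  ei <- ej <- cond <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    r1 <- seq_len(g$nrows - dr)
    c1 <- seq.int(max(1L, 1L - dc), min(g$ncols, g$ncols - dc))
    ia <- as.matrix(expand.grid(row = r1, col = c1))
    ib <- cbind(ia[, 1] + dr, ia[, 2] + dc)
    ok <- valid[ia] & valid[ib]
    ia <- ia[ok, , drop = FALSE]; ib <- ib[ok, , drop = FALSE]
    er <- (R[ia] + R[ib]) / 2
    if (dr != 0L && dc != 0L) er <- er * sqrt(2)
    na <- node_of_cell[ia]; nb <- node_of_cell[ib]
    keep <- na != nb  # drop intra-patch edges
    ei[[k]] <- pmin(na, nb)[keep]
    ej[[k]] <- pmax(na, nb)[keep]
    cond[[k]] <- 1 / er[keep]
  }
  ei <- unlist(ei); ej <- unlist(ej); cond <- unlist(cond)
  # upper-triangular conductance matrix; duplicate (parallel) edges sum
  A <- Matrix::sparseMatrix(i = ei, j = ej, x = cond,
                            dims = c(n_nodes, n_nodes))
  A <- A + Matrix::t(A)
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  deg <- Matrix::rowSums(A != 0)
  isolated <- patch_ids[deg[patch_node] == 0]
  if (length(isolated))
    warning("isolated patch(es) with no incident edge: ",
            paste(isolated, collapse = ", "))
  es <- Matrix::summary(Matrix::triu(A, 1))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = es$i, to = es$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes)))
  comp <- igraph::components(ig)$membership
  structure(list(spec = g, neighborhood = neighborhood, n_nodes = n_nodes,
                 n_cell_nodes = n_cell, L = L,
                 edges = data.frame(i = es$i, j = es$j, conductance = es$x),
                 node_of_cell = node_of_cell, labels = lab,
                 patch_ids = patch_ids, patch_node = patch_node,
                 isolated_patches = isolated, comp = as.integer(comp)),
            class = "conductance_graph")
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("<conductance_graph> %d nodes (%d patch supernodes), %d edges, %d-neighbourhood\n",
              x$n_nodes, length(x$patch_ids), nrow(x$edges), x$neighborhood))
  invisible(x)
}

#' Solve the circuit between one pair of patches
#'
#' One ampere is injected at the source supernode and the target is
#' grounded; the grounded graph Laplacian is solved by sparse Cholesky
#' factorization. The effective resistance is the potential difference
#' between the terminals divided by the injected current (I = V / R_eff),
#' and per-cell current density is half the sum of absolute currents on
#' the cell's incident edges; terminal supernode cells display the full
#' injected current. A pair in different connected components is returned
#' as unreachable (`R_eff = Inf`, zero current), not as an exception.
#'
#' @param graph A [build_graph()] result with patch supernodes.
#' @param source,target Patch ids.
#' @return A `pair_solution`: `reff`, `potentials` (per node, target at
#'   0), `current` (`eco_raster`), `unreachable`, and the Kirchhoff
#'   residual `kcl_residual` (max net current at non-terminal nodes).
#' @export
solve_pair <- function(graph, source, target) {
  stopifnot(inherits(graph, "conductance_graph"))
  if (source == target) stop("source and target patches must differ")
  sn <- graph$patch_node[as.character(source)]
  tn <- graph$patch_node[as.character(target)]
  if (is.na(sn) || is.na(tn))
    stop("unknown patch id: ", if (is.na(sn)) source else target)
  g <- graph$spec
  zero_map <- eco_raster(matrix(0, g$nrows, g$ncols), g)
  if (graph$comp[sn] != graph$comp[tn]) {
    return(structure(list(source = source, target = target, reff = Inf,
                          potentials = rep(NA_real_, graph$n_nodes),
                          current = zero_map, unreachable = TRUE,
                          kcl_residual = 0),
                     class = "pair_solution"))
  }
  incomp <- which(graph$comp == graph$comp[sn])
  keep <- setdiff(incomp, tn)
  b <- numeric(length(keep))
  b[match(sn, keep)] <- 1
  v_red <- Matrix::solve(graph$L[keep, keep, drop = FALSE], b)
  v <- numeric(graph$n_nodes)
  v[keep] <- as.vector(v_red)
  reff <- v[sn]

  e <- graph$edges
  ecur <- e$conductance * (v[e$i] - v[e$j])
  nodecur <- numeric(graph$n_nodes)
  acc <- rowsum(c(abs(ecur), abs(ecur)), c(e$i, e$j))
  nodecur[as.integer(rownames(acc))] <- 0.5 * acc[, 1]
  nodecur[c(sn, tn)] <- 1  # terminal supernodes carry the injected current

  net <- as.vector(graph$L %*% v)
  kcl <- max(abs(net[setdiff(incomp, c(sn, tn))]), 0)

  cur <- matrix(0, g$nrows, g$ncols)
  has_node <- !is.na(graph$node_of_cell)
  cur[has_node] <- nodecur[graph$node_of_cell[has_node]]
  pot <- rep(NA_real_, graph$n_nodes)
  pot[incomp] <- v[incomp]
  structure(list(source = source, target = target, reff = reff,
                 potentials = pot, current = eco_raster(cur, g),
                 unreachable = FALSE, kcl_residual = kcl),
            class = "pair_solution")
}

#' @export
print.pair_solution <- function(x, ...) {
  cat(sprintf("<pair_solution> patches %s -> %s: R_eff = %.6g%s\n",
              x$source, x$target, x$reff,
              if (x$unreachable) " (unreachable)" else ""))
  invisible(x)
}

#' Accumulate current density over patch pairs
#'
#' Solves every requested unordered patch pair and sums the per-cell
#' current-density maps into one cumulative map — the simulated intensity
#' of movement considering all possible paths between all patches.
#' Unreachable pairs contribute zero current and are reported, not
#' dropped silently.
#'
#' @param graph A [build_graph()] result.
#' @param pairs Two-column matrix of patch-id pairs, or `NULL` for all
#'   unordered pairs.
#' @param sources Optional patch-id vector restricting one endpoint (e.g.
#'   type-I patches only, for an initial-migration scenario); ignored when
#'   `pairs` is given.
#' @return A `current_map_result`: `current` (`eco_raster`), `reff`
#'   (symmetric matrix, `Inf` = unreachable), `n_pairs`, `unreachable`
#'   (data frame), `kcl_max`.
#' @export
accumulate_current <- function(graph, pairs = NULL, sources = NULL) {
  stopifnot(inherits(graph, "conductance_graph"))
  ids <- graph$patch_ids
  if (length(ids) < 2L)
    stop("need at least 2 patches to accumulate current")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2L))
    if (!is.null(sources)) {
      keep <- pairs[, 1] %in% sources | pairs[, 2] %in% sources
      pairs <- pairs[keep, , drop = FALSE]
    }
  }
  g <- graph$spec
  total <- matrix(0, g$nrows, g$ncols)
  reff <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(ids, ids))
  diag(reff) <- 0
  unreach <- list()
  kcl_max <- 0
  for (p in seq_len(nrow(pairs))) {
    sol <- solve_pair(graph, pairs[p, 1], pairs[p, 2])
    a <- as.character(pairs[p, 1]); b <- as.character(pairs[p, 2])
    reff[a, b] <- reff[b, a] <- sol$reff
    if (sol$unreachable) {
      unreach[[length(unreach) + 1L]] <- pairs[p, ]
    } else {
      total <- total + as.matrix(sol$current)
      kcl_max <- max(kcl_max, sol$kcl_residual)
    }
  }
  unreach <- if (length(unreach)) {
    do.call(rbind, lapply(unreach, function(u)
      data.frame(source = u[1], target = u[2])))
  } else data.frame(source = integer(), target = integer())
  structure(list(current = eco_raster(total, g), reff = reff,
                 n_pairs = nrow(pairs), unreachable = unreach,
                 kcl_max = kcl_max),
            class = "current_map_result")
}

#' @export
print.current_map_result <- function(x, ...) {
  cat(sprintf("<current_map_result> %d pair(s), %d unreachable, max current %.6g\n",
              x$n_pairs, nrow(x$unreachable), max(as.matrix(x$current))))
  invisible(x)
}
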