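test_that("graph construction follows the mean-resistance edge rule", {
  spec <- grid_spec(2, 3, 100)
  m <- matrix(c(10, NA, 30, NA, 50, NA), 2, 3)  # row 1: 10, 30, 50
  g <- build_graph(eco_raster(m, spec), neighborhood = 4)
  expect_equal(g$n_nodes, 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sort(g$edges$conductance), sort(c(1 / 20, 1 / 40)))
  # uniform 1xN path: every edge conductance 1/r
  u <- matrix(NA_real_, 2, 4); u[1, ] <- 8
  gu <- build_graph(eco_raster(u, spec = grid_spec(2, 4, 100)),
                    neighborhood = 4)
  expect_true(all(abs(gu$edges$conductance - 1 / 8) < 1e-12))
  expect_error(build_graph(eco_raster(matrix(NA_real_, 2, 3), spec)),
               "fully masked")
  expect_error(build_graph(eco_raster(matrix(-1, 2, 3), spec)), "positive")
})

test_that("diagonal edges carry the sqrt(2) distance penalty", {
  spec <- grid_spec(2, 2, 100)
  g4 <- build_graph(eco_raster(matrix(10, 2, 2), spec), neighborhood = 4)
  g8 <- build_graph(eco_raster(matrix(10, 2, 2), spec), neighborhood = 8)
  expect_equal(nrow(g4$edges), 4L)
  expect_equal(nrow(g8$edges), 6L)
  expect_setequal(round(g8$edges$conductance, 10),
                  round(c(rep(1 / 10, 4), rep(1 / (10 * sqrt(2)), 2)), 10))
})

test_that("patch contraction yields one supernode with merged parallel edges", {
  spec <- grid_spec(5, 5, 100)
  lab <- matrix(0L, 5, 5)
  lab[2:4, 2:4] <- 1L  # 3x3 patch block
  lab[1, 1] <- 2L
  g <- build_graph(eco_raster(matrix(10, 5, 5), spec),
                   eco_raster(lab, spec), neighborhood = 4)
  expect_equal(g$n_nodes, 25L - 9L - 1L + 2L)
  pn <- g$patch_node[["1"]]
  deg <- sum(g$edges$i == pn | g$edges$j == pn)
  # distinct outside orthogonal neighbours of the 3x3 block: 12 cells
  expect_equal(deg, 12L)
})

test_that("series and parallel closed forms hold (4-neighbourhood)", {
  for (n in c(5, 9, 20)) {
    fx <- chain_fixture(n, r = 10)
    g <- build_graph(fx$resistance, fx$labels, neighborhood = 4)
    sol <- solve_pair(g, 1, 2)
    expect_equal(sol$reff, (n - 1) * 10, tolerance = 1e-10)
    expect_lt(sol$kcl_residual, 1e-8)
    # Ohm's law self-consistency: injected current x R_eff = terminal gap
    s <- g$patch_node[["1"]]; t <- g$patch_node[["2"]]
    expect_equal(sol$potentials[s] - sol$potentials[t], 1 * sol$reff,
                 tolerance = 1e-10)
  }
  fx <- parallel_fixture(12, r = 10)
  g <- build_graph(fx$resistance, fx$labels, neighborhood = 4)
  sol <- solve_pair(g, 1, 2)
  chain <- solve_pair(build_graph(chain_fixture(12, 10)$resistance,
                                  chain_fixture(12, 10)$labels,
                                  neighborhood = 4), 1, 2)
  expect_equal(sol$reff, chain$reff / 2, tolerance = 1e-10)
})

test_that("sparse solves match the dense pseudoinverse oracle", {
  shapes <- cbind(nr = rep(c(5, 7, 9), length.out = 50),
                  nc = rep(c(8, 9, 11), length.out = 50))
  for (q in 1:50) {
    g <- random_graph_fixture(shapes[q, 1], shapes[q, 2], seed = 100 + q,
                              neighborhood = if (q %% 2) 8 else 4)
    expect_lte(g$n_nodes, 100L)
    sol <- solve_pair(g, 1, 2)
    oracle <- reff_dense_oracle(g, 1, 2)
    expect_equal(sol$reff, oracle, tolerance = 1e-8)
    expect_lt(sol$kcl_residual, 1e-8)
  }
})

test_that("pair solutions are reciprocal and terminals carry the injected current", {
  g <- random_graph_fixture(8, 8, seed = 11)
  a <- solve_pair(g, 1, 2)
  b <- solve_pair(g, 2, 1)
  expect_equal(a$reff, b$reff, tolerance = 1e-12)
  expect_equal(as.matrix(a$current), as.matrix(b$current), tolerance = 1e-9)
  lab <- g$labels
  expect_true(all(abs(as.matrix(a$current)[lab > 0] - 1) < 1e-12))
})

test_that("raising one cell's resistance never lowers effective resistance", {
  for (seed in 1:8) {
    set.seed(seed)
    spec <- grid_spec(10, 10, 100)
    m <- matrix(stats::runif(100, 10, 200), 10, 10)
    lab <- matrix(0L, 10, 10); lab[1, 1] <- 1L; lab[10, 10] <- 2L
    base <- solve_pair(build_graph(eco_raster(m, spec),
                                   eco_raster(lab, spec)), 1, 2)$reff
    i <- sample(setdiff(1:100, c(1, 100)), 1)
    m2 <- m; m2[i] <- m2[i] * 10
    up <- solve_pair(build_graph(eco_raster(m2, spec),
                                 eco_raster(lab, spec)), 1, 2)$reff
    expect_gte(up, base - 1e-10)
  }
})

test_that("disconnected pairs are reported unreachable with zero current", {
  spec <- grid_spec(3, 5, 100)
  m <- matrix(10, 3, 5); m[, 3] <- NA  # wall splits the grid
  lab <- matrix(0L, 3, 5); lab[2, 1] <- 1L; lab[2, 5] <- 2L
  g <- build_graph(eco_raster(m, spec), eco_raster(lab, spec))
  sol <- solve_pair(g, 1, 2)
  expect_true(sol$unreachable)
  expect_identical(sol$reff, Inf)
  expect_true(all(as.matrix(sol$current) == 0))
  acc <- accumulate_current(g)
  expect_equal(nrow(acc$unreachable), 1L)
  expect_true(all(as.matrix(acc$current) == 0))
})

test_that("cumulative current is the cell-wise sum over pairs", {
  spec <- grid_spec(7, 7, 100)
  set.seed(3)
  m <- matrix(stats::runif(49, 10, 100), 7, 7)
  lab <- matrix(0L, 7, 7)
  lab[1, 1] <- 1L; lab[7, 7] <- 2L; lab[1, 7] <- 3L
  g <- build_graph(eco_raster(m, spec), eco_raster(lab, spec))
  acc <- accumulate_current(g)
  expect_equal(acc$n_pairs, 3L)
  total <- as.matrix(solve_pair(g, 1, 2)$current) +
    as.matrix(solve_pair(g, 1, 3)$current) +
    as.matrix(solve_pair(g, 2, 3)$current)
  expect_equal(as.matrix(acc$current), total, tolerance = 1e-12)
  expect_equal(unname(acc$reff["1", "2"]), solve_pair(g, 1, 2)$reff)
  restricted <- accumulate_current(g, sources = 1)
  expect_equal(restricted$n_pairs, 2L)
  expect_error(accumulate_current(build_graph(eco_raster(m, spec))),
               "at least 2")
})

test_that("the channel concentrates the cumulative current", {
  sc <- channel_scene(seed = 1)
  lab <- rasterize_patches(sc$patches, sc$spec)
  rs <- resistance_surface(sc$dem, sc$landuse)
  g <- build_graph(rs$resistance, lab)
  acc <- accumulate_current(g)
  cur <- as.matrix(acc$current)
  cur[as.matrix(lab) > 0] <- 0  # terminals aside, the max must be in-channel
  expect_true(as.matrix(sc$channel_mask)[which.max(cur)])
})
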