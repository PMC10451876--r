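spec50 <- grid_spec(50, 50, 100)

test_that("elevation generator honours range, flat limit, and determinism", {
  d <- generate_dem(spec50, relief = 3000, base_elevation = 700,
                    smoothness = 10, seed = 42)
  expect_gte(min(d), 700)
  expect_lte(max(d), 3700)
  # frozen regression values for this seed
  expect_equal(mean(as.matrix(d)), 1373.456518, tolerance = 1e-8)
  expect_equal(d[25, 25], 1346.289753, tolerance = 1e-6)
  d2 <- generate_dem(spec50, relief = 3000, base_elevation = 700,
                     smoothness = 10, seed = 42)
  expect_identical(as.matrix(d), as.matrix(d2))
  flat <- generate_dem(spec50, relief = 0, base_elevation = 500, seed = 1)
  expect_true(all(as.matrix(flat) == 500))
  expect_error(generate_dem(spec50, relief = -1, seed = 1), "relief")
})

test_that("smoothness monotonically increases spatial autocorrelation", {
  lag1 <- function(s) {
    d <- as.matrix(generate_dem(spec50, relief = 1000, smoothness = s,
                                seed = 7))
    stats::cor(as.vector(d[-1, ]), as.vector(d[-50, ]))
  }
  acs <- vapply(c(1, 4, 10, 20), lag1, numeric(1))
  expect_true(all(diff(acs) > 0))
  # neighbour differences small relative to relief once smoothness >> 1
  d <- as.matrix(generate_dem(spec50, relief = 1000, smoothness = 10,
                              seed = 7))
  expect_lt(mean(abs(diff(d))), 0.02 * 1000)
})

test_that("land-use mosaics match requested class frequencies and are contiguous", {
  spec <- grid_spec(200, 200, 100)
  w <- c(shrub_grass = 0.5, forest_dry = 0.5)
  lu <- generate_landuse(spec, class_weights = w, seed = 1)
  freq <- table(as.vector(as.matrix(lu))) / (200 * 200)
  expect_true(all(abs(freq - 0.5) < 0.05))
  # contiguity: most orthogonal neighbours share a class (not salt-and-pepper)
  m <- as.matrix(lu)
  agree <- mean(m[-1, ] == m[-200, ])
  expect_gt(agree, 0.9)
  expect_identical(as.matrix(generate_landuse(spec, class_weights = w, seed = 1)),
                   m)
  single <- generate_landuse(spec50, class_weights = c(swamp_rural = 1), seed = 2)
  expect_true(all(as.matrix(single) == ecocircuit:::landuse_code("swamp_rural")))
  expect_error(generate_landuse(spec50, class_weights = c(desert = 1), seed = 1),
               "unknown land-use group")
  expect_error(generate_landuse(spec50,
                                class_weights = c(shrub_grass = 0.6,
                                                  forest_dry = 0.6), seed = 1),
               "sum to 1")
})

test_that("default mosaic covers every land-use group on a modest grid", {
  lu <- generate_landuse(grid_spec(20, 20, 100), seed = 3)
  expect_setequal(unique(as.vector(as.matrix(lu))), landuse_legend()$code)
})

test_that("patch generator places disjoint labeled disks or fails loudly", {
  ps <- generate_patches(spec50, n_type1 = 2, n_type2 = 3, radius_cells = 3,
                         seed = 1)
  expect_equal(length(ps), 5L)
  expect_equal(sum(ps$info$type == "I"), 2L)
  cells <- do.call(rbind, ps$geometry)
  expect_equal(anyDuplicated(cells), 0L)  # pairwise disjoint cell sets
  ps2 <- generate_patches(spec50, 2, 3, 3, seed = 1)
  expect_identical(ps$geometry, ps2$geometry)
  expect_error(generate_patches(spec50, n_type1 = 0, seed = 1), "type-I")
  expect_error(generate_patches(spec50, n_type1 = 40, n_type2 = 0,
                                radius_cells = 5, seed = 1), "25%")
  expect_error(generate_patches(grid_spec(16, 16, 100), n_type1 = 4,
                                n_type2 = 0, radius_cells = 2, seed = 1,
                                max_attempts = 3),
               "could not place patch 4")
})

test_that("warning points follow the current distribution", {
  spec <- grid_spec(10, 10, 100)
  conc <- matrix(0, 10, 10)
  conc[4, 7] <- 5
  pts <- generate_warning_points(eco_raster(conc, spec), 25, seed = 1)
  expect_true(all(pts$row == 4 & pts$col == 7))
  # uniform current: cell frequencies consistent with uniform at alpha 0.01
  unif <- eco_raster(matrix(1, 10, 10), spec)
  pts <- generate_warning_points(unif, 10000, seed = 2)
  counts <- table(factor(paste(pts$row, pts$col),
                         levels = paste(rep(1:10, 10), rep(1:10, each = 10))))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  expect_identical(generate_warning_points(unif, 50, seed = 9),
                   generate_warning_points(unif, 50, seed = 9))
  expect_error(generate_warning_points(eco_raster(matrix(0, 10, 10), spec),
                                       5, seed = 1), "all-zero")
})

test_that("the channel scene plants a connected low-resistance corridor", {
  sc <- channel_scene(seed = 1)
  expect_s3_class(sc, "synthetic_scene")
  expect_equal(length(sc$patches), 2L)
  expect_setequal(sc$patches$info$type, c("I", "II"))
  ch <- as.matrix(sc$channel_mask)
  expect_true(all(as.matrix(sc$landuse)[ch] ==
                    ecocircuit:::landuse_code("shrub_grass")))
  # narrow cells are part of the channel and one cell wide
  expect_true(all(ch[sc$narrow_cells]))
  for (cl in sc$narrow_cells[, "col"]) expect_equal(sum(ch[, cl]), 1L)
})
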