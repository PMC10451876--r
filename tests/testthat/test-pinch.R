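# shared solved channel scene
scene <- channel_scene(seed = 1)
labels <- rasterize_patches(scene$patches, scene$spec)
rsurf <- resistance_surface(scene$dem, scene$landuse)
cmap <- accumulate_current(build_graph(rsurf$resistance, labels))

test_that("patch buffers are exact Euclidean discs around type-I cells", {
  spec <- grid_spec(9, 9, 100)
  ps <- patch_set(c(1, 2), c("I", "II"),
                  list(cbind(5L, 5L), cbind(1L, 1L)))
  lab <- rasterize_patches(ps, spec)
  b0 <- buffer_patches(lab, ps, radius_m = 0)
  expect_equal(which(as.matrix(b0)), which(as.matrix(lab) == 1L))
  b2 <- buffer_patches(lab, ps, radius_m = 200)  # 2-cell radius
  expect_equal(sum(as.matrix(b2)), 13L)  # discrete disc of radius 2
  sizes <- vapply(c(0, 100, 200, 400, 800), function(r)
    sum(as.matrix(buffer_patches(lab, ps, radius_m = r))), numeric(1))
  expect_true(all(diff(sizes) > 0))
  only2 <- patch_set(1, "II", list(cbind(5L, 5L)))
  expect_error(buffer_patches(rasterize_patches(only2, spec), only2),
               "no patch of type")
})

test_that("pinch points land on the channel's narrowest cross-section", {
  buf <- buffer_patches(labels, scene$patches, radius_m = 10000)
  pin <- extract_pinch_points(cmap, buf, labels, landuse = scene$landuse)
  pm <- as.matrix(pin$mask)
  expect_gt(sum(pm), 0)
  expect_true(all(as.matrix(buf)[pm]))  # pinch subset of buffer
  hits <- which(pm, arr.ind = TRUE)
  narrow <- scene$narrow_cells
  expect_true(all(paste(hits[, 1], hits[, 2]) %in%
                    paste(narrow[, "row"], narrow[, "col"])))
  expect_equal(pin$total_area_km2, sum(pm) * 0.04)
  expect_equal(sum(pin$composition$percent[
    pin$composition$group != "forest_grassland"]), 100, tolerance = 1e-9)
})

test_that("uniform in-buffer current yields an empty pinch mask with a warning", {
  spec <- grid_spec(8, 8, 100)
  ps <- patch_set(1, "I", list(cbind(4L, 4L)))
  lab <- rasterize_patches(ps, spec)
  buf <- buffer_patches(lab, ps, radius_m = 300)
  flat <- eco_raster(matrix(0.5, 8, 8), spec)
  expect_warning(pin <- extract_pinch_points(flat, buf, lab),
                 "distinct values")
  expect_equal(sum(as.matrix(pin$mask)), 0L)
  none <- eco_raster(matrix(0, 8, 8), spec)
  expect_warning(extract_pinch_points(none, buf, lab), "no positive")
})

test_that("point validation detects a planted current-biased signal", {
  buf <- buffer_patches(labels, scene$patches, radius_m = 10000)
  pin <- extract_pinch_points(cmap, buf, labels)
  # all points exactly on pinch cells: perfect overlap at zero tolerance
  hits <- which(as.matrix(pin$mask), arr.ind = TRUE)
  cc <- cell_centers(scene$spec, hits[, 1], hits[, 2])
  perfect <- validate_points(pin, cc, tolerance_cells = 0, n_null = 50,
                             seed = 1)
  expect_equal(perfect$fraction, 1)
  # current-biased points beat the uniform null
  pts <- generate_warning_points(cmap$current, 200, seed = 2)
  v <- validate_points(pin, pts, tolerance_cells = 2, n_null = 400, seed = 3)
  expect_gt(v$fraction, v$null_q95)
  expect_lt(v$p_value, 0.05)
  # uniform points look like the null
  set.seed(4)
  runif_pts <- data.frame(x = stats::runif(300, 0, 100 * 200),
                          y = stats::runif(300, 0, 100 * 200))
  vu <- validate_points(pin, runif_pts, tolerance_cells = 2, n_null = 400,
                        seed = 5)
  expect_gt(vu$p_value, 0.05)
  near <- sum(as.matrix(EBImage::distmap(
    matrix(as.numeric(!as.matrix(pin$mask)), 100, 100))) <= 2)
  expect_lt(abs(vu$fraction - near / 1e4), 3 * sqrt(near / 1e4 / 300))
  expect_error(validate_points(pin, cc[0, ], n_null = 10), "empty point")
})
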