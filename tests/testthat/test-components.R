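test_that("separated objects get distinct labels; boundary contact is flagged", {
  g <- voxel_grid(c(10, 10, 50), c(80, 40, 16))
  m <- array(FALSE, g$dims)
  v1 <- voxelize_shape(shape_sphere(0.08, center = c(0.2, 0.2, 0.4)), g)
  v2 <- voxelize_shape(shape_sphere(0.08, center = c(0.6, 0.2, 0.4)), g)
  m[v1$labels > 0 | v2$labels > 0] <- TRUE
  cc <- label_components(m, g)
  tab <- attr(cc, "components")
  expect_identical(nrow(tab), 2L)
  expect_false(any(tab$touches_boundary))
  # clip one object at the x = 0 face
  m[1, 18:22, 7:9] <- TRUE
  m[2, 18:22, 7:9] <- TRUE
  cc2 <- label_components(m, g)
  tab2 <- attr(cc2, "components")
  expect_identical(sum(tab2$touches_boundary), 1L)
})

test_that("26-connectivity joins voxels sharing only a corner", {
  g <- voxel_grid(c(10, 10, 10), c(4, 4, 4))
  m <- array(FALSE, g$dims)
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE          # corner contact only
  expect_identical(nrow(attr(label_components(m, g), "components")), 1L)
  m2 <- array(FALSE, g$dims)
  m2[1, 1, 1] <- TRUE
  m2[3, 3, 3] <- TRUE         # gap of one voxel
  expect_identical(nrow(attr(label_components(m2, g), "components")), 2L)
})

test_that("an empty mask yields an empty labeling, not an error", {
  g <- voxel_grid(c(10, 10, 10), c(5, 5, 5))
  cc <- label_components(array(FALSE, g$dims), g)
  expect_identical(nrow(attr(cc, "components")), 0L)
  expect_true(all(cc$labels == 0L))
})

test_that("component volume applies the physical voxel size", {
  # 200,000 voxels at 10 x 10 x 50 nm are exactly 1 um^3
  g <- voxel_grid(c(10, 10, 50), c(100, 100, 20))
  lab <- array(1L, g$dims)
  v <- label_volume(lab, g)
  expect_equal(component_volume(v, 1), 1.0)
  # a single voxel is 5e-6 um^3
  g1 <- voxel_grid(c(10, 10, 50), c(3, 3, 3))
  lab1 <- array(0L, g1$dims)
  lab1[2, 2, 2] <- 1L
  expect_equal(component_volume(label_volume(lab1, g1), 1), 5e-6)
  expect_error(component_volume(label_volume(lab1, g1), 7), "not present")
})

test_that("single-voxel components fall back to the voxel box area with a warning", {
  g <- voxel_grid(c(10, 10, 50), c(3, 3, 3))
  lab <- array(0L, g$dims)
  lab[2, 2, 2] <- 1L
  v <- label_volume(lab, g)
  expect_warning(sa <- component_surface_area(v, 1), "single-voxel")
  expect_equal(sa, 2 * (0.01 * 0.01 + 0.01 * 0.05 + 0.01 * 0.05))
})
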