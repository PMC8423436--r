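test_that("sphere surface area is recovered within 5% on the anisotropic grid", {
  g <- voxel_grid(c(10, 10, 50), c(120, 120, 26))
  v <- voxelize_shape(shape_sphere(0.5, center = c(0.6, 0.6, 0.65)), g)
  sa <- component_surface_area(v, 1)
  expect_equal(sa, 4 * pi * 0.25, tolerance = 0.05)
})

test_that("an axis-aligned box measures its closed-form area with smoothing off", {
  g <- voxel_grid(c(10, 10, 50), c(40, 30, 20))
  lab <- array(0L, g$dims)
  lab[6:35, 6:25, 6:15] <- 1L     # 30 x 20 x 10 voxels = 0.3 x 0.2 x 0.5 um
  v <- label_volume(lab, g)
  a <- 0.3; b <- 0.2; cc <- 0.5
  sa <- component_surface_area(v, 1, smooth = FALSE)
  expect_equal(sa, 2 * (a * b + b * cc + a * cc), tolerance = 0.05)
})

test_that("surface area scales as the square of an isotropic rescale", {
  lab <- array(0L, c(24, 24, 12))
  lab[6:18, 6:18, 4:9] <- 1L
  v1 <- label_volume(lab, voxel_grid(c(10, 10, 50), c(24, 24, 12)))
  v2 <- label_volume(lab, voxel_grid(c(20, 20, 100), c(24, 24, 12)))
  expect_equal(component_surface_area(v2, 1), 4 * component_surface_area(v1, 1),
               tolerance = 1e-12)
})

test_that("mesh-enclosed volume agrees with the voxel count within 3%", {
  g <- voxel_grid(c(10, 10, 50), c(140, 130, 26))
  for (s in list(shape_sphere(0.5, center = c(0.6, 0.6, 0.65)),
                 shape_capsule(0.3, 0.6, center = c(0.65, 0.6, 0.65)))) {
    v <- voxelize_shape(s, g)
    m <- extract_mesh(v, 1)
    expect_equal(mesh_volume(m), component_volume(v, 1), tolerance = 0.03,
                 label = paste("mesh volume of", s$kind))
  }
})

test_that("topology classification separates spheres from donuts", {
  g <- voxel_grid(c(10, 10, 50), c(200, 200, 16))
  vt <- voxelize_shape(shape_torus(0.5, 0.15, center = c(1, 1, 0.4)), g)
  topo <- classify_topology(extract_mesh(vt, 1))
  expect_identical(topo$genus, 1L)
  expect_true(topo$donut)
  gs <- voxel_grid(c(10, 10, 50), c(90, 90, 20))
  vs <- voxelize_shape(shape_sphere(0.35, center = c(0.45, 0.45, 0.5)), gs)
  topo_s <- classify_topology(extract_mesh(vs, 1))
  expect_identical(topo_s$genus, 0L)
  expect_false(topo_s$donut)
  # a broken mesh has undefined topology
  m <- extract_mesh(vs, 1)
  m$faces <- m$faces[-1, , drop = FALSE]
  expect_true(is.na(classify_topology(m)$genus))
})
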