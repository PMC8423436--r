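test_that("the complexity index reproduces closed-form values", {
  # sphere: the global minimum 9/(4 pi)
  expect_equal(mci(4 * pi, 4 * pi / 3), sphere_mci, tolerance = 1e-12)
  # torus: SA^3/(16 pi^2 V^2) collapses algebraically to R/r
  R <- 0.5; r <- 0.1
  expect_equal(mci(4 * pi^2 * R * r, 2 * pi^2 * R * r^2), 5, tolerance = 1e-12)
  # capsule r = 0.1, L = 1.0
  cp <- shape_capsule(0.1, 1)
  expect_equal(mci(analytic_surface_area(cp), analytic_volume(cp)), 2.141,
               tolerance = 0.001 / 2.141)
  expect_error(mci(0, 1), "positive")
  expect_error(mci(1, -1), "positive")
})

test_that("MCI is invariant under isotropic scaling of the solid", {
  for (k in c(0.1, 1, 7)) {
    expect_equal(mci(4 * pi * k^2, 4 * pi * k^3 / 3), sphere_mci, tolerance = 1e-12)
  }
})

test_that("measured sphere MCI stays near the spherical lower bound", {
  g <- voxel_grid(c(10, 10, 50), c(120, 120, 26))
  v <- voxelize_shape(shape_sphere(0.5, center = c(0.6, 0.6, 0.65)), g)
  row <- measure_stack(v)
  expect_equal(row$MCI, sphere_mci, tolerance = 0.1)
  expect_gte(row$MCI, 0.68)   # bound minus discretization slack
  expect_identical(row$genus, 0L)
})

test_that("doubling all spacing components leaves measured MCI unchanged", {
  lab <- array(0L, c(40, 40, 18))
  lab[8:32, 8:32, 5:14] <- 1L
  v1 <- label_volume(lab, voxel_grid(c(10, 10, 50), c(40, 40, 18)))
  v2 <- label_volume(lab, voxel_grid(c(20, 20, 100), c(40, 40, 18)))
  expect_equal(measure_stack(v1)$MCI, measure_stack(v2)$MCI, tolerance = 0.02)
})

test_that("measured torus MCI tracks the aspect ratio", {
  r <- 0.25; A <- 5; R <- A * r
  ext <- 2 * (R + r) + 0.3
  g <- voxel_grid(c(10, 10, 50), c(ceiling(ext / 0.01), ceiling(ext / 0.01), 16))
  ctr <- g$dims * c(10, 10, 50) / 2000
  v <- voxelize_shape(shape_torus(R, r, center = ctr), g)
  row <- measure_stack(v)
  expect_equal(row$MCI, A, tolerance = 0.1)
  expect_identical(row$genus, 1L)
})
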