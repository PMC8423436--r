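test_that("closed-form volume and surface area match textbook values", {
  s <- shape_sphere(0.5)
  expect_equal(analytic_volume(s), 4 / 3 * pi * 0.125)
  expect_equal(analytic_surface_area(s), 4 * pi * 0.25)
  cp <- shape_capsule(r = 0.1, L = 1)
  expect_equal(analytic_volume(cp), pi * 0.01 * 1 + 4 / 3 * pi * 0.001)
  expect_equal(analytic_surface_area(cp), 2 * pi * 0.1 + 4 * pi * 0.01)
  to <- shape_torus(R = 0.5, r = 0.1)
  expect_equal(analytic_volume(to), 2 * pi^2 * 0.5 * 0.01)
  expect_equal(analytic_surface_area(to), 4 * pi^2 * 0.5 * 0.1)
  bt <- shape_branched_tube(r = 0.1, trunk_length = 1)
  expect_true(is.na(analytic_volume(bt)))
  expect_true(is.na(analytic_surface_area(bt)))
})

test_that("invalid shape dimensions are rejected", {
  expect_error(shape_sphere(-1), "positive")
  expect_error(shape_torus(R = 0.1, r = 0.2), "R > r")
  expect_error(shape_sphere(1, axis = c(0, 0, 0)), "nonzero")
})

test_that("voxel-count volume of a sphere converges to the closed form", {
  g <- voxel_grid(c(10, 10, 50), c(120, 120, 26))
  v <- voxelize_shape(shape_sphere(0.5, center = c(0.6, 0.6, 0.65)), g)
  expect_equal(component_volume(v, 1), 4 / 3 * pi * 0.125, tolerance = 0.02)
})

test_that("a shape thinner than the grid resolution still sets its center voxel", {
  g <- voxel_grid(c(10, 10, 50), c(30, 30, 10))
  v <- voxelize_shape(shape_sphere(0.02, center = c(0.15, 0.15, 0.25)), g)
  expect_gte(sum(v$labels == 1L), 1)
})

test_that("shapes exceeding the grid bounds are rejected, never clipped", {
  g <- voxel_grid(c(10, 10, 50), c(40, 40, 10))
  expect_error(voxelize_shape(shape_sphere(0.3, center = c(0.2, 0.2, 0.25)), g),
               "does not fit")
  # an in-bounds shape must leave every face untouched
  v <- voxelize_shape(shape_sphere(0.1, center = c(0.2, 0.2, 0.25)), g)
  lab <- v$labels
  expect_true(all(lab[1, , ] == 0L) && all(lab[dim(lab)[1], , ] == 0L) &&
              all(lab[, 1, ] == 0L) && all(lab[, dim(lab)[2], ] == 0L) &&
              all(lab[, , 1] == 0L) && all(lab[, , dim(lab)[3]] == 0L))
})

test_that("voxelization agrees with the closed form for well-resolved solids", {
  # finest-dimension radius >= 15 voxels for each kind
  g <- voxel_grid(c(10, 10, 10), c(160, 160, 160))
  shapes <- list(sphere = shape_sphere(0.4, center = c(0.8, 0.8, 0.8)),
                 capsule = shape_capsule(0.25, 0.7, center = c(0.8, 0.8, 0.8)),
                 torus = shape_torus(0.45, 0.2, center = c(0.8, 0.8, 0.8)))
  for (nm in names(shapes)) {
    v <- voxelize_shape(shapes[[nm]], g)
    expect_equal(component_volume(v, 1), analytic_volume(shapes[[nm]]),
                 tolerance = 0.02, label = paste(nm, "voxel volume"))
  }
})

test_that("population sampling is deterministic and hits the configured mean", {
  cfg <- population_config(200, 0.27, cv = 0.8, seed = 7)
  s1 <- sample_population(cfg)
  s2 <- sample_population(cfg)
  expect_identical(s1, s2)
  vols <- vapply(s1, function(s) attr(s, "target_volume_um3"), numeric(1))
  expect_equal(mean(vols), 0.27, tolerance = 0.1)
  # single-kind mix
  one <- sample_population(population_config(1, 0.1, shape_mix = c(sphere = 1), seed = 1))
  expect_length(one, 1)
  expect_identical(one[[1]]$kind, "sphere")
})

test_that("unnormalizable shape mixes are configuration errors", {
  expect_error(population_config(5, 0.1, shape_mix = c(sphere = 0)), "normalizable")
  expect_error(population_config(5, 0.1, shape_mix = c(sphere = -1, torus = 2)),
               "normalizable")
  expect_error(population_config(5, 0.1, shape_mix = c(cube = 1)), "kinds")
})

test_that("volume-law truncation redraws the upper tail only", {
  cfg <- population_config(500, 0.19, cv = 0.8, max_volume_um3 = 1.2, seed = 5)
  vols <- vapply(sample_population(cfg), function(s) attr(s, "target_volume_um3"),
                 numeric(1))
  expect_true(all(vols <= 1.2))
  expect_equal(mean(vols), 0.19, tolerance = 0.1)
})
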