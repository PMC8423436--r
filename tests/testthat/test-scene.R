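test_that("an axon scene records its construction ground truth", {
  g <- voxel_grid(c(100, 100, 100), c(160, 24, 24))
  sc <- build_compartment_scene("axon", population_config(5, 0.12, seed = 2), g,
                                geometry = list(radius_um = 0.4))
  expect_equal(sc$manifest$compartment$diameter_um, 0.8)
  expect_identical(nrow(sc$manifest$objects), 5L)
  # every object labeled exactly once, ids unique and positive
  expect_identical(anyDuplicated(sc$manifest$objects$label), 0L)
  expect_true(all(sc$manifest$objects$label >= 3L))
  present <- sort(unique(sc$volume$labels[sc$volume$labels > 2L]))
  expect_identical(as.integer(present), sort(sc$manifest$objects$label))
})

test_that("generated objects never touch a grid face and never overlap", {
  g <- voxel_grid(c(100, 100, 100), c(200, 26, 26))
  sc <- build_compartment_scene("dendrite", population_config(12, 0.2, seed = 9), g)
  lab <- sc$volume$labels
  faces <- c(lab[1, , ], lab[dim(lab)[1], , ], lab[, 1, ], lab[, dim(lab)[2], ],
             lab[, , 1], lab[, , dim(lab)[3]])
  expect_true(all(faces <= 1L))  # only plain compartment may approach faces
  expect_true(all(!attr(label_components(array(lab > 2L, dim(lab)), g),
                        "components")$touches_boundary))
  # voxel counts in manifest match the label field (no overwrites)
  counts <- table(lab[lab > 2L])
  expect_equal(as.integer(counts[as.character(sc$manifest$objects$label)]),
               round(sc$manifest$objects$voxel_volume_um3 / voxel_volume_um3(g)))
})

test_that("the soma partition holds voxel-exactly by construction", {
  g <- voxel_grid(c(100, 100, 100), c(60, 52, 52))
  sc <- build_compartment_scene("soma", population_config(15, 0.19, seed = 4), g,
                                geometry = list(semi_axes_um = c(2.8, 2.3, 2.3),
                                                nucleus_scale = 0.55))
  comp <- summarize_compartment(sc$volume)
  expect_equal(comp$nucleus_volume_um3 + comp$cytoplasm_volume_um3 +
                 comp$mvd * comp$compartment_volume_um3,
               comp$compartment_volume_um3, tolerance = 1e-9)
  expect_equal(comp$frac_nucleus + comp$frac_cytoplasm + comp$frac_mito, 1,
               tolerance = 1e-12)
  expect_true(comp$mvd >= 0 && comp$mvd <= 1)
})

test_that("identical config and seed give identical scenes and manifests", {
  g <- voxel_grid(c(100, 100, 100), c(160, 24, 24))
  cfg <- population_config(8, 0.12, seed = 5)
  a <- build_compartment_scene("axon", cfg, g)
  b <- build_compartment_scene("axon", cfg, g)
  expect_identical(a$volume$labels, b$volume$labels)
  expect_identical(a$manifest, b$manifest)
})

test_that("group means move in the configured direction", {
  g <- voxel_grid(c(100, 100, 100), c(420, 26, 26))
  den <- build_compartment_scene("dendrite", population_config(50, 0.27, seed = 21),
                                 voxel_grid(c(100, 100, 100), c(560, 26, 26)))
  axn <- build_compartment_scene("axon", population_config(50, 0.12, seed = 22), g)
  expect_gt(mean(den$manifest$objects$target_volume_um3),
            mean(axn$manifest$objects$target_volume_um3))
})

test_that("impossible packings raise an explicit packing error", {
  g <- voxel_grid(c(100, 100, 100), c(60, 14, 14))
  cfg <- population_config(40, 0.4, seed = 1, shape_mix = c(sphere = 1))
  expect_error(build_compartment_scene("axon", cfg, g,
                                       geometry = list(radius_um = 0.45),
                                       max_attempts = 200),
               class = "mitomorph_packing_error")
})
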