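test_that("volume density is the mitochondrial share of compartment volume", {
  expect_equal(mitochondrial_volume_density(c(0.1, 0.1), 1), 0.2)
  expect_equal(mitochondrial_volume_density(numeric(0), 1), 0)
  expect_error(mitochondrial_volume_density(c(0.7, 0.7), 1), "exceeds")
  expect_error(mitochondrial_volume_density(0.1, 0), "positive")
})

test_that("soma decomposition is voxel-exact and fractions sum to one", {
  g <- voxel_grid(c(100, 100, 100), c(20, 20, 20))
  soma <- array(FALSE, g$dims); soma[2:19, 2:19, 2:19] <- TRUE
  nuc <- array(FALSE, g$dims); nuc[5:12, 5:12, 5:12] <- TRUE
  mito <- array(0L, g$dims); mito[15:16, 15:16, 15:16] <- 1L
  dec <- soma_decomposition(soma, nuc, mito, g)
  expect_equal(dec$nucleus_volume_um3 + dec$cytoplasm_volume_um3 +
                 dec$mito_volume_um3, dec$soma_volume_um3, tolerance = 1e-12)
  expect_equal(sum(dec$fractions), 1, tolerance = 1e-12)
  expect_identical(dec$n_mito, 1L)
})

test_that("a nucleus filling the soma leaves zero cytoplasm and forbids mitochondria", {
  g <- voxel_grid(c(100, 100, 100), c(8, 8, 8))
  soma <- array(TRUE, g$dims)
  mito0 <- array(0L, g$dims)
  dec <- soma_decomposition(soma, soma, mito0, g)
  expect_equal(dec$cytoplasm_volume_um3, 0)
  mito1 <- array(0L, g$dims); mito1[4, 4, 4] <- 1L
  expect_error(soma_decomposition(soma, soma, mito1, g), "overlap the nucleus")
})

test_that("containment violations are consistency errors", {
  g <- voxel_grid(c(100, 100, 100), c(10, 10, 10))
  soma <- array(FALSE, g$dims); soma[3:8, 3:8, 3:8] <- TRUE
  nuc_out <- array(FALSE, g$dims); nuc_out[1, 1, 1] <- TRUE
  expect_error(soma_decomposition(soma, nuc_out, array(0L, g$dims), g),
               "nucleus voxels outside")
  mito_out <- array(0L, g$dims); mito_out[10, 10, 10] <- 1L
  expect_error(soma_decomposition(soma, array(FALSE, g$dims), mito_out, g),
               "mitochondrial voxels outside")
})
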