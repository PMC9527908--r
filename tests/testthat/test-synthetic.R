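test_that("scene layout follows the z-line rules", {
  spec <- synthetic_spec(n_zlines = 10, zline_spacing = 2, cell_width = 21,
                         twin_probability = 0, longitudinal_probability = 0,
                         dropout_probability = 0)
  sc <- build_scene(spec, seed = 1)
  expect_length(sc$tubules, 10)
  xs <- vapply(sc$tubules, function(t) t$x0, numeric(1))
  expect_equal(xs, (seq_len(10) - 0.5) * 2)
  # twin pairs straddle each z-line when twin probability is 1
  sc2 <- build_scene(synthetic_spec(n_zlines = 5, twin_probability = 1), seed = 2)
  expect_length(sc2$tubules, 10)
  xs2 <- sort(vapply(sc2$tubules, function(t) t$x0, numeric(1)))
  expect_equal(xs2, sort(c((1:5 - 0.5) * 2 - 0.3, (1:5 - 0.5) * 2 + 0.3)))
  # dropout removes everything at probability 1
  sc3 <- build_scene(synthetic_spec(dropout_probability = 1), seed = 3)
  expect_length(sc3$tubules, 0)
})

test_that("impossible geometries are rejected at spec construction", {
  expect_error(synthetic_spec(tubule_radius_mean = 1200, zline_spacing = 2),
               "impossible")
  expect_error(synthetic_spec(twin_probability = 1.4), "0, 1")
  expect_error(synthetic_spec(radius_modulation_amplitude = 1), "amplitude")
  expect_error(synthetic_spec(cell_width = -1), "positive")
})

test_that("scenes and voxelizations are deterministic given (spec, seed)", {
  spec <- spec_border(cell_width = 4, n_zlines = 3, cell_depth = 0.7)
  a <- build_scene(spec, seed = 99)
  b <- build_scene(spec, seed = 99)
  expect_identical(a, b)
  va <- voxelize_scene(a, spacing = c(20, 20, 50))
  vb <- voxelize_scene(b, spacing = c(20, 20, 50))
  expect_identical(va$voxels, vb$voxels)
  expect_false(identical(a, build_scene(spec, seed = 100)))
})

test_that("analytic metrics reduce to the closed cylinder forms", {
  spec <- synthetic_spec(radius_modulation_amplitude = 0, cell_width = 12.5,
                         penetration_fraction_mean = 0.4,
                         penetration_fraction_sd = 0, n_zlines = 1,
                         twin_probability = 0, longitudinal_probability = 0)
  sc <- build_scene(spec, seed = 5)
  gt <- sc$ground_truth
  # r = 200 nm, L = 0.4 * 12.5 = 5 um
  expect_equal(gt$volume_um3, pi * 0.2^2 * 5, tolerance = 1e-8)
  expect_equal(gt$surface_um2, 2 * pi * 0.2 * 5 + 2 * pi * 0.2^2, tolerance = 1e-8)
  expect_equal(gt$diameter_nm, 400, tolerance = 1e-8)
  expect_equal(gt$length_um, 5)
  expect_equal(gt$length_fraction, 0.40)
  # with modulation, a full number of periods preserves the mean diameter
  spec_m <- synthetic_spec(radius_modulation_amplitude = 0.2,
                           radius_modulation_wavelength = 1,
                           cell_width = 12.5, penetration_fraction_mean = 0.4,
                           penetration_fraction_sd = 0, n_zlines = 1,
                           twin_probability = 0, longitudinal_probability = 0)
  gt_m <- build_scene(spec_m, seed = 5)$ground_truth
  expect_equal(gt_m$diameter_nm, 400, tolerance = 1e-6)
  expect_gt(gt_m$surface_um2, gt$surface_um2)  # corrugation adds area
})

test_that("voxelized primitives recover analytic volumes within 5%", {
  spec <- synthetic_spec(radius_modulation_amplitude = 0, cell_width = 6,
                         penetration_fraction_mean = 0.6,
                         penetration_fraction_sd = 0, n_zlines = 1,
                         twin_probability = 0, longitudinal_probability = 0)
  sc <- build_scene(spec, seed = 8)
  vol <- voxelize_scene(sc, spacing = c(10, 10, 50))
  vv <- voxel_count_for(vol, 3L) * prod(vol$spacing) * 1e-9
  expect_lt(abs(vv / (pi * 0.2^2 * 3.6) - 1), 0.05)

  # ellipsoid fragment against (4/3) pi a b c
  spec_f <- synthetic_spec(n_zlines = 1, dropout_probability = 1,
                           fragment_count = 1, fragment_volume_mean = 0.05,
                           cell_width = 6, cell_depth = 1.2)
  sc_f <- build_scene(spec_f, seed = 9)
  fr <- sc_f$fragments[[1]]
  analytic <- 4 / 3 * pi * prod(fr$semi)
  vol_f <- voxelize_scene(sc_f, spacing = c(10, 10, 50))
  vf <- voxel_count_for(vol_f, attr(vol_f, "scene_labels")$label[1]) *
    prod(vol_f$spacing) * 1e-9
  expect_lt(abs(vf / analytic - 1), 0.05)
})

test_that("voxelization error shrinks as the in-plane spacing is refined", {
  spec <- synthetic_spec(radius_modulation_amplitude = 0, cell_width = 3,
                         penetration_fraction_mean = 0.5,
                         penetration_fraction_sd = 0, n_zlines = 1,
                         twin_probability = 0, longitudinal_probability = 0)
  sc <- build_scene(spec, seed = 4)
  analytic <- pi * 0.2^2 * 1.5
  errs <- vapply(c(20, 10, 5), function(sp) {
    v <- voxelize_scene(sc, spacing = c(sp, sp, 50))
    abs(voxel_count_for(v, 3L) * prod(v$spacing) * 1e-9 / analytic - 1)
  }, numeric(1))
  expect_lte(errs[2], errs[1] + 1e-3)
  expect_lte(errs[3], errs[2] + 1e-3)
})

test_that("an empty scene voxelizes to cell mask and extracellular only", {
  spec <- synthetic_spec(n_zlines = 1, dropout_probability = 1, cell_width = 2)
  vol <- voxelize_scene(build_scene(spec, seed = 1), spacing = c(20, 20, 50))
  expect_setequal(unique(as.vector(vol$voxels)), c(1L, 2L))
  expect_length(vol$object_labels, 0)
})
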