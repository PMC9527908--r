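test_that("connected components separate objects and carry connectivity flags", {
  spec <- synthetic_spec(n_zlines = 2, cell_width = 4, twin_probability = 0,
                         longitudinal_probability = 0, fragment_count = 1)
  vol <- voxelize_scene(build_scene(spec, seed = 21), spacing = c(20, 20, 50))
  comps <- label_components(vol)
  expect_identical(nrow(comps$info), 3L)  # 2 tubules + 1 fragment
  expect_identical(sum(comps$info$touches_extracellular), 2L)
  expect_false(any(comps$info$touches_crop_boundary))
  # conservation: component volumes sum to object voxel count x voxel volume
  total <- sum(vapply(comps$info$component_id,
                      function(id) component_volume(comps, id), numeric(1)))
  expect_equal(total,
               sum(vol$voxels %in% vol$object_labels) * prod(vol$spacing) * 1e-9)
})

test_that("components below min_voxels are discarded and counted", {
  arr <- array(1L, dim = c(8, 8, 8))
  arr[1, , ] <- 2L
  arr[4, 4, 4] <- 5L              # isolated voxel
  arr[6:7, 6:7, 6:7] <- 5L        # 8-voxel blob
  vol <- label_volume(arr, c(10, 10, 50))
  comps <- label_components(vol, min_voxels = 4L)
  expect_identical(nrow(comps$info), 1L)
  expect_identical(attr(comps, "discarded"), 1L)
  expect_identical(comps$info$n_voxels, 8L)
})

test_that("6- and 26-connectivity differ across diagonal contacts", {
  arr <- array(1L, dim = c(6, 6, 6))
  arr[1, , ] <- 2L
  arr[3, 3, 3] <- 7L
  arr[4, 4, 4] <- 7L  # diagonal neighbour
  vol <- label_volume(arr, c(10, 10, 50))
  expect_identical(nrow(label_components(vol, connectivity = 26, min_voxels = 1)$info), 1L)
  expect_identical(nrow(label_components(vol, connectivity = 6, min_voxels = 1)$info), 2L)
})

test_that("component volume is exact voxel arithmetic", {
  arr <- array(1L, dim = c(12, 10, 10))
  arr[1, , ] <- 2L
  arr[2:11, , ] <- 9L  # 10 x 10 x 10 = 1000 voxels
  vol <- label_volume(arr, c(10, 10, 50))
  comps <- label_components(vol)
  expect_equal(component_volume(comps, 1L), 1000 * 10 * 10 * 50 * 1e-9)
})

test_that("surface area matches analytic oracles for cube and cylinder", {
  # 1 um cube at anisotropic spacing
  arr <- array(1L, dim = c(28, 120, 120))
  arr[1, , ] <- 2L
  arr[5:24, 11:110, 11:110] <- 3L  # 20 x 100 x 100 voxels = 1 x 1 x 1 um
  vol <- label_volume(arr, c(10, 10, 50))
  comps <- label_components(vol)
  expect_lt(abs(component_surface_area(comps, 1L) / 6 - 1), 0.10)

  cyl <- cylinder_volume(r_nm = 200, L_um = 5, spacing = c(10, 10, 50))
  ccy <- label_components(cyl)
  a_true <- 2 * pi * 0.2 * 5 + 2 * pi * 0.2^2
  expect_lt(abs(component_surface_area(ccy, 1L) / a_true - 1), 0.10)
})

test_that("mesh area grows monotonically when a box is dilated", {
  areas <- vapply(0:3, function(g) {
    arr <- array(1L, dim = c(30, 30, 30))
    arr[1, , ] <- 2L
    rng <- (10 - g):(20 + g)
    arr[rng, rng, rng] <- 3L
    comps <- label_components(label_volume(arr, c(10, 10, 10)))
    component_surface_area(comps, 1L)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("equivalent diameter is the mean contour perimeter over pi", {
  # three circular contours of perimeter pi * 400 -> exactly 400 nm
  cs <- fake_contours(rep(pi * 400, 3))
  comps <- structure(list(), class = "component_set")  # unused when contours given
  expect_equal(equivalent_diameter(comps, 1L, contours = cs), 400)
  expect_equal(equivalent_diameter(comps, 1L, contours = fake_contours(1570.80)),
               1570.80 / pi)
  # algebraic identity against an independently computed mean over contours
  set.seed(42)
  per <- runif(20, 500, 3000)
  expect_equal(equivalent_diameter(comps, 1L, contours = fake_contours(per)),
               mean(per / pi), tolerance = 1e-12)
  # area variant for the same circles
  d_area <- equivalent_diameter(comps, 1L, method = "area",
                                contours = fake_contours(rep(pi * 400, 3)))
  expect_equal(d_area, 400, tolerance = 1e-9)
  expect_error(equivalent_diameter(comps, 1L, contours = list()), "no contours")
})

test_that("voxelized cylinder metrics land within the recovery tolerances", {
  cyl <- cylinder_volume(r_nm = 200, L_um = 5, spacing = c(10, 10, 50))
  comps <- label_components(cyl)
  expect_lt(abs(equivalent_diameter(comps, 1L) / 400 - 1), 0.05)
  expect_lt(abs(component_volume(comps, 1L) / (pi * 0.2^2 * 5) - 1), 0.05)
  # straight axis length 5 um within max(sz, 2 * in-plane) = 100 nm
  expect_lt(abs(longest_branch_length(comps, 1L) - 5), 0.1)
})

test_that("longest branch follows the longest attachment-to-tip path", {
  # Y-shaped tube: trunk 2 um from the attachment, then a straight
  # continuation to 4 um total and a short 1 um side arm
  sp <- c(50, 50, 50)
  arr <- array(1L, dim = c(90, 50, 50))
  arr[1:2, , ] <- 2L
  r2 <- 200^2
  yc <- (seq_len(50) - 0.5) * 50; xc <- (seq_len(50) - 0.5) * 50
  zc <- (seq_len(90) - 0.5) * 50 - 100
  trunk <- which(zc >= 0 & zc <= 4000)
  for (k in trunk) {
    sl <- arr[k, , ]
    sl[outer((yc - 1250)^2, (xc - 1250)^2, "+") <= r2] <- 3L
    arr[k, , ] <- sl
  }
  arm_z <- which(zc >= 1800 & zc <= 2200)  # side arm at depth ~2 um, along x
  for (k in arm_z) {
    sl <- arr[k, , ]
    sl[outer(abs(yc - 1250) <= 200, xc >= 1250 & xc <= 2250, "&")] <- 3L
    arr[k, , ] <- sl
  }
  vol <- label_volume(arr, sp)
  comps <- label_components(vol)
  expect_identical(nrow(comps$info), 1L)
  len <- longest_branch_length(comps, 1L)
  expect_lt(abs(len - 4), 0.15)  # trunk, not trunk-depth + arm (3 um)
})

test_that("single-voxel components report degenerate zero length", {
  arr <- array(1L, dim = c(6, 6, 6))
  arr[1, , ] <- 2L
  arr[3, 3, 3] <- 4L
  comps <- label_components(label_volume(arr, c(10, 10, 50)), min_voxels = 1L)
  expect_warning(len <- longest_branch_length(comps, 1L), "degenerate")
  expect_identical(len, 0)
})

test_that("length fraction is plain normalization with guarded input", {
  expect_equal(length_fraction(5, 12.5), 0.40)
  expect_equal(length_fraction(7.3, 7.3), 1.0)
  expect_error(length_fraction(5, 0), "positive")
})

test_that("cell width follows the penetration axis chord", {
  # perpendicular tubule through a 3-um-wide slab cell
  cyl <- cylinder_volume(r_nm = 200, L_um = 1.5, spacing = c(20, 20, 50),
                         cell_z_um = 3)
  comps <- label_components(cyl)
  w <- cell_width_at(comps, 1L)
  expect_lt(abs(w / 3 - 1), 0.02)

  # oblique tubule at 45 degrees in the (z, x) plane: chord = width * sqrt(2)
  sp <- c(20, 20, 20)
  nz <- 160L; ny <- 40L; nx <- 220L
  arr <- array(1L, dim = c(nz, ny, nx))
  zc <- (seq_len(nz) - 0.5) * 20 - 100
  yc <- (seq_len(ny) - 0.5) * 20
  xc <- (seq_len(nx) - 0.5) * 20
  arr[zc < 0 | zc > 2800, , ] <- 2L
  for (k in which(zc >= 0 & zc <= 1400)) {
    sl <- arr[k, , ]
    sl[outer(abs(yc - 400) <= 150, abs(xc - (500 + zc[k])) <= 150, "&")] <- 3L
    arr[k, , ] <- sl
  }
  vol <- label_volume(arr, sp)
  comps2 <- label_components(vol)
  w2 <- cell_width_at(comps2, 1L)
  expect_lt(abs(w2 / (2.8 * sqrt(2)) - 1), 0.05)
})

test_that("per-cell summaries do the densities arithmetic", {
  rec <- data.frame(component_id = 1:16,
                    class = c(rep("tubule", 14), "fragment", "indeterminate"),
                    volume_um3 = c(rep(0.25, 14), 0.02, 0.01),
                    animal_id = "a", cell_id = "c", region = "control")
  cs <- cell_summaries(rec, cell_volume_um3 = 200)
  expect_equal(cs$tubule_density_um3, 0.07)
  expect_equal(cs$tubule_volume_fraction_pct, 14 * 0.25 / 200 * 100)
  expect_equal(cs$n_indeterminate, 1L)
  # a metric invariant to component relabelling
  rec2 <- rec
  rec2$component_id <- rev(rec2$component_id)
  expect_equal(cell_summaries(rec2, 200), cs)
  # empty cell: zero density and fraction are valid
  empty <- rec[0, ]
  cs0 <- cell_summaries(empty, 200)
  expect_equal(cs0$tubule_density_um3, 0)
  expect_equal(cs0$tubule_volume_fraction_pct, 0)
  expect_error(cell_summaries(rec, 0), "positive")
})

test_that("tubule subsampling is deterministic, capped and seed-sensitive", {
  rec <- data.frame(component_id = 1:20, class = "tubule",
                    volume_um3 = runif(20), animal_id = "a", cell_id = "c",
                    region = "control")
  s1 <- subsample_metrics(rec, k = 15, seed = 7)
  s2 <- subsample_metrics(rec, k = 15, seed = 7)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 15L)
  s3 <- subsample_metrics(rec, k = 15, seed = 8)
  expect_false(identical(s1$component_id, s3$component_id))
  expect_warning(all10 <- subsample_metrics(rec[1:10, ], k = 15, seed = 1),
                 "only 10")
  expect_identical(nrow(all10), 10L)
})

test_that("phantom round trip recovers per-tubule metrics", {
  spec <- synthetic_spec(n_zlines = 4, cell_width = 6, twin_probability = 0,
                         longitudinal_probability = 0, fragment_count = 0)
  sc <- build_scene(spec, seed = 31)
  vol <- voxelize_scene(sc, spacing = c(10, 10, 50))
  comps <- label_components(vol)
  rec <- measure_components(comps, cell_id = "c1")
  map <- match_components_to_scene(comps, vol)
  gt <- sc$ground_truth[match(map$primitive_id, sc$ground_truth$id), ]
  expect_lt(mean(abs(rec$volume_um3 / gt$volume_um3 - 1)), 0.05)
  expect_lt(mean(abs(rec$diameter_nm / gt$diameter_nm - 1)), 0.05)
  expect_lt(mean(abs(rec$length_um / gt$length_um - 1)), 0.05)
  expect_lt(mean(abs(rec$surface_um2 / gt$surface_um2 - 1)), 0.10)
  expect_lt(max(abs(rec$cell_width_um / 6 - 1)), 0.02)
})
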