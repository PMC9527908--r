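# Phantom builders shared across the test files. Everything is generated in
# code so tests carry no binary fixtures.

# A straight cylinder of radius r_nm along the Z (sectioning) axis, attached
# to an extracellular slab at the low-Z face; the rest of the box is cell mask.
cylinder_volume <- function(r_nm = 200, L_um = 5, spacing = c(10, 10, 50),
                            pad_xy = 8L, label = 5L, cell_z_um = NULL) {
  sx <- spacing[1]; sy <- spacing[2]; sz <- spacing[3]
  L_nm <- L_um * 1000
  nz <- ceiling((if (is.null(cell_z_um)) L_um else cell_z_um) * 1000 / sz) + 6L
  ny <- nx <- ceiling(2 * r_nm / sx) + pad_xy
  arr <- array(1L, dim = c(nz, ny, nx))
  z_cell <- (seq_len(nz) - 0.5) * sz - 3 * sz
  yc <- (seq_len(ny) - 0.5) * sy
  xc <- (seq_len(nx) - 0.5) * sx
  arr[z_cell < 0, , ] <- 2L
  if (!is.null(cell_z_um)) arr[z_cell > cell_z_um * 1000, , ] <- 2L
  cy <- ny / 2 * sy; cx <- nx / 2 * sx
  disc <- outer((yc - cy)^2, (xc - cx)^2, "+") <= r_nm^2
  for (k in which(z_cell >= 0 & z_cell <= L_nm)) {
    sl <- arr[k, , ]
    sl[disc] <- label
    arr[k, , ] <- sl
  }
  label_volume(arr, spacing = spacing, cell_label = 1L,
               extracellular_label = 2L)
}

# digitized disc mask at a given in-plane spacing (for contour oracles)
disc_mask <- function(r_nm, sp_nm, pad = 4L, off = c(0, 0)) {
  n <- ceiling(2 * r_nm / sp_nm) + 2L * pad
  ctr <- n / 2 * sp_nm
  yy <- (seq_len(n) - 0.5) * sp_nm
  xx <- (seq_len(n) - 0.5) * sp_nm
  outer((yy - ctr - off[1])^2, (xx - ctr - off[2])^2, "+") <= r_nm^2
}

# map measured components back to scene primitives through the voxel labels
# that voxelize_scene assigned (components never mix primitives, so any one
# voxel identifies the primitive)
match_components_to_scene <- function(comps, vol) {
  sl <- attr(vol, "scene_labels")
  orig <- vapply(comps$info$component_id, function(id)
    vol$voxels[ttmorph:::comp_voxels(comps, id)[1]], integer(1))
  data.frame(component_id = comps$info$component_id,
             primitive_id = sl$id[match(orig, sl$label)],
             true_class = sl$class[match(orig, sl$label)])
}

# synthetic fake contour stack for formula-identity tests
fake_contours <- function(perimeters, areas = NULL) {
  if (is.null(areas)) areas <- (perimeters / (2 * pi))^2 * pi
  lapply(seq_along(perimeters), function(i)
    structure(list(slice_index = i,
                   vertices = matrix(0, 2, 2, dimnames = list(NULL, c("x", "y"))),
                   perimeter = perimeters[i], area = areas[i]),
              class = "slice_contour"))
}

# clustered two-region table generator used by the mixed-model tests
simulate_clustered <- function(seed, delta = 0, n_animals = 3L, n_cells = 3L,
                               n_obs = 15L, sd_animal = 0.3, sd_cell = 0.2,
                               sd_resid = 1) {
  set.seed(seed)
  rows <- list()
  for (r in c("A", "B")) {
    for (a in seq_len(n_animals)) {
      av <- rnorm(1, 0, sd_animal)
      for (cc in seq_len(n_cells)) {
        cv <- rnorm(1, 0, sd_cell)
        v <- (if (r == "B") delta else 0) + av + cv + rnorm(n_obs, 0, sd_resid)
        rows[[length(rows) + 1L]] <-
          data.frame(value = v, region = r, animal_id = paste0(r, a),
                     cell_id = paste0(r, a, "_", cc))
      }
    }
  }
  do.call(rbind, rows)
}

voxel_count_for <- function(vol, label) sum(vol$voxels == label)
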