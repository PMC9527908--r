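#' Component volume
#'
#' Voxel count times the physical voxel volume.
#'
#' @param components a `component_set` from [label_components()].
#' @param component_id component id.
#' @return Volume in \eqn{\mu m^3}.
#' @export
component_volume <- function(components, component_id) {
  row <- comp_row(components, component_id)
  row$n_voxels * voxel_volume_um3(components$volume)
}

#' Component surface area
#'
#' Area of the sub-voxel iso-surface mesh of the component at the 0.5 level
#' of its 3x3x3 box-smoothed indicator, extracted by marching tetrahedra with
#' the anisotropic voxel spacing honoured. Open faces at the crop window
#' boundary are excluded (components cut by the crop are not capped there);
#' interfaces with the extracellular partition are meshed like any other
#' boundary.
#'
#' @inheritParams component_volume
#' @return Surface area in \eqn{\mu m^2}.
#' @export
component_surface_area <- function(components, component_id) {
  dims <- dim(components$labels)
  idx <- comp_voxels(components, component_id)
  if (!length(idx)) stop("component has no voxels")
  bb <- comp_bbox(idx, dims, pad = 3L)
  sub <- components$labels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                           bb$lo[3]:bb$hi[3], drop = FALSE] == component_id
  area_nm2 <- .mtetra_area(sub, dim(sub), spacing_zyx(components$volume))
  area_nm2 * 1e-6  # nm^2 -> um^2
}

#' Per-slice contour stack of a component
#'
#' Closed sub-voxel contours of the component's cross-sections on every slice
#' it spans, traced per component (never mixing objects) as required by the
#' per-tubule equivalent-diameter formula.
#'
#' @inheritParams component_volume
#' @return List of `slice_contour` objects across all slices.
#' @export
contour_stack <- function(components, component_id) {
  dims <- dim(components$labels)
  idx <- comp_voxels(components, component_id)
  if (!length(idx)) return(list())
  bb <- comp_bbox(idx, dims, pad = 2L)
  sp <- components$volume$spacing
  out <- list()
  for (z in bb$lo[1]:bb$hi[1]) {
    mask <- components$labels[z, bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                              drop = TRUE] == component_id
    if (!is.matrix(mask)) next
    cs <- trace_mask_contours(mask, sp[1], sp[2], z)
    out <- c(out, cs)
  }
  out
}

#' Contour-based equivalent diameter
#'
#' The per-tubule diameter statistic under the approximation that serial-
#' section cross-sections are circles: the mean contour perimeter divided by
#' \eqn{\pi} (a circle's perimeter over \eqn{\pi} is its diameter),
#' \deqn{d_{eq} = \frac{\sum_i P(contour_i)}{n \pi},}
#' with \eqn{n} the total number of contours of the component. The
#' `"area"` variant \eqn{d = 2\sqrt{\bar A / \pi}} is available for
#' sensitivity analysis.
#'
#' @inheritParams component_volume
#' @param method `"perimeter"` (default) or `"area"`.
#' @param contours optionally, a precomputed [contour_stack()].
#' @return Equivalent diameter in nm.
#' @export
equivalent_diameter <- function(components, component_id,
                                method = c("perimeter", "area"),
                                contours = NULL) {
  method <- match.arg(method)
  if (is.null(contours)) contours <- contour_stack(components, component_id)
  if (length(contours) == 0L)
    stop("component has no contours; equivalent diameter undefined")
  if (method == "perimeter") {
    mean(vapply(contours, function(cc) cc$perimeter, numeric(1))) / pi
  } else {
    2 * sqrt(mean(vapply(contours, function(cc) cc$area, numeric(1))) / pi)
  }
}

# full-array linear indices of component voxels face-adjacent to the
# extracellular partition (the sarcolemmal attachment voxels)
attachment_voxels <- function(components, component_id) {
  dims <- dim(components$labels)
  idx <- comp_voxels(components, component_id)
  sub <- arrayInd(idx, dims)
  vol <- components$volume$voxels
  ec <- components$volume$extracellular_label
  att <- logical(length(idx))
  for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
    nb <- sweep(sub, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] + (nb[ok, 3] - 1) * dims[1] * dims[2]
    att[ok][vol[lin] == ec] <- TRUE
  }
  idx[att]
}

#' Longest-branch length of a tubule component
#'
#' The length of the longest branch, realized as the maximum geodesic path
#' length through the component's voxel graph (26-neighbour adjacency,
#' physical anisotropic edge weights) from the sarcolemmal attachment voxels
#' to any voxel. For a component without attachment (which should not occur
#' for tubules) the voxel-graph pseudo-diameter is returned. Path length, not
#' straight-line chord: a bent tubule is credited its curved length.
#'
#' @inheritParams component_volume
#' @return Length in \eqn{\mu m}; 0 (with a warning) for a single-voxel
#'   component.
#' @export
longest_branch_length <- function(components, component_id) {
  dims <- dim(components$labels)
  idx <- comp_voxels(components, component_id)
  if (!length(idx)) stop("component has no voxels")
  if (length(idx) == 1L) {
    warning("single-voxel component: degenerate length 0")
    return(0)
  }
  bb <- comp_bbox(idx, dims, pad = 0L)
  att <- attachment_voxels(components, component_id)
  ldims <- bb$hi - bb$lo + 1L
  lsub <- sweep(bb$sub, 2, bb$lo - 1L, "-")
  lidx <- lsub[, 1] + (lsub[, 2] - 1) * ldims[1] + (lsub[, 3] - 1) * ldims[1] * ldims[2]
  src <- which(idx %in% att)
  len_nm <- .geodesic_longest(as.integer(lidx), as.integer(src),
                              as.integer(ldims), spacing_zyx(components$volume))
  # the geodesic runs voxel centre to voxel centre; credit the half-voxel
  # extent beyond each end, projected onto the component's principal axis
  sp_zyx <- spacing_zyx(components$volume)
  phys <- sweep(bb$sub, 2, sp_zyx, "*")
  dir <- prcomp(phys, center = TRUE, rank. = 1)$rotation[, 1]
  dir <- dir / sqrt(sum(dir^2))
  (len_nm + sum(abs(dir) * sp_zyx)) / 1000
}

#' Length as a fraction of cell width
#'
#' Normalizes a tubule's longest-branch length to the width of the cell so
#' that penetration depth is comparable across cells of different widths.
#' Values above 1 are possible for oblique or convoluted tubules and are
#' flagged by [measure_components()].
#'
#' @param length_um tubule length, um.
#' @param cell_width_um cell width, um.
#' @return Unitless fraction.
#' @export
length_fraction <- function(length_um, cell_width_um) {
  if (any(cell_width_um <= 0, na.rm = TRUE)) stop("cell width must be positive")
  length_um / cell_width_um
}

#' Cell width along a component's penetration axis
#'
#' Chord length of the cell mask (cytoplasm plus embedded objects) along the
#' line through the component's sarcolemmal attachment point in the direction
#' of the component's first principal axis. The chord is traced by stepping at
#' half the finest voxel pitch from the attachment point in both directions
#' until the line leaves the cell mask.
#'
#' @inheritParams component_volume
#' @return Cell width in \eqn{\mu m}, or `NA` for a component with no
#'   sarcolemmal attachment (fragments have no penetration axis).
#' @export
cell_width_at <- function(components, component_id) {
  dims <- dim(components$labels)
  idx <- comp_voxels(components, component_id)
  att <- attachment_voxels(components, component_id)
  if (!length(att)) return(NA_real_)
  sp_zyx <- spacing_zyx(components$volume)  # nm
  sub <- arrayInd(idx, dims)
  phys <- sweep(sub, 2, sp_zyx, "*")  # nm, (z, y, x)
  dir <- prcomp(phys, center = TRUE, rank. = 1)$rotation[, 1]
  dir <- dir / sqrt(sum(dir^2))
  att_sub <- arrayInd(att, dims)
  p0 <- colMeans(sweep(att_sub, 2, sp_zyx, "*"))
  vol <- components$volume$voxels
  inside_cell <- function(p) {
    v <- floor(p / sp_zyx) + 1
    if (any(v < 1) || any(v > dims)) return(FALSE)
    lab <- vol[v[1] + (v[2] - 1) * dims[1] + (v[3] - 1) * dims[1] * dims[2]]
    lab == components$volume$cell_label ||
      lab %in% components$volume$object_labels
  }
  step <- min(sp_zyx) / 2
  reach <- function(sgn) {
    t <- 0
    repeat {
      tn <- t + step
      if (!inside_cell(p0 + sgn * tn * dir)) return(t)
      t <- tn
      if (t > 1e9) stop("unbounded cell mask chord")
    }
  }
  (reach(1) + reach(-1) + step) / 1000  # nm -> um, + one step for voxel extent
}
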