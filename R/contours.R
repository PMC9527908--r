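#' Extract sub-voxel closed contours of a label on one slice
#'
#' Traces the in-plane cross-sections of a label on one Z slice at the 0.5
#' iso-level of the (3x3 box-smoothed) binary indicator, with linear
#' interpolation along pixel edges. Tracing the smoothed indicator rather than
#' the raw voxel boundary avoids the systematic staircase over-estimation of
#' perimeters (roughly +27% for axis-aligned boundary polygons, +6-9% for
#' midpoint marching squares on raw binary data), which would otherwise bias
#' the contour-based equivalent diameter.
#'
#' @param volume a [label_volume].
#' @param label object label to trace.
#' @param slice_index 1-based Z slice index.
#' @return A list of `slice_contour` objects (possibly empty), each with
#'   fields `slice_index`, `vertices` (closed polygon, columns x and y in nm),
#'   `perimeter` (nm) and `area` (nm^2).
#' @export
extract_slice_contours <- function(volume, label, slice_index) {
  stopifnot(inherits(volume, "label_volume"))
  nz <- dim(volume$voxels)[1]
  if (slice_index < 1L || slice_index > nz)
    stop("slice_index out of range")
  mask <- volume$voxels[slice_index, , , drop = TRUE] == label
  trace_mask_contours(mask, volume$spacing[1], volume$spacing[2], slice_index)
}

# mask: logical (ny, nx) matrix; sx, sy: nm per voxel in-plane
trace_mask_contours <- function(mask, sx, sy, slice_index) {
  if (!any(mask)) return(list())
  polys <- .trace_contours(mask)
  out <- vector("list", length(polys))
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    x <- p[, "col"] * sx
    y <- p[, "row"] * sy
    m <- length(x)
    per <- sum(sqrt(diff(x)^2 + diff(y)^2))
    # shoelace on the closed polygon (last vertex repeats the first)
    area <- 0.5 * abs(sum(x[-m] * y[-1] - x[-1] * y[-m]))
    out[[i]] <- structure(list(slice_index = slice_index,
                               vertices = cbind(x = x, y = y),
                               perimeter = per,
                               area = area),
                          class = "slice_contour")
  }
  out
}

#' @export
print.slice_contour <- function(x, ...) {
  cat(sprintf("slice_contour: slice %d, %d vertices, perimeter %.1f nm, area %.1f nm^2\n",
              x$slice_index, nrow(x$vertices) - 1L, x$perimeter, x$area))
  invisible(x)
}
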