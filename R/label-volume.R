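#' Label volume container
#'
#' A `label_volume` wraps a 3D integer voxel grid together with its anisotropic
#' voxel spacing and the roles of the labels it contains. Axis order is fixed
#' as (slice/Z, row/Y, column/X), with Z the serial-sectioning axis (typically
#' 50 nm sections against 8-11 nm in-plane pixels). Label roles: `cell_label`
#' marks the intracellular partition (cytoplasm inside the sarcolemma),
#' `extracellular_label` marks space outside the sarcolemma, and every other
#' positive label is a segmented tubular object.
#'
#' @param voxels 3D integer array, dim `(nz, ny, nx)`.
#' @param spacing numeric length-3 voxel spacing `(sx, sy, sz)` in nm.
#' @param cell_label integer label of the cell-mask partition.
#' @param extracellular_label integer label of the extracellular partition.
#' @param object_labels integer vector of object labels; defaults to all
#'   positive labels present other than the two partitions.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing, cell_label = 1L,
                         extracellular_label = 2L, object_labels = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (is.double(voxels)) {
    if (any(voxels != round(voxels), na.rm = TRUE))
      stop("voxel data must be integer labels")
    storage.mode(voxels) <- "integer"
  }
  if (!is.integer(voxels)) stop("voxel data must be integer labels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (sx, sy, sz) in nm")
  cell_label <- as.integer(cell_label)
  extracellular_label <- as.integer(extracellular_label)
  if (cell_label == extracellular_label)
    stop("cell_label and extracellular_label must differ")
  if (is.null(object_labels)) {
    present <- sort(unique(as.vector(voxels)))
    object_labels <- setdiff(present[present > 0L],
                             c(cell_label, extracellular_label))
  }
  object_labels <- as.integer(object_labels)
  if (any(object_labels %in% c(cell_label, extracellular_label, 0L)))
    stop("object labels overlap partition labels")
  structure(list(voxels = voxels,
                 spacing = spacing,
                 cell_label = cell_label,
                 extracellular_label = extracellular_label,
                 object_labels = object_labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_volume: %d slices x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (x,y,z): %.3g x %.3g x %.3g nm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  cell label %d, extracellular label %d, %d object label(s)\n",
              x$cell_label, x$extracellular_label, length(x$object_labels)))
  crop <- attr(x, "crop_window")
  if (!is.null(crop))
    cat(sprintf("  crop window: slices %d..%d of parent stack\n",
                crop[1], crop[2]))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

# spacing reordered to the (z, y, x) axis order of the voxel array
spacing_zyx <- function(volume) volume$spacing[c(3, 2, 1)]

# physical voxel volume in um^3 (spacing is in nm)
voxel_volume_um3 <- function(volume) prod(volume$spacing) * 1e-9

#' Total cell volume of a label volume
#'
#' The volume inside the sarcolemma: voxels carrying the cell label plus all
#' object voxels (tubule lumina are part of the cell volume, as in volume
#' fraction denominators).
#'
#' @param volume a [label_volume].
#' @return Cell volume in \eqn{\mu m^3}.
#' @export
cell_volume <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  n <- sum(volume$voxels == volume$cell_label |
             (volume$voxels %in% volume$object_labels))
  n * voxel_volume_um3(volume)
}

#' Crop a contiguous portion of slices from a stack
#'
#' Analyses conventionally run on a portion of about 100 consecutive sections;
#' this extracts such a window and records its provenance on the result.
#'
#' @param volume a [label_volume].
#' @param start_slice first slice of the window (1-based).
#' @param n_slices number of slices to keep (default 100).
#' @return A [label_volume] with `n_slices` slices; spacing and label roles
#'   unchanged; the crop window recorded in attribute `"crop_window"`.
#' @export
crop_stack_portion <- function(volume, start_slice, n_slices = 100L) {
  stopifnot(inherits(volume, "label_volume"))
  start_slice <- as.integer(start_slice)
  n_slices <- as.integer(n_slices)
  nz <- dim(volume$voxels)[1]
  if (start_slice < 1L || n_slices < 1L || start_slice + n_slices - 1L > nz)
    stop(sprintf("crop window [%d, %d] out of range for %d slices",
                 start_slice, start_slice + n_slices - 1L, nz))
  out <- label_volume(volume$voxels[start_slice:(start_slice + n_slices - 1L), , ,
                                    drop = FALSE],
                      volume$spacing, volume$cell_label,
                      volume$extracellular_label, volume$object_labels)
  attr(out, "crop_window") <- c(start_slice, start_slice + n_slices - 1L)
  out
}

#' Read a label volume from disk
#'
#' Supports multi-page TIFF label stacks (8/16-bit integer pages, one per
#' slice) and MRC2014 volumes. For TIFF, spacing and label roles are taken
#' from a sidecar JSON (`<path>.json`, as written by [write_label_volume()])
#' when present, else from the arguments. For MRC, spacing comes from the cell
#' dimensions in the header.
#'
#' @param path file path (`.tif`, `.tiff` or `.mrc`).
#' @param spacing voxel spacing `(sx, sy, sz)` in nm; overrides metadata when
#'   given.
#' @param cell_label,extracellular_label,object_labels label roles, as in
#'   [label_volume()].
#' @return A [label_volume].
#' @export
read_label_volume <- function(path, spacing = NULL, cell_label = 1L,
                              extracellular_label = 2L, object_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (ext %in% c("tif", "tiff")) {
    first <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(first, "bits.per.sample")
    if (!is.null(bps) && !bps %in% c(1L, 8L, 16L))
      stop("TIFF stack stores non-integer voxel data (", bps,
           "-bit samples); label stacks must be 8- or 16-bit integer")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) any(p != round(p)), logical(1))))
      stop("TIFF stack contains non-integer voxel data")
    d <- dim(pages[[1]])
    vox <- array(0L, dim = c(length(pages), d[1], d[2]))
    for (k in seq_along(pages)) vox[k, , ] <- as.integer(round(pages[[k]]))
  } else if (ext == "mrc") {
    mrc <- read_mrc(path)
    vox <- mrc$voxels
    if (is.null(spacing)) spacing <- mrc$spacing
  } else stop("unsupported volume format: .", ext)
  if (!is.null(meta)) {
    if (is.null(spacing)) spacing <- as.numeric(meta$spacing_nm)
    if (!is.null(meta$cell_label)) cell_label <- meta$cell_label
    if (!is.null(meta$extracellular_label)) extracellular_label <- meta$extracellular_label
    if (!is.null(meta$object_labels) && is.null(object_labels))
      object_labels <- as.integer(meta$object_labels)
  }
  if (is.null(spacing))
    stop("no spacing metadata found; pass `spacing` explicitly")
  out <- label_volume(vox, spacing, cell_label, extracellular_label, object_labels)
  if (!is.null(meta$crop_window)) attr(out, "crop_window") <- as.integer(meta$crop_window)
  out
}

#' Write a label volume to disk
#'
#' TIFF output stores one 16-bit page per slice plus a sidecar JSON
#' (`<path>.json`) carrying spacing, label roles and any crop provenance.
#' MRC output stores 16-bit signed data with the spacing encoded in the
#' header's cell dimensions.
#'
#' @param volume a [label_volume].
#' @param path output file path.
#' @param format `"tiff"` or `"mrc"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mrc") "mrc" else "tiff"
  }
  format <- match.arg(format, c("tiff", "mrc"))
  vox <- volume$voxels
  if (format == "tiff") {
    if (max(vox) > 65535L || min(vox) < 0L)
      stop("TIFF label output supports labels in [0, 65535]")
    pages <- lapply(seq_len(dim(vox)[1]),
                    function(k) vox[k, , , drop = TRUE] / 65535)
    ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
    if (!all(ok > 0)) stop("failed to write TIFF: ", path)
    meta <- list(spacing_nm = volume$spacing,
                 cell_label = volume$cell_label,
                 extracellular_label = volume$extracellular_label,
                 object_labels = volume$object_labels,
                 axis_order = "zyx")
    crop <- attr(volume, "crop_window")
    if (!is.null(crop)) meta$crop_window <- crop
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    write_mrc(volume, path)
  }
  invisible(path)
}

# --- minimal MRC2014 reader/writer (mode 1, int16) -------------------------
# Header: 56 4-byte words + 800 bytes of text labels = 1024 bytes.
# Data order: x fastest, then y, then z; our arrays are (z, y, x).

write_mrc <- function(volume, path) {
  vox <- volume$voxels
  if (max(vox) > 32767L || min(vox) < -32768L)
    stop("MRC mode-1 output supports labels in [-32768, 32767]")
  d <- dim(vox)  # (nz, ny, nx)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  sp <- volume$spacing  # (sx, sy, sz) nm
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 1L))                    # dims + mode 1 (int16)
  wi(c(0L, 0L, 0L))                        # nxstart/nystart/nzstart
  wi(c(nx, ny, nz))                        # mx/my/mz
  wf(c(nx * sp[1], ny * sp[2], nz * sp[3]) * 10)  # cell dims in Angstrom
  wf(c(90, 90, 90))                        # cell angles
  wi(c(1L, 2L, 3L))                        # mapc/mapr/maps
  wf(c(min(vox), max(vox), mean(vox)))     # dmin/dmax/dmean
  wi(c(0L, 0L))                            # ispg, nsymbt
  wi(integer(25))                          # extra
  wf(c(0, 0, 0))                           # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.integer(c(68L, 65L, 0L, 0L)), con, size = 1)  # little-endian stamp
  wf(stats::sd(as.numeric(vox)))           # rms
  wi(0L)                                   # nlabl
  writeBin(raw(800), con)
  writeBin(as.integer(aperm(vox, c(3, 2, 1))), con, size = 2, endian = "little")
  invisible(path)
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  hdr1 <- ri(4)  # nx ny nz mode
  nx <- hdr1[1]; ny <- hdr1[2]; nz <- hdr1[3]; mode <- hdr1[4]
  if (mode != 1L) stop("only MRC mode 1 (int16) label volumes are supported")
  ri(3); mxyz <- ri(3); cella <- rf(3)
  seek(con, 1024)
  raw_vals <- readBin(con, "integer", nx * ny * nz, size = 2, endian = "little",
                      signed = TRUE)
  vox <- aperm(array(as.integer(raw_vals), dim = c(nx, ny, nz)), c(3, 2, 1))
  spacing <- c(cella[1] / mxyz[1], cella[2] / mxyz[2], cella[3] / mxyz[3]) / 10  # nm
  list(voxels = vox, spacing = spacing)
}
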