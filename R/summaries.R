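#' Measure every component of a volume
#'
#' Runs the full per-object morphometry over a `component_set`: class
#' (tubule / fragment / indeterminate by sarcolemmal connectivity), volume,
#' surface area, contour-based equivalent diameter, and — for tubules —
#' longest-branch length, cell width along the penetration axis and length
#' fraction. Fragments carry `NA` length and length fraction.
#'
#' @param components a `component_set` from [label_components()].
#' @param animal_id,cell_id,region grouping metadata attached to every row.
#' @param diameter_method `"perimeter"` (default) or `"area"`, see
#'   [equivalent_diameter()].
#' @param cell_width `"per_tubule"` (chord along each tubule's own penetration
#'   axis, the default) or `"per_cell"` (every tubule normalized by the mean
#'   of the per-tubule widths of its cell).
#' @return A data.frame of morphometry records, one row per component:
#'   `component_id`, `class`, `volume_um3`, `surface_um2`, `diameter_nm`,
#'   `length_um`, `cell_width_um`, `length_fraction`, `oblique_flag`
#'   (length fraction above 1), `crop_flag`, plus the grouping columns.
#' @export
measure_components <- function(components, animal_id = NA_character_,
                               cell_id = NA_character_,
                               region = NA_character_,
                               diameter_method = c("perimeter", "area"),
                               cell_width = c("per_tubule", "per_cell")) {
  stopifnot(inherits(components, "component_set"))
  diameter_method <- match.arg(diameter_method)
  cell_width <- match.arg(cell_width)
  ids <- components$info$component_id
  n <- length(ids)
  rec <- data.frame(component_id = ids,
                    class = character(n),
                    volume_um3 = numeric(n),
                    surface_um2 = numeric(n),
                    diameter_nm = numeric(n),
                    length_um = NA_real_,
                    cell_width_um = NA_real_,
                    length_fraction = NA_real_,
                    oblique_flag = FALSE,
                    crop_flag = components$info$touches_crop_boundary,
                    animal_id = animal_id, cell_id = cell_id, region = region,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- ids[i]
    cls <- classify_component(components, id)
    rec$class[i] <- cls
    rec$volume_um3[i] <- component_volume(components, id)
    rec$surface_um2[i] <- component_surface_area(components, id)
    rec$diameter_nm[i] <- tryCatch(
      equivalent_diameter(components, id, diameter_method),
      error = function(e) NA_real_)  # sub-resolution blob with no contour
    if (cls == "tubule") {
      rec$length_um[i] <- longest_branch_length(components, id)
      rec$cell_width_um[i] <- cell_width_at(components, id)
    }
  }
  if (cell_width == "per_cell" && any(rec$class == "tubule")) {
    w <- mean(rec$cell_width_um[rec$class == "tubule"], na.rm = TRUE)
    rec$cell_width_um[rec$class == "tubule"] <- w
  }
  tub <- rec$class == "tubule"
  rec$length_fraction[tub] <- length_fraction(rec$length_um[tub],
                                              rec$cell_width_um[tub])
  rec$oblique_flag <- !is.na(rec$length_fraction) & rec$length_fraction > 1
  rec
}

#' Per-cell summary metrics
#'
#' Aggregates morphometry records of one cell: tubule density (count of
#' sarcolemma-connected tubules per unit cell volume) and tubule volume
#' fraction (percentage of the cell volume occupied by tubules), together
#' with the fragment summaries of [fragment_summary()].
#'
#' @param records morphometry records of one cell ([measure_components()]).
#' @param cell_volume_um3 cell volume in \eqn{\mu m^3}.
#' @return One-row data.frame: `n_tubules`, `tubule_density_um3` (um^-3),
#'   `tubule_volume_fraction_pct`, `n_fragments`, `fragment_density_um3`,
#'   `mean_fragment_volume_um3`, `fragment_volume_fraction_pct`,
#'   `n_indeterminate`, plus the grouping columns of the records.
#' @export
cell_summaries <- function(records, cell_volume_um3) {
  if (cell_volume_um3 <= 0) stop("cell volume must be positive")
  if (nrow(records) > 1L && length(unique(records$cell_id)) > 1L)
    stop("records must come from a single cell")
  tub <- records[records$class == "tubule", , drop = FALSE]
  fs <- fragment_summary(records, cell_volume_um3)
  data.frame(animal_id = if (nrow(records)) records$animal_id[1] else NA_character_,
             cell_id = if (nrow(records)) records$cell_id[1] else NA_character_,
             region = if (nrow(records)) records$region[1] else NA_character_,
             cell_volume_um3 = cell_volume_um3,
             n_tubules = nrow(tub),
             tubule_density_um3 = nrow(tub) / cell_volume_um3,
             tubule_volume_fraction_pct = sum(tub$volume_um3) / cell_volume_um3 * 100,
             n_fragments = fs$fragment_count,
             fragment_density_um3 = fs$fragment_density_um3,
             mean_fragment_volume_um3 = fs$mean_fragment_volume_um3,
             fragment_volume_fraction_pct = fs$fragment_volume_fraction_pct,
             n_indeterminate = sum(records$class == "indeterminate"),
             stringsAsFactors = FALSE)
}

#' Fragment summary of one cell
#'
#' Count, density, mean volume and volume fraction of the orphaned fragments
#' (components not connected to the extracellular space). Indeterminate
#' components (cut by the crop face) are excluded and counted separately.
#'
#' @inheritParams cell_summaries
#' @return One-row data.frame: `fragment_count`, `fragment_density_um3`,
#'   `mean_fragment_volume_um3` (`NA` when no fragments),
#'   `fragment_volume_fraction_pct`, `indeterminate_count`.
#' @export
fragment_summary <- function(records, cell_volume_um3) {
  if (cell_volume_um3 <= 0) stop("cell volume must be positive")
  fr <- records[records$class == "fragment", , drop = FALSE]
  data.frame(fragment_count = nrow(fr),
             fragment_density_um3 = nrow(fr) / cell_volume_um3,
             mean_fragment_volume_um3 = if (nrow(fr)) mean(fr$volume_um3) else NA_real_,
             fragment_volume_fraction_pct = sum(fr$volume_um3) / cell_volume_um3 * 100,
             indeterminate_count = sum(records$class == "indeterminate"))
}

#' Random subsample of tubule records
#'
#' Uniform sample without replacement of `min(k, n)` tubule records,
#' deterministic given `seed`; mirrors the convention of measuring length and
#' diameter on 15 randomly chosen tubules per cell while volume and surface
#' area use all tubules.
#'
#' @param records morphometry records of one cell's tubules.
#' @param k sample size (default 15).
#' @param seed integer seed.
#' @return The sampled rows of `records`.
#' @export
subsample_metrics <- function(records, k = 15L, seed = 1L) {
  tub <- records[records$class == "tubule", , drop = FALSE]
  n <- nrow(tub)
  if (n <= k) {
    if (n < k) warning("only ", n, " tubule record(s) available for subsample of ", k)
    return(tub)
  }
  sel <- with_seed(seed, sample.int(n, k))
  tub[sort(sel), , drop = FALSE]
}
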