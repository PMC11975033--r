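## Mediolateral binning of atlas-mapped neurons.
##
## Each cortical hemisphere is divided into 5 equal-width half-open bins
## running from the midline to the lateral cortical edge of the same
## rostro-caudal slice. Bin 0 (most medial) is cingulate cortex, bins 1-2
## medial cortex, bins 3-4 lateral cortex.

ML_CLASSES <- c("cingulate", "medial", "medial", "lateral", "lateral")

#' Class label for a mediolateral bin
#'
#' @param bin Integer bin indices 0-4 (`NA` passes through).
#' @return Character vector: bin 0 -> "cingulate", bins 1-2 -> "medial",
#'   bins 3-4 -> "lateral".
#' @export
ml_class <- function(bin) {
  out <- rep(NA_character_, length(bin))
  ok <- !is.na(bin) & bin >= 0 & bin <= 4
  out[ok] <- ML_CLASSES[bin[ok] + 1L]
  out
}

#' Assign hemisphere from the mediolateral coordinate
#'
#' Points exactly on the midline are assigned to the right hemisphere
#' (documented tie rule).
#'
#' @param ml_um Numeric vector of mediolateral coordinates (micrometers).
#' @param midline_ml_um Midline coordinate (micrometers).
#' @return Character vector of "left"/"right".
#' @export
assign_hemisphere <- function(ml_um, midline_ml_um) {
  stopifnot(all(is.finite(ml_um)))
  ifelse(ml_um >= midline_ml_um, "right", "left")
}

#' Mediolateral extent of cortex in one hemisphere of one slice
#'
#' The extent runs from the midline to the far (lateral) edge of the
#' lateral-most cortex voxel in the requested rostro-caudal slice and
#' hemisphere. `ml_max_um` is expressed as midline + width, so bins are
#' computed on the distance `|ml - midline|` identically in both
#' hemispheres.
#'
#' @param atl An `atlas` object.
#' @param ap_slice_index 0-based voxel index along the rostro-caudal axis.
#' @param hemisphere "left" or "right".
#' @param cortex_region_id Region id of cortex (descendants included).
#' @return List with `ap_slice_index`, `hemisphere`, `ml_min_um` (the
#'   midline) and `ml_max_um` (midline + hemisphere cortical width).
#' @export
cortical_extent <- function(atl, ap_slice_index, hemisphere, cortex_region_id) {
  stopifnot(inherits(atl, "atlas"), hemisphere %in% c("left", "right"))
  d <- dim(atl$labels)
  if (ap_slice_index < 0 || ap_slice_index >= d[1]) {
    stopf("slice %d has no cortex voxels in the %s hemisphere",
          ap_slice_index, hemisphere, class = "atlastrace_empty_extent_error")
  }
  ids <- region_descendants(atl, cortex_region_id)
  slc <- atl$labels[ap_slice_index + 1L, , , drop = TRUE]  # z x ml
  h <- atl$voxel_size_um
  ml_cols <- which(apply(matrix(slc %in% ids, nrow = d[2]), 2, any)) - 1L
  ctr <- (ml_cols + 0.5) * h
  ml_cols <- if (hemisphere == "right") ml_cols[ctr >= atl$midline_ml_um]
             else ml_cols[ctr < atl$midline_ml_um]
  if (!length(ml_cols)) {
    stopf("slice %d has no cortex voxels in the %s hemisphere",
          ap_slice_index, hemisphere, class = "atlastrace_empty_extent_error")
  }
  width <- if (hemisphere == "right") {
    (max(ml_cols) + 1) * h - atl$midline_ml_um
  } else {
    atl$midline_ml_um - min(ml_cols) * h
  }
  list(ap_slice_index = as.integer(ap_slice_index), hemisphere = hemisphere,
       ml_min_um = atl$midline_ml_um,
       ml_max_um = atl$midline_ml_um + width)
}

#' Mediolateral bin of a point within a hemisphere extent
#'
#' `bin = floor(5 * |ml - midline| / width)` with half-open bin boundaries;
#' a point exactly at the lateral edge is clamped into bin 4. Points lateral
#' of the extent return `NA` (flagged out-of-extent by callers).
#'
#' @param ml_um Mediolateral coordinates (micrometers).
#' @param extent Extent from [cortical_extent()] (or a list with `ml_min_um`,
#'   `ml_max_um` for atlas-free sections).
#' @return Integer bins 0-4, `NA` for out-of-extent points.
#' @export
ml_bin <- function(ml_um, extent) {
  width <- extent$ml_max_um - extent$ml_min_um
  stopifnot(width > 0)
  rel <- abs(ml_um - extent$ml_min_um) / width
  bin <- floor(5 * rel)
  bin[rel == 1] <- 4        # lateral edge belongs to the outermost bin
  bin[rel > 1] <- NA        # lateral of the cortical edge
  as.integer(bin)
}

#' Map annotated cells into atlas space and mediolateral bins
#'
#' Applies each section's planar affine transform to the cell pixel
#' coordinates, assigns hemisphere, computes the 5-bin mediolateral class,
#' and looks up the atlas region under each cell.
#'
#' @param transforms Named list of `planar_affine` objects keyed by
#'   section id.
#' @param cells Data frame with columns `section_id`, `animal_id`, `group`,
#'   `channel`, `u_px`, `v_px`.
#' @param atl An `atlas` object, or `NULL` when `extents` supplies manual
#'   per-section extents (sections without a reference atlas).
#' @param cortex_region_id Cortex region id used for the binning extent.
#' @param extents Optional data frame of manual extents with columns
#'   `section_id`, `hemisphere`, `ml_min_um`, `ml_max_um`; overrides
#'   atlas-derived extents.
#' @param midline_ml_um Midline override; defaults to the atlas midline.
#' @return Data frame of cell records: input ids plus `x_um`, `z_um`,
#'   `ml_um`, `hemisphere`, `ml_bin`, `ml_class`, `region_id`
#'   (`NA` if background or outside the grid) and `in_extent`.
#' @export
map_cells <- function(transforms, cells, atl = NULL, cortex_region_id = NULL,
                      extents = NULL, midline_ml_um = NULL) {
  need <- c("section_id", "animal_id", "group", "channel", "u_px", "v_px")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    stopf("cell table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(cells) == 0L) {
    out <- cells[, need]
    out$x_um <- out$z_um <- out$ml_um <- numeric(0)
    out$hemisphere <- out$ml_class <- character(0)
    out$ml_bin <- out$region_id <- integer(0)
    out$in_extent <- logical(0)
    return(out)
  }
  missing_tr <- setdiff(unique(cells$section_id), names(transforms))
  if (length(missing_tr)) {
    stopf("no fitted transform for section(s): %s",
          paste(missing_tr, collapse = ", "))
  }
  if (is.null(midline_ml_um)) {
    if (is.null(atl)) stopf("midline_ml_um required when no atlas is given")
    midline_ml_um <- atl$midline_ml_um
  }

  xyz <- matrix(NA_real_, nrow(cells), 3,
                dimnames = list(NULL, c("x_um", "z_um", "ml_um")))
  for (sid in unique(cells$section_id)) {
    rows <- which(cells$section_id == sid)
    xyz[rows, ] <- apply_affine(transforms[[sid]],
                                as.matrix(cells[rows, c("u_px", "v_px")]))
  }
  hemi <- assign_hemisphere(xyz[, "ml_um"], midline_ml_um)

  bin <- rep(NA_integer_, nrow(cells))
  extent_cache <- new.env(parent = emptyenv())
  get_extent <- function(sid, ap_idx, hm) {
    if (!is.null(extents)) {
      row <- extents[extents$section_id == sid & extents$hemisphere == hm, ]
      if (nrow(row) == 1L) {
        return(list(ml_min_um = row$ml_min_um, ml_max_um = row$ml_max_um))
      }
    }
    if (is.null(atl)) return(NULL)
    key <- paste(ap_idx, hm)
    if (!is.null(extent_cache[[key]])) return(extent_cache[[key]])
    ext <- tryCatch(
      cortical_extent(atl, ap_idx, hm, cortex_region_id),
      atlastrace_empty_extent_error = function(e) NULL)
    extent_cache[[key]] <- ext
    ext
  }
  h <- if (!is.null(atl)) atl$voxel_size_um else NA_real_
  for (r in seq_len(nrow(cells))) {
    ap_idx <- if (is.na(h)) NA_integer_ else floor(xyz[r, "x_um"] / h)
    ext <- get_extent(cells$section_id[r], ap_idx, hemi[r])
    if (!is.null(ext)) bin[r] <- ml_bin(xyz[r, "ml_um"], ext)
  }
  in_extent <- !is.na(bin)
  n_out <- sum(!in_extent)
  if (n_out > 0) {
    message(sprintf(
      "map_cells: %d cell(s) outside the cortical extent, flagged and excluded from bin counts",
      n_out))
  }

  region_id <- if (!is.null(atl)) {
    lab <- label_at(atl, xyz)
    lab[!is.na(lab) & lab == 0L] <- NA_integer_
    lab
  } else rep(NA_integer_, nrow(cells))

  out <- cells[, need]
  out$x_um <- xyz[, "x_um"]
  out$z_um <- xyz[, "z_um"]
  out$ml_um <- xyz[, "ml_um"]
  out$hemisphere <- hemi
  out$ml_bin <- bin
  out$ml_class <- ml_class(bin)
  out$region_id <- region_id
  out$in_extent <- in_extent
  rownames(out) <- NULL
  out
}

#' Per-group counts of cells by mediolateral class
#'
#' @param cell_records Output of [map_cells()].
#' @return Data frame with columns `group`, `ml_class`, `n` (in-extent cells
#'   only).
#' @export
count_by_class <- function(cell_records) {
  rec <- cell_records[cell_records$in_extent, ]
  classes <- c("cingulate", "medial", "lateral")
  groups <- sort(unique(cell_records$group))
  out <- expand.grid(group = groups, ml_class = classes,
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(g, cl) sum(rec$group == g & rec$ml_class == cl),
                  out$group, out$ml_class)
  out[order(out$group, match(out$ml_class, classes)), , drop = FALSE]
}

#' Per-group distribution along the rostro-caudal and dorso-ventral axes
#'
#' Reports the arithmetic mean and standard error (sample SD over sqrt(n))
#' of the rostro-caudal (x) and dorso-ventral (z) coordinates per group.
#'
#' @param cell_records Output of [map_cells()] (needs `group`, `x_um`,
#'   `z_um`).
#' @return Data frame with columns `group`, `n`, `mean_x_um`, `sem_x_um`,
#'   `mean_z_um`, `sem_z_um`. Groups with a single cell get `NA` SEMs and a
#'   warning.
#' @export
summarize_distribution <- function(cell_records) {
  stopifnot(nrow(cell_records) >= 1L)
  groups <- sort(unique(cell_records$group))
  rows <- lapply(groups, function(g) {
    sub <- cell_records[cell_records$group == g, ]
    n <- nrow(sub)
    if (n == 1L) {
      warnf("group '%s' has a single cell; SEM undefined", g)
    }
    data.frame(group = g, n = n,
               mean_x_um = mean(sub$x_um), sem_x_um = sem(sub$x_um),
               mean_z_um = mean(sub$z_um), sem_z_um = sem(sub$z_um),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
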