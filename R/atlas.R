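## Reference atlas: 3-D label volume + region hierarchy.
##
## Axis semantics are fixed: axis 1 = rostro-caudal (x), axis 2 =
## dorso-ventral (z), axis 3 = medio-lateral (ml). Voxel i (0-based) along
## any axis spans the half-open physical interval [i*h, (i+1)*h) um.

#' Construct an atlas object
#'
#' @param labels 3-D integer array; 0 is background, any other value must be
#'   a `region_id` present in `regions`.
#' @param regions Data frame with columns `region_id`, `acronym`, `name`,
#'   `parent_id` (NA only for the root) and `category`
#'   (one of motor/sensory/behavior/other).
#' @param voxel_size_um Isotropic voxel edge length in micrometers.
#' @param midline_ml_um Medio-lateral coordinate of the midline in
#'   micrometers; defaults to half the ML physical extent.
#' @return An object of class `atlas`.
#' @export
atlas <- function(labels, regions, voxel_size_um,
                  midline_ml_um = dim(labels)[3] * voxel_size_um / 2) {
  if (length(dim(labels)) != 3L) {
    stopf("labels must be a 3-D array", class = "atlastrace_format_error")
  }
  if (!is.numeric(labels) || any(labels != floor(labels), na.rm = TRUE)) {
    stopf("label volume must contain integers",
          class = "atlastrace_format_error")
  }
  storage.mode(labels) <- "integer"
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0) {
    stopf("voxel_size_um must be positive")
  }
  regions <- validate_regions(regions)
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  unknown <- setdiff(present, regions$region_id)
  if (length(unknown)) {
    stopf("label volume contains region id(s) absent from the region table: %s",
          paste(unknown, collapse = ", "),
          class = "atlastrace_validation_error")
  }
  structure(
    list(labels = labels, regions = regions,
         voxel_size_um = as.numeric(voxel_size_um),
         midline_ml_um = as.numeric(midline_ml_um)),
    class = "atlas"
  )
}

#' @export
print.atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<atlas> %d x %d x %d voxels @ %g um (%.1f x %.1f x %.1f mm), %d regions\n",
    d[1], d[2], d[3], x$voxel_size_um,
    d[1] * x$voxel_size_um / 1000, d[2] * x$voxel_size_um / 1000,
    d[3] * x$voxel_size_um / 1000, nrow(x$regions)))
  invisible(x)
}

validate_regions <- function(regions) {
  regions <- as.data.frame(regions)
  need <- c("region_id", "acronym", "name", "parent_id", "category")
  missing <- setdiff(need, names(regions))
  if (length(missing)) {
    stopf("region table lacks column(s): %s", paste(missing, collapse = ", "),
          class = "atlastrace_validation_error")
  }
  regions$region_id <- as.integer(regions$region_id)
  regions$parent_id <- suppressWarnings(as.integer(regions$parent_id))
  if (any(regions$region_id <= 0)) {
    stopf("region ids must be positive integers",
          class = "atlastrace_validation_error")
  }
  if (anyDuplicated(regions$region_id)) {
    stopf("duplicate region ids", class = "atlastrace_validation_error")
  }
  if (anyDuplicated(regions$acronym)) {
    stopf("duplicate region acronyms", class = "atlastrace_validation_error")
  }
  bad_cat <- setdiff(regions$category, c("motor", "sensory", "behavior", "other"))
  if (length(bad_cat)) {
    stopf("unknown region category: %s", paste(bad_cat, collapse = ", "),
          class = "atlastrace_validation_error")
  }
  roots <- is.na(regions$parent_id)
  if (sum(roots) != 1L) {
    stopf("region hierarchy must have exactly one root (parent_id NA)",
          class = "atlastrace_validation_error")
  }
  orphan <- setdiff(regions$parent_id[!roots], regions$region_id)
  if (length(orphan)) {
    stopf("parent_id(s) not present in table: %s",
          paste(orphan, collapse = ", "),
          class = "atlastrace_validation_error")
  }
  # tree check: walking parents from every node must reach the root
  parent <- stats::setNames(regions$parent_id, regions$region_id)
  root_id <- regions$region_id[roots]
  for (id in regions$region_id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) {
        stopf("cycle in region hierarchy at id %d", id,
              class = "atlastrace_validation_error")
      }
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
    }
  }
  regions[order(regions$region_id), need]
}

#' Load an atlas from disk
#'
#' The volume may be NRRD (raw encoding) or NIfTI (`.nii`, `.nii.gz`); the
#' region hierarchy may be JSON (list of objects with fields `id`, `acronym`,
#' `name`, `parent_structure_id`, `category`) or a CSV with the same columns
#' as [atlas()].
#'
#' @param volume_path Path to the label volume.
#' @param regions_path Path to the region hierarchy.
#' @return An `atlas` object; all invariants validated.
#' @export
load_atlas <- function(volume_path, regions_path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", volume_path)))
  if (ext == "nrrd") {
    nr <- read_nrrd(volume_path)
    labels <- nr$data
    vs <- as.numeric(nr$header[["voxel_size_um"]] %||% NA)
    if (is.na(vs)) {
      sd_field <- nr$header[["space directions"]]
      if (!is.null(sd_field)) {
        nums <- as.numeric(regmatches(sd_field,
          gregexpr("[-0-9.eE+]+", sd_field))[[1]])
        vs <- max(abs(nums))
      }
    }
    if (is.na(vs)) stopf("NRRD header lacks voxel size",
                         class = "atlastrace_format_error")
    mid <- as.numeric(nr$header[["midline_ml_um"]] %||% NA)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(volume_path)
    labels <- array(as.numeric(img), dim = dim(img))
    if (any(labels != floor(labels))) {
      stopf("NIfTI volume is not integer-valued",
            class = "atlastrace_format_error")
    }
    vs <- RNifti::pixdim(img)[1]
    mid <- NA_real_
  } else {
    stopf("unsupported volume format: %s", volume_path,
          class = "atlastrace_format_error")
  }
  regions <- load_regions(regions_path)
  if (is.na(mid)) mid <- dim(labels)[3] * vs / 2
  atlas(labels, regions, voxel_size_um = vs, midline_ml_um = mid)
}

#' Save an atlas to disk
#'
#' @param atl An `atlas` object.
#' @param volume_path Output volume path (`.nrrd` or `.nii`).
#' @param regions_path Output region-table path (`.json` or `.csv`).
#' @export
save_atlas <- function(atl, volume_path, regions_path) {
  stopifnot(inherits(atl, "atlas"))
  ext <- tolower(tools::file_ext(volume_path))
  if (ext == "nrrd") {
    write_nrrd(atl$labels, volume_path,
               fields = c(
                 voxel_size_um = format(atl$voxel_size_um),
                 midline_ml_um = format(atl$midline_ml_um),
                 axes = "x-rostrocaudal z-dorsoventral ml-mediolateral"),
               space_um = atl$voxel_size_um)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(atl$labels)
    RNifti::pixdim(img) <- rep(atl$voxel_size_um, 3)
    RNifti::writeNifti(img, volume_path)
  } else {
    stopf("unsupported volume format: %s", volume_path,
          class = "atlastrace_format_error")
  }
  save_regions(atl$regions, regions_path)
  invisible(c(volume_path, regions_path))
}

load_regions <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    js <- read_json_file(path)
    df <- as.data.frame(js)
    # Allen structure-graph-like field names
    nm <- names(df)
    nm[nm == "id"] <- "region_id"
    nm[nm == "parent_structure_id"] <- "parent_id"
    names(df) <- nm
    df
  } else if (ext == "csv") {
    read_table_csv(path)
  } else {
    stopf("unsupported region-table format: %s", path,
          class = "atlastrace_format_error")
  }
}

save_regions <- function(regions, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    out <- lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      list(id = r$region_id, acronym = r$acronym, name = r$name,
           parent_structure_id = if (is.na(r$parent_id)) NULL else r$parent_id,
           category = r$category)
    })
    write_json_file(out, path)
  } else if (ext == "csv") {
    write_table_csv(regions, path)
  } else {
    stopf("unsupported region-table format: %s", path,
          class = "atlastrace_format_error")
  }
  invisible(path)
}

#' Region ids of a region and all its descendants
#'
#' @param atl An `atlas` object.
#' @param region_id Region id present in the atlas's region table.
#' @return Integer vector of region ids (the region first).
#' @export
region_descendants <- function(atl, region_id) {
  stopifnot(inherits(atl, "atlas"))
  ids <- atl$regions$region_id
  if (!region_id %in% ids) {
    stopf("unknown region id: %s", region_id,
          class = "atlastrace_lookup_error")
  }
  out <- integer(0)
  frontier <- as.integer(region_id)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- ids[atl$regions$parent_id %in% frontier & !is.na(atl$regions$parent_id)]
  }
  out
}

#' Voxels labeled with a region
#'
#' @param atl An `atlas` object.
#' @param region_id Region id (background 0 is not a region).
#' @param include_descendants If `TRUE` (default) include voxels of all
#'   hierarchy descendants.
#' @return Integer matrix with columns `i`, `j`, `k` of 0-based voxel
#'   indices along the rostro-caudal, dorso-ventral and medio-lateral axes.
#' @export
region_voxels <- function(atl, region_id, include_descendants = TRUE) {
  stopifnot(inherits(atl, "atlas"))
  if (length(region_id) != 1L || is.na(region_id) || region_id == 0 ||
      !region_id %in% atl$regions$region_id) {
    stopf("unknown region id: %s", region_id,
          class = "atlastrace_lookup_error")
  }
  ids <- if (include_descendants) region_descendants(atl, region_id)
         else as.integer(region_id)
  idx <- which(array(atl$labels %in% ids, dim = dim(atl$labels)),
               arr.ind = TRUE)
  out <- idx - 1L  # 0-based
  colnames(out) <- c("i", "j", "k")
  out
}

## region_voxels regenerated on an arbitrary voxel grid (same origin):
## each voxel of the new grid takes the label under its center.
region_voxels_at <- function(atl, region_id, voxel_size_um,
                             include_descendants = TRUE) {
  ids <- if (include_descendants) region_descendants(atl, region_id)
         else as.integer(region_id)
  d <- dim(atl$labels)
  ext <- d * atl$voxel_size_um
  n <- ceiling(ext / voxel_size_um)
  ctr <- lapply(seq_len(3), function(a) {
    c <- (seq_len(n[a]) - 0.5) * voxel_size_um
    c[c < ext[a]]  # drop voxels whose center falls past the atlas
  })
  src <- lapply(seq_len(3), function(a) {
    floor(ctr[[a]] / atl$voxel_size_um) + 1L
  })
  sub <- atl$labels[src[[1]], src[[2]], src[[3]], drop = FALSE]
  idx <- which(array(sub %in% ids, dim = dim(sub)), arr.ind = TRUE)
  out <- idx - 1L
  colnames(out) <- c("i", "j", "k")
  out
}

#' Map physical points to voxel indices
#'
#' Half-open convention: a coordinate of exactly `(i+1)*voxel_size` falls in
#' voxel `i+1`. Points outside the grid get `NA` indices.
#'
#' @param atl An `atlas` object.
#' @param points_um Numeric matrix (n x 3) of coordinates in micrometers, or
#'   a length-3 vector for a single point.
#' @return Integer matrix (n x 3) of 0-based voxel indices with `NA` rows for
#'   out-of-grid points.
#' @export
point_to_voxel <- function(atl, points_um) {
  stopifnot(inherits(atl, "atlas"))
  if (is.null(dim(points_um))) points_um <- matrix(points_um, ncol = 3)
  pts <- as.matrix(points_um)
  idx <- floor(pts / atl$voxel_size_um)
  d <- dim(atl$labels)
  outside <- idx[, 1] < 0 | idx[, 2] < 0 | idx[, 3] < 0 |
    idx[, 1] >= d[1] | idx[, 2] >= d[2] | idx[, 3] >= d[3]
  idx[outside, ] <- NA_real_
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Atlas label under each physical point
#'
#' @inheritParams point_to_voxel
#' @return Integer vector of region ids; 0 for background, `NA` outside the
#'   grid.
#' @export
label_at <- function(atl, points_um) {
  idx <- point_to_voxel(atl, points_um)
  out <- rep(NA_integer_, nrow(idx))
  ok <- !is.na(idx[, 1])
  if (any(ok)) {
    lin <- idx[ok, 1] + 1L +
      dim(atl$labels)[1] * (idx[ok, 2] + dim(atl$labels)[2] * idx[ok, 3])
    out[ok] <- atl$labels[lin]
  }
  out
}
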