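## 3-D injection-volume reconstruction: outline points -> convex surface ->
## smoothed mesh -> enclosed 100-um voxels -> volumes and percent overlaps.

#' Triangulate an injection boundary cloud
#'
#' Builds the boundary surface of the 3-D Delaunay triangulation of the
#' pooled outline points, which for a point cloud is its convex hull,
#' oriented outward.
#'
#' @param points Numeric matrix (n x 3) of outline coordinates in
#'   micrometers (n >= 4, non-coplanar).
#' @return A closed `surface_mesh`.
#' @export
triangulate_boundary <- function(points) {
  mesh <- convex_hull_3d(points)
  stopifnot(is_closed_mesh(mesh), mesh_volume(mesh) > 0)
  mesh
}

#' Voxelize a closed mesh on an atlas-anchored grid
#'
#' A voxel is retained iff its center lies inside the closed surface
#' (ray-parity containment). The grid is anchored at the atlas origin so
#' injection solids and structure masks share indices: voxel `(i,j,k)` has
#' center `((i+0.5) h, (j+0.5) h, (k+0.5) h)`.
#'
#' @param mesh A closed `surface_mesh` (micrometer coordinates).
#' @param voxel_size_um Voxel edge length in micrometers (default 100).
#' @return An object of class `voxel_solid`: list with `voxels` (n x 3
#'   integer, 0-based), `voxel_size_um` and `volume_mm3`.
#' @export
voxelize <- function(mesh, voxel_size_um = 100) {
  if (!is_closed_mesh(mesh)) {
    stopf("mesh is not closed", class = "atlastrace_topology_error")
  }
  h <- voxel_size_um
  lo <- floor(apply(mesh$vertices, 2, min) / h)
  hi <- floor(apply(mesh$vertices, 2, max) / h)
  grid <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  centers <- (as.matrix(grid) + 0.5) * h
  keep <- points_in_mesh(mesh, centers)
  vox <- as.matrix(grid)[keep, , drop = FALSE]
  storage.mode(vox) <- "integer"
  if (nrow(vox) == 0L) {
    warnf("mesh encloses no voxel centers at %g um; empty solid", h)
  }
  voxel_solid(vox, h)
}

#' Construct a voxel solid
#'
#' @param voxels Integer matrix (n x 3) of 0-based voxel indices.
#' @param voxel_size_um Voxel edge length in micrometers.
#' @return A `voxel_solid` with `volume_mm3 = n * (h/1000)^3`.
#' @export
voxel_solid <- function(voxels, voxel_size_um) {
  voxels <- matrix(as.integer(voxels), ncol = 3,
                   dimnames = list(NULL, c("i", "j", "k")))
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um,
                 volume_mm3 = nrow(voxels) * (voxel_size_um / 1000)^3),
            class = "voxel_solid")
}

#' @export
print.voxel_solid <- function(x, ...) {
  cat(sprintf("<voxel_solid> %d voxels @ %g um = %.4f mm^3\n",
              nrow(x$voxels), x$voxel_size_um, x$volume_mm3))
  invisible(x)
}

#' Percent overlap of a voxel solid with a target voxel set
#'
#' `percent = 100 * |source intersect target| / |target|`; also usable for
#' volume-versus-volume comparisons by passing a second solid as target.
#'
#' @param source A `voxel_solid`.
#' @param target A `voxel_solid`, or an integer matrix of 0-based voxel
#'   indices on the same grid (e.g. from [region_voxels()]).
#' @param target_voxel_size_um Voxel size of `target` when it is a bare
#'   matrix; must equal the source's.
#' @param source_label,target_label Labels carried into the result.
#' @return Data frame with `source`, `target`, `overlap_voxels`,
#'   `target_voxels`, `percent`.
#' @export
percent_overlap <- function(source, target,
                            target_voxel_size_um = NULL,
                            source_label = "source", target_label = "target") {
  stopifnot(inherits(source, "voxel_solid"))
  if (inherits(target, "voxel_solid")) {
    tvox <- target$voxels
    tvs <- target$voxel_size_um
  } else {
    tvox <- target
    tvs <- target_voxel_size_um %||% source$voxel_size_um
  }
  if (!isTRUE(all.equal(tvs, source$voxel_size_um))) {
    stopf("voxel grids differ (%g vs %g um)", source$voxel_size_um, tvs,
          class = "atlastrace_grid_mismatch_error")
  }
  if (nrow(tvox) == 0L) {
    stopf("target voxel set is empty: percent overlap undefined",
          class = "atlastrace_empty_target_error")
  }
  ov <- sum(voxel_keys(source$voxels) %in% voxel_keys(tvox))
  data.frame(source = source_label, target = target_label,
             overlap_voxels = ov, target_voxels = nrow(tvox),
             percent = 100 * ov / nrow(tvox),
             stringsAsFactors = FALSE)
}

#' Reconstruct an injection volume from outline points
#'
#' Runs the full chain: convex triangulation of the pooled outline
#' vertices, Laplacian smoothing, and voxelization on the atlas-anchored
#' grid.
#'
#' @param points Numeric matrix (n x 3) of outline coordinates
#'   (micrometers).
#' @param voxel_size_um Voxel grid size (default 100).
#' @param smooth_iterations,smooth_lambda Laplacian smoothing parameters
#'   (defaults 10 and 0.5; `smooth_iterations = 0` disables smoothing).
#' @return List with `mesh` (smoothed), `solid` (a `voxel_solid`) and the
#'   parameters used.
#' @export
reconstruct_injection <- function(points, voxel_size_um = 100,
                                  smooth_iterations = 10L,
                                  smooth_lambda = 0.5) {
  mesh <- triangulate_boundary(points)
  mesh <- laplacian_smooth(mesh, smooth_iterations, smooth_lambda)
  solid <- voxelize(mesh, voxel_size_um)
  list(mesh = mesh, solid = solid,
       params = list(voxel_size_um = voxel_size_um,
                     smooth_iterations = smooth_iterations,
                     smooth_lambda = smooth_lambda))
}

#' Overlap of an injection solid with atlas structures
#'
#' @param solid A `voxel_solid` on the atlas-anchored grid.
#' @param atl An `atlas` object.
#' @param region_ids Integer vector of target region ids (descendants
#'   included).
#' @param source_label Label for the source column.
#' @return Data frame (one row per region) with overlap counts, target
#'   sizes, percents and the solid's volume.
#' @export
structure_overlaps <- function(solid, atl, region_ids,
                               source_label = "injection") {
  rows <- lapply(region_ids, function(rid) {
    tvox <- if (isTRUE(all.equal(solid$voxel_size_um, atl$voxel_size_um))) {
      region_voxels(atl, rid)
    } else {
      region_voxels_at(atl, rid, solid$voxel_size_um)
    }
    acr <- atl$regions$acronym[atl$regions$region_id == rid]
    res <- percent_overlap(solid, tvox, solid$voxel_size_um,
                           source_label = source_label, target_label = acr)
    res$region_id <- rid
    res$volume_mm3 <- solid$volume_mm3
    res
  })
  do.call(rbind, rows)
}
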