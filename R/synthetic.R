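## Synthetic histology generator: a toy labeled atlas (cortical shell +
## brainstem nuclei), sections with known planar-affine pixel frames, cell
## cohorts with planted mediolateral bin proportions, ellipsoidal injection
## volumes with analytic ground truth, and Poisson axon-signal images.
## Every generator records a ground-truth manifest sufficient to recompute
## the expected output of the downstream modules.

TOY_NUCLEI <- data.frame(
  region_id = 21:26,
  acronym = c("MRN", "PRNr", "PRNc", "SPV", "MDRNd", "GRN"),
  name = c("midbrain reticular nucleus", "pontine reticular nucleus rostral",
           "pontine reticular nucleus caudal", "spinal trigeminal nucleus",
           "medullary reticular nucleus dorsal", "gigantocellular nucleus"),
  category = c("motor", "behavior", "motor", "sensory", "sensory", "motor"),
  stringsAsFactors = FALSE
)

toy_region_table <- function() {
  rbind(
    data.frame(region_id = 1L, acronym = "root", name = "brain",
               parent_id = NA_integer_, category = "other"),
    data.frame(region_id = 10L, acronym = "CTX", name = "cerebral cortex",
               parent_id = 1L, category = "other"),
    data.frame(region_id = 11L, acronym = "CTX-L", name = "cortex left",
               parent_id = 10L, category = "other"),
    data.frame(region_id = 12L, acronym = "CTX-R", name = "cortex right",
               parent_id = 10L, category = "other"),
    data.frame(region_id = 20L, acronym = "BS", name = "brainstem",
               parent_id = 1L, category = "other"),
    data.frame(region_id = TOY_NUCLEI$region_id, acronym = TOY_NUCLEI$acronym,
               name = TOY_NUCLEI$name, parent_id = 20L,
               category = TOY_NUCLEI$category)
  )
}

#' Generate the toy reference atlas
#'
#' Builds a labeled volume with a bilateral dorsal cortical shell running
#' from the midline to a known lateral edge, and six non-overlapping 8x8x8
#' brainstem nucleus blocks placed deterministically from the seed, under a
#' two-level region hierarchy with motor/sensory/behavior categories.
#'
#' @param seed Integer seed; the atlas is a pure function of it.
#' @param shape Grid shape (rostro-caudal, dorso-ventral, medio-lateral);
#'   each axis >= 20 voxels.
#' @param voxel_size_um Voxel edge length in micrometers (default 100).
#' @param out_dir Optional directory; when given, writes `atlas.nrrd`,
#'   `regions.json` and `atlas_manifest.json`.
#' @return List with `atlas` (an [atlas()] object) and `manifest` (ground
#'   truth: layout, extents, nucleus blocks).
#' @export
make_toy_atlas <- function(seed = 1L, shape = c(60L, 40L, 80L),
                           voxel_size_um = 100, out_dir = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 20L))
  shape <- as.integer(shape)
  h <- voxel_size_um
  labels <- array(0L, dim = shape)
  mid_k <- shape[3] %/% 2L                     # midline at k = mid_k boundary
  midline_um <- mid_k * h

  ## cortical shell: dorsal slab from the midline out to a known ML edge
  ctx_width <- as.integer(round(0.35 * shape[3]))
  ctx_x <- c(4L, shape[1] - 5L)                # 0-based inclusive
  ctx_z <- c(2L, min(9L, shape[2] - 1L))
  right_k <- c(mid_k, mid_k + ctx_width - 1L)
  left_k <- c(mid_k - ctx_width, mid_k - 1L)
  labels[(ctx_x[1]:ctx_x[2]) + 1L, (ctx_z[1]:ctx_z[2]) + 1L,
         (left_k[1]:left_k[2]) + 1L] <- 11L
  labels[(ctx_x[1]:ctx_x[2]) + 1L, (ctx_z[1]:ctx_z[2]) + 1L,
         (right_k[1]:right_k[2]) + 1L] <- 12L

  ## brainstem nuclei: 8x8x8 blocks in the ventral half, non-overlapping
  blk <- 8L
  rng_state <- set_local_seed(seed)
  on.exit(restore_seed(rng_state), add = TRUE)
  z_lo <- as.integer(ceiling(shape[2] * 0.55))
  placements <- list()
  occupied <- matrix(numeric(0), ncol = 6)   # corner + corner+blk per axis
  for (r in seq_len(nrow(TOY_NUCLEI))) {
    repeat {
      corner <- c(sample(seq(ctx_x[1], shape[1] - blk - 1L), 1L),
                  sample(seq(z_lo, shape[2] - blk - 1L), 1L),
                  sample(seq(2L, shape[3] - blk - 2L), 1L))
      ok <- TRUE
      if (nrow(occupied) > 0) {
        for (q in seq_len(nrow(occupied))) {
          sep <- any(corner >= occupied[q, 4:6] | corner + blk <= occupied[q, 1:3])
          if (!sep) { ok <- FALSE; break }
        }
      }
      if (ok) break
    }
    occupied <- rbind(occupied, c(corner, corner + blk))
    placements[[TOY_NUCLEI$acronym[r]]] <- list(
      region_id = TOY_NUCLEI$region_id[r], corner = corner, size = blk)
    labels[(corner[1]:(corner[1] + blk - 1L)) + 1L,
           (corner[2]:(corner[2] + blk - 1L)) + 1L,
           (corner[3]:(corner[3] + blk - 1L)) + 1L] <- TOY_NUCLEI$region_id[r]
  }

  atl <- atlas(labels, toy_region_table(), voxel_size_um = h,
               midline_ml_um = midline_um)
  manifest <- list(
    seed = seed, shape = shape, voxel_size_um = h,
    midline_ml_um = midline_um,
    cortex = list(
      region_id = 10L, x_index_range = ctx_x, z_index_range = ctx_z,
      left = list(region_id = 11L, ml_index_range = left_k,
                  ml_um_range = c(left_k[1] * h, (left_k[2] + 1) * h)),
      right = list(region_id = 12L, ml_index_range = right_k,
                   ml_um_range = c(right_k[1] * h, (right_k[2] + 1) * h)),
      hemisphere_width_um = ctx_width * h),
    nuclei = placements)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_atlas(atl, file.path(out_dir, "atlas.nrrd"),
               file.path(out_dir, "regions.json"))
    write_json_file(manifest, file.path(out_dir, "atlas_manifest.json"))
  }
  list(atlas = atl, manifest = manifest)
}

## localized RNG: generators are bit-reproducible per seed and do not
## disturb the caller's RNG stream
set_local_seed <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  state
}

restore_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate sections and a labeled-cell cohort with planted bin proportions
#'
#' Sections are rostro-caudal planes of the toy atlas, each with a random
#' but recorded planar-affine pixel frame (rotation, scale, translation).
#' Cells realize exact per-bin counts (largest-remainder apportionment of
#' the planted proportions), are placed at known mediolateral positions
#' inside their bin, and converted to section pixel coordinates through the
#' inverse frame; optional Gaussian pixel jitter emulates annotation noise.
#'
#' @param atl Toy atlas from [make_toy_atlas()].
#' @param manifest Matching atlas manifest.
#' @param groups Named list: for each group, a numeric length-5 vector of
#'   planted bin proportions (bins 0-4, summing to 1).
#' @param cells_per_group Cells per group (scalar or named vector).
#' @param n_sections Number of sections (default 4, mirroring four
#'   pre-defined rostro-caudal levels).
#' @param pixel_noise_sd Gaussian jitter SD in pixels applied to cell and
#'   control-point pixel coordinates (default 0 = noiseless).
#' @param n_control_points Control points per section (default 8).
#' @param seed Integer seed.
#' @param out_dir Optional directory; writes `control_points.csv`,
#'   `cells.csv` and `cells_truth.json`.
#' @return List with `control_points`, `cells`, `transforms` (true
#'   per-section `planar_affine`s) and `truth` (per-cell bins and per-group
#'   class counts).
#' @export
simulate_sections_and_cells <- function(atl, manifest,
                                        groups = list(
                                          medial = c(0.1, 0.35, 0.35, 0.1, 0.1),
                                          lateral = c(0.05, 0.075, 0.075, 0.4, 0.4)),
                                        cells_per_group = 400L,
                                        n_sections = 4L,
                                        pixel_noise_sd = 0,
                                        n_control_points = 8L,
                                        seed = 1L, out_dir = NULL) {
  stopifnot(inherits(atl, "atlas"), n_sections >= 1L, n_control_points >= 4L)
  for (g in names(groups)) {
    if (abs(sum(groups[[g]]) - 1) > 1e-8 || length(groups[[g]]) != 5L) {
      stopf("planted bin proportions for group '%s' must be 5 values summing to 1", g)
    }
  }
  if (length(cells_per_group) == 1L && is.null(names(cells_per_group))) {
    cells_per_group <- stats::setNames(rep(cells_per_group, length(groups)),
                                       names(groups))
  }
  h <- atl$voxel_size_um
  rng_state <- set_local_seed(seed + 1000L)
  on.exit(restore_seed(rng_state), add = TRUE)

  ctx_x <- manifest$cortex$x_index_range
  ctx_z <- manifest$cortex$z_index_range
  width_um <- manifest$cortex$hemisphere_width_um
  midline <- atl$midline_ml_um
  bin_w <- width_um / 5

  sec_x_idx <- round(seq(ctx_x[1] + 1, ctx_x[2] - 1,
                         length.out = n_sections))
  section_ids <- sprintf("sec%02d", seq_len(n_sections))

  transforms <- list()
  cp_rows <- list()
  for (s in seq_len(n_sections)) {
    theta <- stats::runif(1, -pi, pi)
    scl <- stats::runif(1, 1.5, 3)             # um per pixel
    tz <- stats::runif(1, -500, 500)
    tml <- stats::runif(1, -500, 500)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    A <- rbind(c(0, 0), scl * R)               # rows: x, z, ml
    b <- c((sec_x_idx[s] + 0.5) * h, tz, tml)
    tr <- structure(list(A = A, b = b, fit_rms_um = 0,
                         n_points = n_control_points),
                    class = "planar_affine")
    transforms[[section_ids[s]]] <- tr
    ## control points on a pixel grid covering the section
    uv <- cbind(stats::runif(n_control_points, -2000, 2000),
                stats::runif(n_control_points, -2000, 2000))
    q <- apply_affine(tr, uv)
    uv_noisy <- uv + matrix(stats::rnorm(length(uv), 0, pixel_noise_sd),
                            ncol = 2)
    cp_rows[[s]] <- data.frame(
      section_id = section_ids[s], u_px = uv_noisy[, 1], v_px = uv_noisy[, 2],
      x_um = q[, "x_um"], z_um = q[, "z_um"], ml_um = q[, "ml_um"],
      stringsAsFactors = FALSE)
  }
  control_points <- do.call(rbind, cp_rows)

  cell_rows <- list()
  truth_rows <- list()
  for (g in names(groups)) {
    counts <- apportion_counts(cells_per_group[[g]], groups[[g]])
    for (bin in 0:4) {
      nb <- counts[bin + 1L]
      if (nb == 0L) next
      sec <- sample(seq_len(n_sections), nb, replace = TRUE)
      hemi <- sample(c("left", "right"), nb, replace = TRUE)
      ## mediolateral distance from midline: strictly inside the bin
      dist <- (bin + stats::runif(nb, 0.05, 0.95)) * bin_w
      ml <- ifelse(hemi == "right", midline + dist, midline - dist)
      ## right-hemisphere tie rule: keep left-hemisphere cells off midline
      z <- stats::runif(nb, (ctx_z[1] + 0.1) * h, (ctx_z[2] + 0.9) * h)
      for (i in seq_len(nb)) {
        tr <- transforms[[section_ids[sec[i]]]]
        zml <- c(z[i], ml[i]) - tr$b[2:3]
        uv <- solve(tr$A[2:3, ], zml)
        uv <- uv + stats::rnorm(2, 0, pixel_noise_sd)
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          section_id = section_ids[sec[i]],
          animal_id = paste0("anim_", g), group = g, channel = "ch1",
          u_px = uv[1], v_px = uv[2], stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          group = g, true_bin = bin, true_class = ml_class(bin),
          true_hemisphere = hemi[i], true_ml_um = ml[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- if (length(cell_rows)) do.call(rbind, cell_rows) else
    data.frame(section_id = character(0), animal_id = character(0),
               group = character(0), channel = character(0),
               u_px = numeric(0), v_px = numeric(0))
  truth_cells <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL

  class_counts <- lapply(names(groups), function(g) {
    counts <- apportion_counts(cells_per_group[[g]], groups[[g]])
    list(group = g,
         bins = as.list(stats::setNames(counts, paste0("bin", 0:4))),
         cingulate = counts[1], medial = counts[2] + counts[3],
         lateral = counts[4] + counts[5])
  })
  truth <- list(seed = seed, n_sections = n_sections,
                pixel_noise_sd = pixel_noise_sd,
                section_x_index = as.integer(sec_x_idx),
                planted_proportions = groups,
                class_counts = class_counts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(control_points, file.path(out_dir, "control_points.csv"))
    write_table_csv(cells, file.path(out_dir, "cells.csv"))
    write_json_file(truth, file.path(out_dir, "cells_truth.json"))
  }
  list(control_points = control_points, cells = cells,
       transforms = transforms, truth = truth, truth_cells = truth_cells)
}

#' Simulate an ellipsoidal injection volume
#'
#' Samples outline points on an ellipsoid surface and records analytic
#' ground truth: the closed-form volume and, when an atlas is given,
#' brute-force per-structure overlaps obtained by testing every atlas voxel
#' center against the ellipsoid inequality.
#'
#' @param center Ellipsoid center (x, z, ml) in micrometers.
#' @param radii Positive semi-axis lengths in micrometers.
#' @param n_boundary_points Number of surface points (default 500).
#' @param seed Integer seed.
#' @param atl Optional `atlas` for overlap ground truth.
#' @param animal_id,label Identifiers for the outline table.
#' @param out_dir Optional directory; writes `outlines.csv` and
#'   `injection_truth.json`.
#' @return List with `outlines` (data frame), `truth` (analytic volume in
#'   cubic millimeters, per-region oracle overlaps).
#' @export
simulate_injection <- function(center, radii, n_boundary_points = 500L,
                               seed = 1L, atl = NULL,
                               animal_id = "anim_01", label = "injection",
                               out_dir = NULL) {
  stopifnot(all(radii > 0), n_boundary_points >= 4L)
  rng_state <- set_local_seed(seed + 2000L)
  on.exit(restore_seed(rng_state), add = TRUE)
  u <- matrix(stats::rnorm(3 * n_boundary_points), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u %*% diag(radii), 2, center, `+`)
  outlines <- data.frame(animal_id = animal_id, label = label,
                         x_um = pts[, 1], z_um = pts[, 2], ml_um = pts[, 3],
                         stringsAsFactors = FALSE)
  truth <- list(center = center, radii = radii, seed = seed,
                analytic_volume_mm3 = 4 / 3 * pi * prod(radii) / 1e9)
  if (!is.null(atl)) {
    truth$region_overlaps <- ellipsoid_region_overlaps(atl, center, radii)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(outlines, file.path(out_dir, "outlines.csv"))
    write_json_file(truth, file.path(out_dir, "injection_truth.json"))
  }
  list(outlines = outlines, truth = truth)
}

## brute-force oracle: label every atlas voxel center against the analytic
## ellipsoid inequality and intersect with each region's voxel set
ellipsoid_region_overlaps <- function(atl, center, radii) {
  d <- dim(atl$labels)
  h <- atl$voxel_size_um
  ci <- (seq_len(d[1]) - 0.5) * h
  cj <- (seq_len(d[2]) - 0.5) * h
  ck <- (seq_len(d[3]) - 0.5) * h
  t1 <- ((ci - center[1]) / radii[1])^2
  t2 <- ((cj - center[2]) / radii[2])^2
  t3 <- ((ck - center[3]) / radii[3])^2
  inside <- outer(outer(t1, t2, `+`), t3, `+`) <= 1
  leaf_ids <- setdiff(sort(unique(as.vector(atl$labels))), 0L)
  rows <- lapply(leaf_ids, function(rid) {
    in_region <- atl$labels == rid
    data.frame(region_id = rid,
               acronym = atl$regions$acronym[atl$regions$region_id == rid],
               overlap_voxels = sum(inside & in_region),
               target_voxels = sum(in_region),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percent <- 100 * out$overlap_voxels / out$target_voxels
  out
}

#' Simulate axon signal images with planted region density fractions
#'
#' For each animal, sections are rostro-caudal slices of the toy atlas
#' chosen to cover every nucleus; each (section, region) pair yields a
#' binary mask cut from the atlas slice and a signal image whose masked
#' pixels carry Poisson counts with total expectation proportional to the
#' group's planted fraction for that region (photon-count noise). With
#' `noise = "none"` the expected counts are rounded to integers and written
#' as-is, making downstream recovery exact; the realized totals are
#' recorded in the truth manifest.
#'
#' @param atl Toy atlas.
#' @param manifest Matching atlas manifest.
#' @param group_fractions Named list: per group, named numeric vector of
#'   planted density fractions over the nucleus acronyms (sums to 1).
#' @param animals_per_group Animals per group (default 3).
#' @param n_sections Sections per animal (default 6).
#' @param expected_total Expected total signal count per animal across all
#'   regions (default 6e5, i.e. about 1e5 per region for balanced
#'   fractions).
#' @param noise "poisson" (default) or "none".
#' @param seed Integer seed.
#' @param out_dir Directory for TIFFs and `axon_manifest.csv` (required).
#' @return List with `manifest` (data frame linking TIFFs to
#'   animal/section/region) and `truth` (planted and realized fractions).
#' @export
simulate_axon_images <- function(atl, manifest, group_fractions = list(
                                   lateral = c(MRN = 0.30, PRNr = 0.10,
                                               PRNc = 0.25, SPV = 0.10,
                                               MDRNd = 0.05, GRN = 0.20),
                                   medial = c(MRN = 0.10, PRNr = 0.25,
                                              PRNc = 0.10, SPV = 0.25,
                                              MDRNd = 0.20, GRN = 0.10)),
                                 animals_per_group = 3L, n_sections = 6L,
                                 expected_total = 6e5, noise = "poisson",
                                 seed = 1L, out_dir) {
  stopifnot(inherits(atl, "atlas"), noise %in% c("poisson", "none"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rng_state <- set_local_seed(seed + 3000L)
  on.exit(restore_seed(rng_state), add = TRUE)
  nuclei <- manifest$nuclei
  acronyms <- names(nuclei)
  d <- dim(atl$labels)

  ## sections through nucleus centers so every region is covered
  centers_x <- vapply(nuclei, function(n) n$corner[1] + n$size %/% 2L,
                      integer(1))
  sec_x <- centers_x[seq_len(min(n_sections, length(centers_x)))]
  while (length(sec_x) < n_sections) {
    extra <- centers_x[(length(sec_x) %% length(centers_x)) + 1L] + 2L
    sec_x <- c(sec_x, min(extra, d[1] - 1L))
  }
  sec_x <- as.integer(sec_x)

  ## per-region active pixel totals across sections (masks from the atlas)
  masks <- list()
  for (s in seq_along(sec_x)) {
    slc <- atl$labels[sec_x[s] + 1L, , , drop = TRUE]
    for (a in acronyms) {
      rid <- nuclei[[a]]$region_id
      masks[[paste(s, a)]] <- (slc == rid) * 1
    }
  }
  active_px <- vapply(acronyms, function(a) {
    sum(vapply(seq_along(sec_x), function(s) sum(masks[[paste(s, a)]]),
               numeric(1)))
  }, numeric(1))
  uncovered <- acronyms[active_px == 0]
  if (length(uncovered)) {
    stopf("section placement leaves region(s) with no mask pixels: %s",
          paste(uncovered, collapse = ", "))
  }

  manifest_rows <- list()
  truth_animals <- list()
  for (g in names(group_fractions)) {
    fr <- group_fractions[[g]]
    if (abs(sum(fr) - 1) > 1e-8) {
      stopf("planted fractions for group '%s' must sum to 1", g)
    }
    fr <- fr[acronyms]
    for (an in seq_len(animals_per_group)) {
      animal_id <- sprintf("%s_%02d", g, an)
      realized <- stats::setNames(numeric(length(acronyms)), acronyms)
      for (s in seq_along(sec_x)) {
        section_id <- sprintf("%s_sec%02d", animal_id, s)
        sig_name <- sprintf("%s_signal.tif", section_id)
        sig <- NULL
        for (a in acronyms) {
          mask <- masks[[paste(s, a)]]
          if (is.null(sig)) sig <- mask * 0
          npx <- sum(mask)
          if (npx > 0) {
            lam <- fr[[a]] * expected_total / active_px[[a]]
            vals <- if (noise == "poisson") stats::rpois(npx, lam)
                    else round(rep(lam, npx))
            sig[mask == 1] <- sig[mask == 1] + vals
            realized[[a]] <- realized[[a]] + sum(vals)
          }
          mask_name <- sprintf("%s_%s_mask.tif", section_id, a)
          write_image_tiff(mask, file.path(out_dir, mask_name))
          manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
            animal_id = animal_id, group = g, section_id = section_id,
            region_id = nuclei[[a]]$region_id, region_acronym = a,
            mask_path = mask_name, signal_path = sig_name,
            stringsAsFactors = FALSE)
        }
        write_image_tiff(sig, file.path(out_dir, sig_name))
      }
      truth_animals[[animal_id]] <- list(
        group = g, realized_counts = as.list(realized),
        realized_fractions = as.list(realized / sum(realized)))
    }
  }
  man <- do.call(rbind, manifest_rows)
  truth <- list(seed = seed, noise = noise, expected_total = expected_total,
                n_sections = length(sec_x),
                section_x_index = sec_x,
                planted_fractions = lapply(group_fractions, as.list),
                animals = truth_animals)
  write_table_csv(man, file.path(out_dir, "axon_manifest.csv"))
  write_json_file(truth, file.path(out_dir, "axon_truth.json"))
  list(manifest = man, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs all generators with one seed and writes a runnable dataset: toy
#' atlas (NRRD + JSON), control points, cells, injection outlines, axon
#' mask/signal TIFFs and ground-truth manifests.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param pixel_noise_sd Pixel jitter for cell annotations (default 0).
#' @param noise Axon-image noise model ("poisson" or "none").
#' @return Invisibly, a list with all generator outputs.
#' @export
simulate_all <- function(seed = 1L, out_dir, pixel_noise_sd = 0,
                         noise = "poisson") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  toy <- make_toy_atlas(seed = seed, out_dir = out_dir)
  cohort <- simulate_sections_and_cells(toy$atlas, toy$manifest,
                                        pixel_noise_sd = pixel_noise_sd,
                                        seed = seed, out_dir = out_dir)
  ## injection centered in the first nucleus block
  nuc <- toy$manifest$nuclei[[1]]
  h <- toy$atlas$voxel_size_um
  center <- (nuc$corner + nuc$size / 2) * h
  inj <- simulate_injection(center = center, radii = c(800, 600, 500),
                            seed = seed, atl = toy$atlas, out_dir = out_dir)
  axons <- simulate_axon_images(toy$atlas, toy$manifest, seed = seed,
                                noise = noise,
                                out_dir = file.path(out_dir, "axon_images"))
  invisible(list(toy = toy, cohort = cohort, injection = inj, axons = axons))
}
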