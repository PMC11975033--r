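test_that("hemisphere assignment follows the sign rule with right-side ties", {
  expect_equal(assign_hemisphere(3999, 4000), "left")
  expect_equal(assign_hemisphere(4000, 4000), "right")
  expect_equal(assign_hemisphere(4001, 4000), "right")
  set.seed(21)
  ml <- runif(1000, 0, 8000)
  hemi <- assign_hemisphere(ml, 4000)
  off <- ml != 4000
  expect_identical(hemi[off], ifelse(ml[off] > 4000, "right", "left"))
})

test_that("cortical extent runs from the midline to the lateral cortex edge", {
  toy <- toy_fixture()
  atl <- toy$atlas
  k <- toy$manifest$cortex$x_index_range[1] + 2L
  ext_r <- cortical_extent(atl, k, "right", 10L)
  expect_equal(ext_r$ml_min_um, atl$midline_ml_um)
  # far edge of the lateral-most cortex voxel, from the generator manifest
  expect_equal(ext_r$ml_max_um, toy$manifest$cortex$right$ml_um_range[2])

  # symmetric atlas: left and right widths mirror exactly
  ext_l <- cortical_extent(atl, k, "left", 10L)
  expect_equal(ext_l$ml_max_um - ext_l$ml_min_um,
               ext_r$ml_max_um - ext_r$ml_min_um)
  # brute-force scan oracle for the left width
  slc <- atl$labels[k + 1, , ]
  in_ctx <- matrix(slc %in% c(10L, 11L, 12L), nrow = nrow(slc))
  ml_cols <- which(apply(in_ctx, 2, any)) - 1L
  left_cols <- ml_cols[(ml_cols + 0.5) * 100 < atl$midline_ml_um]
  expect_equal(ext_l$ml_max_um - ext_l$ml_min_um,
               atl$midline_ml_um - min(left_cols) * 100)

  # slice with no cortex
  expect_error(cortical_extent(atl, 0L, "right", 10L),
               class = "atlastrace_empty_extent_error")
})

test_that("ml_bin implements half-open equal-width bins with edge clamping", {
  ext <- list(ml_min_um = 4000, ml_max_um = 7000)
  w <- 3000
  expect_equal(ml_bin(4000 + 0.50 * w, ext), 2L)  # midpoint -> medial
  expect_equal(ml_class(2L), "medial")
  expect_equal(ml_bin(4000 + 0.20 * w, ext), 1L)  # half-open boundary
  expect_equal(ml_bin(4000 + 1.00 * w, ext), 4L)  # lateral edge clamped
  expect_true(is.na(ml_bin(4000 + 1.01 * w, ext)))
  # left-hemisphere distances bin identically
  expect_equal(ml_bin(4000 - 0.50 * w, ext), 2L)

  # uniform positions land in each bin ~ n/5 (3-sigma binomial band)
  set.seed(22)
  n <- 1e4
  bins <- ml_bin(runif(n, 4000, 7000), ext)
  counts <- tabulate(bins + 1L, 5)
  expect_equal(sum(counts), n)
  sd3 <- 3 * sqrt(n * 0.2 * 0.8)
  expect_true(all(abs(counts - n / 5) < sd3))

  # class mapping is fixed: 0 -> cingulate, 1-2 -> medial, 3-4 -> lateral
  expect_equal(ml_class(0:4),
               c("cingulate", "medial", "medial", "lateral", "lateral"))
})

test_that("map_cells recovers planted bins exactly in the noiseless case", {
  toy <- toy_fixture()
  coh <- simulate_sections_and_cells(toy$atlas, toy$manifest, seed = 5L)
  tr <- fit_section_transforms(coh$control_points)
  rec <- map_cells(tr, coh$cells, toy$atlas, 10L)
  expect_equal(nrow(rec), nrow(coh$cells))
  expect_identical(rec$ml_bin, coh$truth_cells$true_bin)
  expect_identical(rec$ml_class, coh$truth_cells$true_class)
  expect_identical(rec$hemisphere, coh$truth_cells$true_hemisphere)
  expect_true(all(rec$in_extent))

  # planted class counts recovered exactly
  tab <- count_by_class(rec)
  for (tc in coh$truth$class_counts) {
    for (cl in c("cingulate", "medial", "lateral")) {
      expect_equal(tab$n[tab$group == tc$group & tab$ml_class == cl], tc[[cl]])
    }
  }
  # bin counts partition the in-extent total per hemisphere
  for (hm in c("left", "right")) {
    sub <- rec[rec$hemisphere == hm & rec$in_extent, ]
    expect_equal(sum(tabulate(sub$ml_bin + 1L, 5)), nrow(sub))
  }
  # all planted cells sit inside painted cortex
  expect_true(all(rec$region_id %in% c(11L, 12L)))
})

test_that("map_cells is invariant to rigid in-plane pixel re-parameterization", {
  toy <- toy_fixture()
  coh <- simulate_sections_and_cells(toy$atlas, toy$manifest,
                                     cells_per_group = 100L, seed = 6L)
  tr <- fit_section_transforms(coh$control_points)
  rec1 <- map_cells(tr, coh$cells, toy$atlas, 10L)

  # rotate + translate every pixel frame, refit, remap
  phi <- 0.7; Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  shift <- c(123, -456)
  cp2 <- coh$control_points
  uv2 <- as.matrix(cp2[, c("u_px", "v_px")]) %*% t(Rm) +
    matrix(shift, nrow(cp2), 2, byrow = TRUE)
  cp2$u_px <- uv2[, 1]; cp2$v_px <- uv2[, 2]
  cells2 <- coh$cells
  cuv2 <- as.matrix(cells2[, c("u_px", "v_px")]) %*% t(Rm) +
    matrix(shift, nrow(cells2), 2, byrow = TRUE)
  cells2$u_px <- cuv2[, 1]; cells2$v_px <- cuv2[, 2]
  rec2 <- map_cells(fit_section_transforms(cp2), cells2, toy$atlas, 10L)
  expect_identical(rec2$ml_bin, rec1$ml_bin)
  expect_identical(rec2$hemisphere, rec1$hemisphere)
  expect_equal(rec2$ml_um, rec1$ml_um, tolerance = 1e-6)
})

test_that("map_cells edge cases: empty input, missing transform, outside grid", {
  toy <- toy_fixture()
  coh <- simulate_sections_and_cells(toy$atlas, toy$manifest,
                                     cells_per_group = 5L, seed = 7L)
  tr <- fit_section_transforms(coh$control_points)

  empty <- coh$cells[0, ]
  expect_equal(nrow(map_cells(tr, empty, toy$atlas, 10L)), 0L)

  orphan <- coh$cells
  orphan$section_id[1] <- "sec99"
  expect_error(map_cells(tr, orphan, toy$atlas, 10L), "sec99")

  # a cell mapping above the atlas grid (z < 0): region NA, still binned
  tr_id <- fit_affine(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                      cbind(c(250, 250, 250, 250), c(0, 1, 0, 1), c(0, 0, 1, 1)))
  trs <- list(secX = tr_id)
  cells <- data.frame(section_id = "secX", animal_id = "a", group = "g",
                      channel = "c", u_px = -500, v_px = 4500)
  ext <- data.frame(section_id = "secX", hemisphere = "right",
                    ml_min_um = 4000, ml_max_um = 7000)
  rec <- map_cells(trs, cells, toy$atlas, 10L, extents = ext)
  expect_true(is.na(rec$region_id))
  expect_equal(rec$ml_bin, 0L)
  expect_true(rec$in_extent)
})

test_that("manual extents support atlas-free sections", {
  # same 5-bin rule applied to a user-supplied hemisphere width
  tr_id <- fit_affine(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                      cbind(0, c(0, 1, 0, 1), c(0, 0, 1, 1)))
  trs <- list(p4 = tr_id)
  cells <- data.frame(section_id = "p4", animal_id = "a", group = "g",
                      channel = "c", u_px = c(100, 100),
                      v_px = c(2500, 900))
  ext <- data.frame(section_id = "p4", hemisphere = c("right", "left"),
                    ml_min_um = 2000, ml_max_um = 4500)
  rec <- map_cells(trs, cells, atl = NULL, extents = ext,
                   midline_ml_um = 2000)
  expect_equal(rec$ml_bin, c(1L, 2L))
  expect_equal(rec$hemisphere, c("right", "left"))
  expect_true(all(is.na(rec$region_id)))
})

test_that("axis summaries report mean and SEM with n-1 denominator", {
  rec <- data.frame(group = rep("g", 3), x_um = c(1, 2, 3), z_um = c(5, 5, 5))
  s <- summarize_distribution(rec)
  expect_equal(s$mean_x_um, 2)
  expect_equal(s$sem_x_um, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(s$sem_x_um, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$sem_z_um, 0)

  expect_warning(
    s1 <- summarize_distribution(data.frame(group = "g", x_um = 1, z_um = 2)),
    "single cell")
  expect_true(is.na(s1$sem_x_um))

  # mean of a known normal lands within 3 SEM of truth
  set.seed(23)
  rec2 <- data.frame(group = "n", x_um = rnorm(500, 3000, 200),
                     z_um = rnorm(500, 600, 50))
  s2 <- summarize_distribution(rec2)
  expect_lt(abs(s2$mean_x_um - 3000), 3 * s2$sem_x_um)
  expect_lt(abs(s2$mean_z_um - 600), 3 * s2$sem_z_um)
})
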