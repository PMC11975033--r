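test_that("toy atlas round-trips through NRRD and NIfTI identically", {
  toy <- toy_fixture()
  td <- withr::local_tempdir()
  vol <- file.path(td, "atlas.nrrd")
  reg <- file.path(td, "regions.json")
  save_atlas(toy$atlas, vol, reg)
  back <- load_atlas(vol, reg)
  expect_identical(back$labels, toy$atlas$labels)
  expect_equal(back$voxel_size_um, toy$atlas$voxel_size_um)
  expect_equal(back$midline_ml_um, toy$atlas$midline_ml_um)
  expect_equal(back$regions, toy$atlas$regions)

  # second save from the reloaded object is byte-identical (load-save-load)
  vol2 <- file.path(td, "atlas2.nrrd")
  reg2 <- file.path(td, "regions2.json")
  save_atlas(back, vol2, reg2)
  expect_identical(readBin(vol, "raw", file.size(vol)),
                   readBin(vol2, "raw", file.size(vol2)))
  expect_identical(readLines(reg), readLines(reg2))

  nii <- file.path(td, "atlas.nii")
  csvp <- file.path(td, "regions.csv")
  save_atlas(toy$atlas, nii, csvp)
  back2 <- load_atlas(nii, csvp)
  expect_identical(back2$labels, toy$atlas$labels)
  expect_equal(back2$voxel_size_um, toy$atlas$voxel_size_um)
})

test_that("atlas validation rejects unknown labels and broken hierarchies", {
  toy <- toy_fixture()
  bad <- toy$atlas$labels
  bad[1, 1, 1] <- 999L
  expect_error(atlas(bad, toy$atlas$regions, 100),
               "999", class = "atlastrace_validation_error")

  regs <- toy$atlas$regions
  regs$parent_id[regs$region_id == 20] <- 555L
  expect_error(atlas(toy$atlas$labels, regs, 100),
               class = "atlastrace_validation_error")

  # cycle: two nodes parenting each other (plus a root)
  cyc <- data.frame(region_id = c(1L, 2L, 3L), acronym = c("r", "a", "b"),
                    name = c("r", "a", "b"), parent_id = c(NA, 3L, 2L),
                    category = "other")
  expect_error(atlas(array(0L, c(2, 2, 2)), cyc, 100),
               "cycle|root", class = "atlastrace_validation_error")
})

test_that("region_voxels honors the hierarchy and matches a brute-force scan", {
  toy <- toy_fixture()
  atl <- toy$atlas
  expect_error(region_voxels(atl, 0), class = "atlastrace_lookup_error")
  expect_error(region_voxels(atl, 4242), class = "atlastrace_lookup_error")

  # each nucleus is an 8x8x8 block
  for (nm in names(toy$manifest$nuclei)) {
    nuc <- toy$manifest$nuclei[[nm]]
    expect_equal(nrow(region_voxels(atl, nuc$region_id)), 512L)
  }

  # parent voxels = union of children (cortex has two disjoint children)
  vox_parent <- region_voxels(atl, 10L, include_descendants = TRUE)
  vox_l <- region_voxels(atl, 11L)
  vox_r <- region_voxels(atl, 12L)
  expect_equal(nrow(vox_parent), nrow(vox_l) + nrow(vox_r))
  expect_true(all(paste(vox_l[, 1], vox_l[, 2], vox_l[, 3]) %in%
                  paste(vox_parent[, 1], vox_parent[, 2], vox_parent[, 3])))
  # direct label-grid scan oracle
  expect_equal(nrow(vox_parent), sum(atl$labels %in% c(10L, 11L, 12L)))

  # leaf voxel counts + background = grid size
  leaves <- setdiff(sort(unique(as.vector(atl$labels))), 0L)
  n_leaf <- sum(vapply(leaves, function(id)
    nrow(region_voxels(atl, id, include_descendants = FALSE)), numeric(1)))
  expect_equal(n_leaf + sum(atl$labels == 0L), length(atl$labels))
})

test_that("point_to_voxel follows the half-open 0-based convention", {
  toy <- toy_fixture()
  atl <- toy$atlas
  expect_equal(unname(point_to_voxel(atl, c(0, 0, 0))[1, ]), c(0L, 0L, 0L))
  # a boundary coordinate of exactly (i+1)*h belongs to voxel i+1
  expect_equal(unname(point_to_voxel(atl, c(100, 0, 0))[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(point_to_voxel(atl, c(99.999, 0, 0))[1, ]), c(0L, 0L, 0L))
  expect_true(all(is.na(point_to_voxel(atl, c(-1, 0, 0)))))
  expect_true(all(is.na(point_to_voxel(atl, c(0, 0, 8000)))))

  # random in-bounds points match a per-point nearest-lower-gridline oracle
  set.seed(7)
  n <- 1000
  d <- dim(atl$labels)
  pts <- cbind(runif(n, 0, d[1] * 100), runif(n, 0, d[2] * 100),
               runif(n, 0, d[3] * 100))
  idx <- point_to_voxel(atl, pts)
  for (r in sample(n, 50)) {
    oracle <- vapply(1:3, function(a) {
      g <- seq(0, d[a] * 100, by = 100)
      max(which(g <= pts[r, a])) - 1L
    }, integer(1))
    oracle <- pmin(oracle, d - 1L)
    expect_equal(unname(idx[r, ]), oracle)
  }
  # label lookups agree with direct array indexing
  lab <- label_at(atl, pts)
  for (r in sample(n, 50)) {
    expect_equal(lab[r], atl$labels[idx[r, 1] + 1, idx[r, 2] + 1, idx[r, 3] + 1])
  }
})
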