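test_that("toy atlas generation is deterministic and matches its manifest", {
  toy1 <- make_toy_atlas(seed = 4L)
  toy2 <- make_toy_atlas(seed = 4L)
  expect_identical(toy1$atlas$labels, toy2$atlas$labels)
  expect_identical(toy1$manifest, toy2$manifest)
  # a different seed moves the nuclei
  toy3 <- make_toy_atlas(seed = 5L)
  expect_false(identical(toy1$atlas$labels, toy3$atlas$labels))

  # manifest ground truth: every declared nucleus block is painted verbatim
  for (nm in names(toy1$manifest$nuclei)) {
    nuc <- toy1$manifest$nuclei[[nm]]
    blk <- toy1$atlas$labels[
      (nuc$corner[1]:(nuc$corner[1] + nuc$size - 1)) + 1,
      (nuc$corner[2]:(nuc$corner[2] + nuc$size - 1)) + 1,
      (nuc$corner[3]:(nuc$corner[3] + nuc$size - 1)) + 1]
    expect_true(all(blk == nuc$region_id))
    expect_equal(sum(toy1$atlas$labels == nuc$region_id), nuc$size^3)
  }
  # region table: 8 leaves under the declared parents
  regs <- toy1$atlas$regions
  leaves <- regs[!regs$region_id %in% regs$parent_id, ]
  expect_equal(nrow(leaves), 8L)
  expect_setequal(leaves$parent_id, c(10L, 20L))

  # same-seed file outputs are byte-identical
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  make_toy_atlas(seed = 4L, out_dir = td1)
  make_toy_atlas(seed = 4L, out_dir = td2)
  for (f in list.files(td1)) {
    expect_identical(readBin(file.path(td1, f), "raw", 1e7),
                     readBin(file.path(td2, f), "raw", 1e7))
  }
})

test_that("physical region volumes agree across voxel resolutions", {
  toy100 <- make_toy_atlas(seed = 4L, voxel_size_um = 100)
  toy50 <- make_toy_atlas(seed = 4L, shape = c(120L, 80L, 160L),
                          voxel_size_um = 50)
  # cortical shell: equal physical extent within one voxel shell
  w100 <- toy100$manifest$cortex$hemisphere_width_um
  w50 <- toy50$manifest$cortex$hemisphere_width_um
  expect_lt(abs(w100 - w50), 100)
})

test_that("planted cohorts give exact class counts and proportions", {
  toy <- toy_fixture()
  coh <- simulate_sections_and_cells(
    toy$atlas, toy$manifest,
    groups = list(g = c(0.10, 0.10, 0.10, 0.35, 0.35)),
    cells_per_group = 1000L, seed = 8L)
  # construction places exact counts: 70/20/10 lateral/medial/cingulate
  tc <- coh$truth$class_counts[[1]]
  expect_equal(tc$cingulate, 100L)
  expect_equal(tc$medial, 200L)
  expect_equal(tc$lateral, 700L)
  expect_equal(nrow(coh$cells), 1000L)

  # empty group yields empty outputs, no error
  coh0 <- simulate_sections_and_cells(
    toy$atlas, toy$manifest, groups = list(g = c(1, 0, 0, 0, 0)),
    cells_per_group = 0L, seed = 8L)
  expect_equal(nrow(coh0$cells), 0L)

  # determinism per seed
  cohA <- simulate_sections_and_cells(toy$atlas, toy$manifest, seed = 8L)
  cohB <- simulate_sections_and_cells(toy$atlas, toy$manifest, seed = 8L)
  expect_identical(cohA$cells, cohB$cells)
  expect_identical(cohA$control_points, cohB$control_points)
})

test_that("injection truth carries closed-form volumes and a re-runnable oracle", {
  toy <- toy_fixture()
  inj_sphere <- simulate_injection(center = c(3000, 2000, 4000),
                                   radii = c(500, 500, 500),
                                   n_boundary_points = 500L, seed = 2L)
  expect_equal(inj_sphere$truth$analytic_volume_mm3, 4 / 3 * pi * 0.5^3,
               tolerance = 1e-12)
  inj <- simulate_injection(center = c(3000, 2000, 4000),
                            radii = c(800, 600, 500), seed = 2L,
                            atl = toy$atlas)
  expect_equal(inj$truth$analytic_volume_mm3, 1.0053, tolerance = 1e-4)
  # the voxel-scan oracle is reproducible
  ov1 <- inj$truth$region_overlaps
  ov2 <- atlastrace:::ellipsoid_region_overlaps(toy$atlas, c(3000, 2000, 4000),
                                                c(800, 600, 500))
  expect_equal(ov1, ov2)
  expect_equal(nrow(inj$outlines), 500L)
})

test_that("degenerate axon-density profiles produce one-hot fractions", {
  toy <- toy_fixture()
  td <- withr::local_tempdir()
  onehot <- c(MRN = 1, PRNr = 0, PRNc = 0, SPV = 0, MDRNd = 0, GRN = 0)
  ax <- simulate_axon_images(toy$atlas, toy$manifest,
                             group_fractions = list(g = onehot),
                             animals_per_group = 1L, noise = "none",
                             seed = 3L, out_dir = td)
  agg <- aggregate_and_normalize(quantify_sections(ax$manifest, td))
  acr <- toy$atlas$regions$acronym[match(agg$region_id,
                                         toy$atlas$regions$region_id)]
  expect_equal(agg$norm_fraction, unname(onehot[acr]))
})
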