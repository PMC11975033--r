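test_that("masked sums and areas match per-pixel loop oracles exactly", {
  # constant image under a full mask
  expect_equal(region_signal(matrix(1, 4, 4), matrix(3, 4, 4)), 48)
  expect_equal(region_signal(matrix(0, 4, 4), matrix(3, 4, 4)), 0)
  expect_equal(region_area(matrix(1, 10, 10)), 100)
  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(region_area(checker), 32)

  # 50 random integer fixtures against explicit double loops
  set.seed(41)
  for (rep in 1:50) {
    mask <- matrix(rbinom(64 * 64, 1, 0.4), 64, 64)
    img <- matrix(sample(0:5000, 64 * 64, replace = TRUE), 64, 64)
    loop_sum <- 0L
    loop_area <- 0L
    for (i in 1:64) for (j in 1:64) {
      loop_sum <- loop_sum + mask[i, j] * img[i, j]
      loop_area <- loop_area + (mask[i, j] == 1)
    }
    expect_identical(region_signal(mask, img), loop_sum)
    expect_identical(region_area(mask), loop_area)
  }
})

test_that("shape and mask validation errors are raised", {
  expect_error(region_signal(matrix(1, 4, 4), matrix(1, 4, 5)),
               class = "atlastrace_dimension_error")
  expect_error(region_signal(matrix(2, 4, 4), matrix(1, 4, 4)),
               class = "atlastrace_validation_error")
  expect_error(region_area(matrix(0.5, 2, 2)),
               class = "atlastrace_validation_error")
  expect_error(region_signal(matrix(1, 2, 2), matrix(-1, 2, 2)),
               class = "atlastrace_validation_error")
})

test_that("aggregation sums sections first, then normalizes within animals", {
  df <- data.frame(
    animal_id = c("a", "a", "a", "a", "b", "b"),
    region_id = c(1L, 1L, 2L, 2L, 1L, 2L),
    raw_sum = c(10, 20, 30, 40, 50, 0),
    area_px = c(5, 5, 10, 10, 8, 2))
  agg <- aggregate_and_normalize(df)
  a <- agg[agg$animal_id == "a", ]
  expect_equal(a$raw_sum, c(30, 70))           # summed across sections
  expect_equal(a$norm_fraction, c(0.30, 0.70)) # then normalized
  expect_equal(a$area_px, c(10, 20))
  b <- agg[agg$animal_id == "b", ]
  expect_equal(b$norm_fraction, c(1, 0))       # single active region -> 1

  # per-animal fractions sum to 1 within 1e-9
  sums <- tapply(agg$norm_fraction, agg$animal_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # zero-total animal is a named error
  zero <- data.frame(animal_id = "z", region_id = 1L, raw_sum = 0, area_px = 3)
  expect_error(aggregate_and_normalize(zero), "z",
               class = "atlastrace_normalization_error")
})

test_that("fractions are scale invariant and permutation equivariant", {
  set.seed(42)
  df <- data.frame(animal_id = "a", region_id = 1:6,
                   raw_sum = runif(6, 10, 100), area_px = 50L)
  f1 <- aggregate_and_normalize(df)$norm_fraction
  df2 <- df; df2$raw_sum <- df2$raw_sum * 37.5
  expect_equal(aggregate_and_normalize(df2)$norm_fraction, f1,
               tolerance = 1e-12)
  # relabeling regions permutes rows, nothing else
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  df3 <- df; df3$region_id <- perm
  f3 <- aggregate_and_normalize(df3)
  expect_equal(f3$norm_fraction[match(perm, f3$region_id)], f1,
               tolerance = 1e-12)
})

test_that("TIFF-backed quantification recovers planted densities", {
  toy <- toy_fixture()
  td <- withr::local_tempdir()

  # no-noise identity: recovered fractions equal the recorded truth exactly
  ax0 <- simulate_axon_images(toy$atlas, toy$manifest, animals_per_group = 1L,
                              noise = "none", seed = 9L, out_dir = td)
  agg0 <- aggregate_and_normalize(quantify_sections(ax0$manifest, td))
  for (an in unique(agg0$animal_id)) {
    truth <- ax0$truth$animals[[an]]$realized_fractions
    sub <- agg0[agg0$animal_id == an, ]
    acr <- toy$atlas$regions$acronym[match(sub$region_id,
                                           toy$atlas$regions$region_id)]
    expect_equal(sub$norm_fraction, unlist(truth[acr], use.names = FALSE),
                 tolerance = 1e-12)
  }

  # Poisson noise at ~1e5 expected counts per region: within 0.02 absolute
  td2 <- withr::local_tempdir()
  ax <- simulate_axon_images(toy$atlas, toy$manifest, animals_per_group = 2L,
                             expected_total = 6e5, seed = 10L, out_dir = td2)
  agg <- aggregate_and_normalize(quantify_sections(ax$manifest, td2))
  agg$group <- ax$manifest$group[match(agg$animal_id, ax$manifest$animal_id)]
  for (r in seq_len(nrow(agg))) {
    acr <- toy$atlas$regions$acronym[toy$atlas$regions$region_id ==
                                       agg$region_id[r]]
    planted <- ax$truth$planted_fractions[[agg$group[r]]][[acr]]
    expect_lt(abs(agg$norm_fraction[r] - planted), 0.02)
  }
})
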