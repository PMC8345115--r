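# Synthetic-data generators: planted truth, determinism, regime presets.

test_that("simulated localisation tables have the exact count, all inside the contour", {
  circ <- make_circle_roi()
  sim <- simulate_localisations(smlm_spec(circ, 1000L, 20L,
                                          background_fraction = 0.5, seed = 3L))
  expect_equal(nrow(sim$table), 1000L)
  expect_equal(nrow(filter_by_roi(sim$table, circ)), 1000L)
  expect_equal(sim$truth$n_background, 500)
  expect_equal(sum(sim$truth$cluster_id == 0L), 500L)
  expect_equal(nrow(sim$truth$cluster_centres), 20L)
})

test_that("identical specs and seeds reproduce localisations bit-identically", {
  spec <- smlm_spec(make_blob_roi(2), 2000L, 50L, background_fraction = 0.3,
                    radial_gradient_gamma = 2, seed = 17L)
  a <- simulate_localisations(spec)
  b <- simulate_localisations(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$cluster_centres, b$truth$cluster_centres)
  c2 <- simulate_localisations(smlm_spec(make_blob_roi(2), 2000L, 50L,
                                         background_fraction = 0.3,
                                         radial_gradient_gamma = 2, seed = 18L))
  expect_false(identical(a$table$x_nm, c2$table$x_nm))
})

test_that("a non-star-shaped contour is a geometry error", {
  expect_error(simulate_localisations(smlm_spec(make_c_roi(), 100L, 5L)),
               "geometry error")
})

test_that("pure background with no gradient is uniform across rings", {
  circ <- make_circle_roi()
  sim <- simulate_localisations(smlm_spec(circ, 30000L, 0L,
                                          background_fraction = 1, seed = 5L))
  prof <- ring_profile(sim$table, build_rings(circ))
  p_hat <- prof$counts / 30000
  se <- sqrt((1 / 6) * (5 / 6) / 30000)
  expect_true(all(abs(p_hat - 1 / 6) <= 3 * se))
})

test_that("the planted radial gradient shifts mass to the outer rings", {
  circ <- make_circle_roi()
  sim <- simulate_localisations(smlm_spec(circ, 30000L, 30000L,
                                          cluster_sigma_nm = 0,
                                          background_fraction = 0,
                                          radial_gradient_gamma = 2, seed = 6L))
  prof <- ring_profile(sim$table, build_rings(circ))
  p_hat <- prof$counts / 30000
  p_exp <- expected_ring_probs(2)
  se <- sqrt(p_exp * (1 - p_exp) / 30000)
  expect_true(all(abs(p_hat - p_exp) <= 3 * se))
  expect_identical(sim$truth$expected_ring_probs, p_exp)
})

test_that("occupancy-regime presets order the pooled medians (carcinoma < normal)", {
  lower <- vapply(1:10, function(seed) {
    carc <- simulate_localisations(smlm_preset("carcinoma-like", seed = seed,
                                               total_count = 20000L))
    norm <- simulate_localisations(smlm_preset("normal-like", seed = seed + 1000L,
                                               total_count = 20000L))
    mc <- bin_count_distribution(bin_localisations(carc$table))$median
    mn <- bin_count_distribution(bin_localisations(norm$table))$median
    mc < mn
  }, logical(1L))
  expect_true(mean(lower) >= 0.9)
})

test_that("preset totals default to the desk-scale exemplar counts", {
  expect_equal(smlm_preset("carcinoma-like")$total_count, 1600L)
  expect_equal(smlm_preset("normal-like")$total_count, 9800L)
  expect_equal(smlm_preset("muscle-like")$total_count, 13400L)
  expect_equal(smlm_preset("submucosa-like")$total_count, 5500L)
})

test_that("simulated nuclei hit the planted compact fraction within 1%", {
  for (cf in list(c(0.1, 12), c(0.5, 4), c(0.9, 1))) {
    sim <- simulate_nucleus_image(nucleus_image_spec(40L, cf[1L], cf[2L], seed = 7L))
    expect_lt(abs(sim$truth$achieved_fraction - cf[1L]), 0.01)
    expect_true(all(sim$truth$nucleus_mask[sim$truth$domain_mask]))
  }
})

test_that("nucleus images are bit-identical under the same seed", {
  spec <- nucleus_image_spec(40L, 0.3, 8L, seed = 5L)
  expect_identical(simulate_nucleus_image(spec)$image$pixels,
                   simulate_nucleus_image(spec)$image$pixels)
})

test_that("unreachable compact fractions with non-overlapping patches error out", {
  expect_error(simulate_nucleus_image(nucleus_image_spec(40L, 0.9, 10L, seed = 1L)),
               "spec error")
})

test_that("a near-noiseless nucleus is recovered within 2 points", {
  sim <- simulate_nucleus_image(nucleus_image_spec(40L, 0.5, 4L,
                                                   noise_sigma = 0, seed = 13L))
  seg <- analyze_chromatin_compaction(sim$image)
  expect_lt(abs(seg$compact_percent - 100 * sim$truth$achieved_fraction), 2)
})

test_that("tissue fields plant the exact number of positive cells", {
  sim <- simulate_tissue_field(tissue_field_spec(20L, 0.25, seed = 9L))
  expect_equal(sim$truth$n_positive, 5)
  expect_equal(sum(sim$truth$is_positive), 5L)
  expect_true(all(sim$field$mir_channel >= 0 & sim$field$mir_channel <= 255))

  none <- simulate_tissue_field(tissue_field_spec(12L, 0, seed = 10L))
  fs <- field_summary(classify_mir_positive(detect_cells(none$field)))
  expect_equal(fs$percent_positive, 0)
})

test_that("high-contrast tissue fields are recovered exactly end to end", {
  sim <- simulate_tissue_field(tissue_field_spec(25L, 0.4, positive_mean = 30,
                                                 negative_mean = 1,
                                                 noise_sigma = 1, seed = 12L))
  fs <- field_summary(classify_mir_positive(detect_cells(sim$field)))
  expect_equal(fs$n_cells, 25L)
  expect_equal(fs$percent_positive, 40)
})

test_that("a field too small for the requested cells is a placement error", {
  expect_error(simulate_tissue_field(
    tissue_field_spec(50L, 0.5, seed = 1L, dim = c(64L, 64L))),
    "placement error")
})

test_that("truth sidecars are written as JSON", {
  sim <- simulate_tissue_field(tissue_field_spec(4L, 0.5, seed = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_sidecar(sim$truth, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$n_positive, 2)
})
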