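# Confocal nucleus segmentation, chromatin domains, compaction summary.

test_that("a bright disk is segmented with the analytic area", {
  set.seed(5)
  side <- 100L
  gx <- matrix(seq_len(side), side, side)
  gy <- matrix(seq_len(side), side, side, byrow = TRUE)
  px <- ifelse((gx - 50)^2 + (gy - 50)^2 <= 40^2, 200, 5) +
    matrix(rnorm(side^2, 0, 4), side, side)
  seg <- segment_nucleus(nucleus_image(pmax(px, 0), 0.1))
  expect_lt(abs(seg$nucleus_area_um2 - pi * 16) / (pi * 16), 0.02)
})

test_that("an image with no contrast is a segmentation error", {
  expect_error(segment_nucleus(nucleus_image(matrix(0, 32, 32), 0.1)),
               "segmentation error")
})

test_that("with two nuclei in the crop only the larger is kept", {
  side <- 120L
  gx <- matrix(seq_len(side), side, side)
  gy <- matrix(seq_len(side), side, side, byrow = TRUE)
  px <- matrix(5, side, side)
  px[(gx - 40)^2 + (gy - 60)^2 <= 30^2] <- 200   # diameter 60
  px[(gx - 100)^2 + (gy - 60)^2 <= 15^2] <- 200  # diameter 30
  seg <- segment_nucleus(nucleus_image(px, 0.1))
  expect_lt(abs(seg$nucleus_area_um2 - pi * 9) / (pi * 9), 0.05)
  expect_false(any(seg$mask[90:110, ]))
})

test_that("well-separated planted blobs are each detected as one domain", {
  centres <- as.matrix(expand.grid(x = c(30, 45, 60, 75), y = c(40, 60, 80)))
  img <- blob_nucleus(side = 120L, R = 50, centres = centres, seed = 2)
  seg <- segment_nucleus(img)
  maxima <- detect_chromatin_domains(img, seg$mask)
  expect_equal(nrow(maxima), 12L)
  # every planted centre has a detected maximum within 2 px
  d <- as.matrix(dist(rbind(centres, as.matrix(maxima[, c("x", "y")]))))
  nearest <- apply(d[1:12, 13:24, drop = FALSE], 1L, min)
  expect_true(all(nearest <= 2))
})

test_that("a flat nucleus yields zero domains and an all-zero label map", {
  side <- 80L
  gx <- matrix(seq_len(side), side, side)
  gy <- matrix(seq_len(side), side, side, byrow = TRUE)
  px <- matrix(0, side, side)
  nucleus <- (gx - 40)^2 + (gy - 40)^2 <= 30^2
  px[nucleus] <- 100
  img <- nucleus_image(px, 0.1)
  seg <- segment_nucleus(img, smoothing_sigma_px = 0)
  maxima <- detect_chromatin_domains(img, seg$mask, smoothing_sigma_px = 0)
  expect_equal(nrow(maxima), 0L)
  labels <- grow_domains(img, seg$mask, maxima)
  expect_true(all(labels == 0L))
})

test_that("peaks closer than the minimum separation are merged into one", {
  centres <- rbind(c(59, 60), c(61, 60))  # 2 px apart
  img <- blob_nucleus(side = 120L, R = 50, centres = centres, sigma = 1.5,
                      noise = 0, seed = 3)
  seg <- segment_nucleus(img)
  maxima <- detect_chromatin_domains(img, seg$mask, min_separation_px = 3L)
  expect_equal(nrow(maxima), 1L)
})

test_that("an isolated Gaussian blob grows to its half-max contour area", {
  img <- blob_nucleus(side = 120L, R = 50, centres = rbind(c(60, 60)),
                      amp = 150, sigma = 4, noise = 0, seed = 4)
  seg <- segment_nucleus(img, smoothing_sigma_px = 0)
  maxima <- detect_chromatin_domains(img, seg$mask, smoothing_sigma_px = 0)
  expect_equal(nrow(maxima), 1L)
  labels <- grow_domains(img, seg$mask, maxima, level_fraction = 0.5,
                         smoothing_sigma_px = 0)
  # analytic half-max disk of a Gaussian: radius sigma*sqrt(2 ln 2)
  analytic <- pi * (4 * sqrt(2 * log(2)))^2
  expect_lt(abs(sum(labels > 0L) - analytic) / analytic, 0.15)
})

test_that("two equal adjacent blobs split along the midline into equal domains", {
  centres <- rbind(c(48, 60), c(72, 60))
  img <- blob_nucleus(side = 120L, R = 50, centres = centres, amp = 150,
                      sigma = 4, noise = 0, seed = 6)
  seg <- segment_nucleus(img, smoothing_sigma_px = 0)
  maxima <- detect_chromatin_domains(img, seg$mask, smoothing_sigma_px = 0)
  expect_equal(nrow(maxima), 2L)
  labels <- grow_domains(img, seg$mask, maxima, smoothing_sigma_px = 0)
  a1 <- sum(labels == 1L); a2 <- sum(labels == 2L)
  expect_lt(abs(a1 - a2) / max(a1, a2), 0.10)
  # no domain pixel crosses to the far side of the midline
  expect_true(all(which(labels == 1L, arr.ind = TRUE)[, 1L] <= 60))
  expect_true(all(which(labels == 2L, arr.ind = TRUE)[, 1L] >= 60))
})

test_that("compaction summary subtracts domain area from nuclear area", {
  seg <- list(nucleus_area_um2 = 10, domain_total_area_um2 = 5)
  s <- compaction_summary(seg)
  expect_equal(s$compact_percent, 50)
  expect_equal(s$dark_area_um2, 5)
  none <- compaction_summary(list(nucleus_area_um2 = 10, domain_total_area_um2 = 0))
  expect_equal(none$compact_percent, 0)
  expect_equal(none$dark_area_um2, 10)
  expect_error(compaction_summary(list(nucleus_area_um2 = 1,
                                       domain_total_area_um2 = 2)),
               "consistency")
})

test_that("planted compact fractions are recovered within 5 points and monotonically", {
  cases <- list(c(0.1, 12), c(0.5, 4), c(0.9, 1))
  rec <- vapply(cases, function(cf) {
    sim <- simulate_nucleus_image(nucleus_image_spec(40L, cf[1L], cf[2L], seed = 11L))
    analyze_chromatin_compaction(sim$image)$compact_percent
  }, numeric(1L))
  expect_true(all(abs(rec - 100 * c(0.1, 0.5, 0.9)) <= 5))
  expect_true(all(diff(rec) > 0))
})

test_that("the whole analysis is invariant to intensity rescaling", {
  sim <- simulate_nucleus_image(nucleus_image_spec(40L, 0.3, 8L, seed = 9L))
  a <- analyze_chromatin_compaction(sim$image)
  scaled <- nucleus_image(sim$image$pixels * 7.3, sim$image$pixel_size_um)
  b <- analyze_chromatin_compaction(scaled)
  expect_identical(a$nucleus_mask, b$nucleus_mask)
  expect_identical(a$domain_label_map, b$domain_label_map)
  expect_equal(a$compact_percent, b$compact_percent)
  expect_equal(a$n_domains, b$n_domains)
})

test_that("compaction accounting is exact in pixel units", {
  sim <- simulate_nucleus_image(nucleus_image_spec(40L, 0.3, 8L, seed = 15L))
  seg <- analyze_chromatin_compaction(sim$image)
  expect_gte(seg$compact_percent, 0)
  expect_lte(seg$compact_percent, 100)
  expect_equal(seg$dark_area_um2 + seg$domain_total_area_um2,
               seg$nucleus_area_um2)
  expect_true(all(seg$nucleus_mask[seg$domain_label_map > 0L]))
})

test_that("mode +/- SD summary uses the tallest histogram bin and flags multimodality", {
  const <- mode_sd_summary(rep(92, 50))
  expect_equal(const$mode, 92)
  expect_equal(const$sd, 0)

  # sampling check: the histogram mode of a symmetric unimodal sample
  # tracks its centre to within the bin resolution (the tallest bin can
  # wobble to a neighbour, so the error is bounded over repeated draws)
  errs <- vapply(1:8, function(seed) {
    set.seed(1000 + seed)
    s <- mode_sd_summary(rnorm(10000, mean = 47, sd = 16))
    abs(s$mode - 47) / s$histogram_bin_width
  }, numeric(1L))
  expect_lt(median(errs), 1)
  expect_lt(max(errs), 4)
  set.seed(1234)
  s <- mode_sd_summary(rnorm(10000, mean = 47, sd = 16))
  expect_lt(abs(s$sd - 16), 0.5)
  expect_equal(s$n_peaks, 1L)

  bimodal <- mode_sd_summary(c(rnorm(3000, 10, 1), rnorm(3000, 30, 1)))
  expect_equal(bimodal$n_peaks, 2L)
  expect_true(abs(bimodal$mode - 10) < 1 || abs(bimodal$mode - 30) < 1)

  expect_error(mode_sd_summary(numeric()), "parameter error")
})

test_that("nucleus images survive a TIFF round trip", {
  sim <- simulate_nucleus_image(nucleus_image_spec(30L, 0.3, 5L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_matrix(sim$image$pixels, path, max_value = 255)
  back <- read_nucleus_image(path, 0.1)
  expect_equal(dim(back$pixels), dim(sim$image$pixels))
  # 16-bit quantisation of the 0-255 range: worst error 255/65535
  expect_lt(max(abs(back$pixels / 65535 * 255 - sim$image$pixels)), 0.005)
})
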