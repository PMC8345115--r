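# Per-cell miR-FISH quantification and the one-sided rank-sum test.

test_that("disjoint planted nuclei each yield one cell record", {
  sim <- simulate_tissue_field(tissue_field_spec(10L, 0.3, seed = 21L))
  cells <- detect_cells(sim$field)
  expect_equal(nrow(cells), 10L)
  expect_s3_class(cells, "cell_records")
  # nucleus and cytoplasm label maps are disjoint region sets
  nuc <- attr(cells, "nuclei_labels")
  cyt <- attr(cells, "cyto_labels")
  expect_true(all(cyt[nuc > 0L] == 0L))
})

test_that("a blank nuclear channel yields zero cells, not an error", {
  blank <- tissue_field(matrix(0, 64, 64), matrix(0, 64, 64), 0.5)
  expect_equal(nrow(detect_cells(blank)), 0L)
})

test_that("touching nuclei are split by the watershed into two cells", {
  side <- 80L
  gx <- matrix(seq_len(side), side, side)
  gy <- matrix(seq_len(side), side, side, byrow = TRUE)
  nucch <- matrix(0, side, side)
  nucch[(gx - 32)^2 + (gy - 40)^2 <= 9^2] <- 200
  nucch[(gx - 49)^2 + (gy - 40)^2 <= 9^2] <- 200   # centres 17 px apart, r 9
  field <- tissue_field(nucch, matrix(0, side, side), 0.5)
  cells <- detect_cells(field, min_nucleus_area_um2 = 10)
  expect_equal(nrow(cells), 2L)
  # split is near the midline: centroids on opposite sides
  expect_lt(min(cells$centroid_x_px), 40)
  expect_gt(max(cells$centroid_x_px), 41)
  # cytoplasm regions are pairwise disjoint by construction of the label map
  cyt <- attr(cells, "cyto_labels")
  expect_setequal(unique(as.vector(cyt)), c(0L, 1L, 2L))
})

test_that("positivity is boundary-inclusive at the threshold", {
  sim <- simulate_tissue_field(tissue_field_spec(4L, 0, seed = 1L))
  cells <- detect_cells(sim$field)[1:3, ]
  class(cells) <- c("cell_records", "data.frame")
  cells$cytoplasm_mir_intensity <- c(5.0, 4.99, 0)
  cells <- classify_mir_positive(cells, threshold = 5)
  expect_equal(cells$is_mir_positive, c(TRUE, FALSE, FALSE))
})

test_that("raising the threshold never increases the number of positives", {
  sim <- simulate_tissue_field(tissue_field_spec(16L, 0.5, noise_sigma = 3,
                                                 seed = 8L))
  cells <- detect_cells(sim$field)
  n_pos <- vapply(c(0, 2, 5, 20, 40, 300), function(th)
    sum(classify_mir_positive(cells, th)$is_mir_positive), numeric(1L))
  expect_true(all(diff(n_pos) <= 0))
})

test_that("field summaries report the percentage of miR+ cells", {
  sim <- simulate_tissue_field(tissue_field_spec(10L, 0.2, seed = 31L))
  cells <- classify_mir_positive(detect_cells(sim$field))
  fs <- field_summary(cells)
  expect_equal(fs$n_cells, 10L)
  expect_equal(fs$n_positive, 2L)
  expect_equal(fs$percent_positive, 20)

  all_pos <- simulate_tissue_field(tissue_field_spec(8L, 1, seed = 32L))
  fs2 <- field_summary(classify_mir_positive(detect_cells(all_pos$field)))
  expect_equal(fs2$percent_positive, 100)

  empty <- detect_cells(tissue_field(matrix(0, 64, 64), matrix(0, 64, 64), 0.5))
  expect_error(field_summary(empty), "zero cells")
  unclassified <- detect_cells(sim$field)
  expect_error(field_summary(unclassified), "classify")
})

test_that("planted positive fractions are recovered at high contrast", {
  sim <- simulate_tissue_field(tissue_field_spec(200L, 0.3, positive_mean = 30,
                                                 negative_mean = 1,
                                                 noise_sigma = 1, seed = 77L))
  cells <- classify_mir_positive(detect_cells(sim$field))
  fs <- field_summary(cells)
  expect_equal(fs$n_cells, 200L)
  expect_lt(abs(fs$percent_positive - 30), 3)
})

test_that("fully separated samples give the exact enumeration p-value", {
  r <- rank_sum_one_sided(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1 / 20)
  expect_equal(r$u_statistic, 9)
  # reversed direction: the extreme ordering in the other tail
  r2 <- rank_sum_one_sided(c(4, 5, 6), c(1, 2, 3), "less")
  expect_equal(r2$p_value, 1)
  # identical samples show no separation
  r3 <- rank_sum_one_sided(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_gt(r3$p_value, 0.5)
  expect_error(rank_sum_one_sided(numeric(), 1), "parameter error")
})

test_that("exact p-values match wilcox.test and a permutation oracle", {
  set.seed(55)
  for (rep in 1:5) {
    x <- round(rnorm(5, 1), 3)
    y <- round(rnorm(5), 3)
    r <- rank_sum_one_sided(x, y, "greater")
    expect_equal(r$method, "exact")
    expect_equal(r$p_value,
                 wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value)
  }
  # Monte-Carlo permutation oracle
  x <- c(1.2, 3.4, 0.5, 2.2, 4.1)
  y <- c(0.1, 1.1, 2.0, 0.7, 1.9)
  r <- rank_sum_one_sided(x, y, "greater")
  pool <- c(x, y)
  set.seed(99)
  u_perm <- replicate(10000, {
    idx <- sample(10L, 5L)
    sum(rank(pool)[idx]) - 15
  })
  expect_lt(abs(mean(u_perm >= r$u_statistic) - r$p_value), 0.01)
})

test_that("sidedness identity holds for tie-free exact tests", {
  set.seed(60)
  x <- rnorm(4); y <- rnorm(5)
  pg <- rank_sum_one_sided(x, y, "greater")$p_value
  pl <- rank_sum_one_sided(y, x, "greater")$p_value
  # P(U >= u) + P(U' >= u') = 1 + P(U = u) under the exact null
  combs <- utils::combn(9L, 4L)
  us <- colSums(matrix(rank(c(x, y))[combs], nrow = 4L)) - 10
  u_obs <- sum(rank(c(x, y))[1:4]) - 10
  expect_equal(pg + pl, 1 + mean(us == u_obs))
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(70)
  x <- rnorm(20, 0.8); y <- rnorm(25)
  r <- rank_sum_one_sided(x, y, "greater")
  expect_equal(r$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                      exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  # ties force the approximation even at small n
  xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4)
  rt <- rank_sum_one_sided(xt, yt, "less")
  expect_equal(rt$method, "normal_approx")
  reft <- suppressWarnings(wilcox.test(xt, yt, alternative = "less",
                                       exact = FALSE, correct = TRUE))
  expect_equal(rt$p_value, reft$p.value, tolerance = 1e-10)
})

test_that("background subtraction clips at zero and feeds classification", {
  sim <- simulate_tissue_field(tissue_field_spec(9L, 1, positive_mean = 10,
                                                 noise_sigma = 0, seed = 4L))
  corrected <- subtract_background(sim$field, mir_bg = 8)
  expect_gte(min(corrected$mir_channel), 0)
  cells <- classify_mir_positive(detect_cells(corrected))
  expect_equal(sum(cells$is_mir_positive), 0L)  # 10 - 8 = 2 < 5
})
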