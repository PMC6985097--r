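test_that("noiseless simulation recovers 50% positive cells", {
  sim <- generate_micrograph(small_image_spec(seed = 3))
  q <- quantify_micrograph(sim$micrograph)
  expect_equal(q$markers$marker_1$percent_positive_cells, 50)
})

test_that("empty marker mask gives zero positives and zero area", {
  seg <- structure(list(mask = matrix(FALSE, 40, 40), threshold = 0.5,
                        qc_pcc = 0.9, qc_passed = TRUE,
                        fallback_applied = FALSE, exclusion_mask = NULL),
                   class = "segmentation_result")
  q <- quantify_marker(seg, cbind(x = c(10, 30), y = c(10, 30)), 0.64)
  expect_identical(q$n_positive_cells, 0L)
  expect_equal(q$percent_area, 0)
  expect_equal(q$percent_area_per_avg_cell, 0)
  expect_equal(q$cells_per_mm2, 0)
})

test_that("whole-frame mask with one nucleus covers 100% of the area", {
  seg <- structure(list(mask = matrix(TRUE, 40, 40), threshold = 0.5,
                        qc_pcc = 0.9, qc_passed = TRUE,
                        fallback_applied = FALSE, exclusion_mask = NULL),
                   class = "segmentation_result")
  q <- quantify_marker(seg, cbind(x = 20, y = 20), 0.64)
  expect_identical(q$n_positive_cells, 1L)
  expect_equal(q$percent_area, 100)
  # one positive cell in a 40x40 field at 0.64 um/px
  expect_equal(q$cells_per_mm2, 1 / (1600 * (0.64 / 1000)^2))
})

test_that("per-cell area times count reproduces the total percent area", {
  for (seed in 1:5) {
    sim <- generate_micrograph(small_image_spec(seed = seed, noise_sd = 0.05))
    q <- quantify_micrograph(sim$micrograph)$markers$marker_1
    if (q$n_positive_cells > 0)
      expect_equal(q$percent_area_per_avg_cell * q$n_positive_cells,
                   q$percent_area, tolerance = 1e-9)
  }
})

test_that("zero nuclei make the positive-cell percentage an error", {
  seg <- structure(list(mask = matrix(TRUE, 10, 10), threshold = 0.5,
                        qc_pcc = 0.9, qc_passed = TRUE,
                        fallback_applied = FALSE, exclusion_mask = NULL),
                   class = "segmentation_result")
  expect_error(quantify_marker(seg, matrix(numeric(0), 0, 2,
                                           dimnames = list(NULL, c("x", "y"))),
                               0.64),
               class = "undefined_percentage")
})

test_that("co-localization of a channel with itself is 1", {
  sim <- generate_micrograph(small_image_spec(seed = 7, noise_sd = 0.02))
  ch <- sim$micrograph$channels$marker_1
  expect_equal(colocalize(ch, ch)$pcc, 1, tolerance = 1e-14)
})

test_that("fully co-expressed markers give PCC near 1, disjoint sets below 0", {
  same <- generate_micrograph(small_image_spec(
    seed = 8, fractions = c(0.5, 0.5), coexpression_pcc_target = 1))
  r1 <- colocalize(same$micrograph$channels$marker_1,
                   same$micrograph$channels$marker_2)
  expect_gt(r1$pcc, 0.99)
  disj <- generate_micrograph(small_image_spec(
    seed = 8, fractions = c(0.5, 0.5), coexpression_pcc_target = -1))
  r2 <- colocalize(disj$micrograph$channels$marker_1,
                   disj$micrograph$channels$marker_2)
  expect_lte(r2$pcc, 0)
})

test_that("mask policy changes the pixel set and is recorded", {
  sim <- generate_micrograph(small_image_spec(seed = 9,
                                              fractions = c(0.5, 0.5)))
  a <- sim$micrograph$channels$marker_1
  b <- sim$micrograph$channels$marker_2
  all_px <- colocalize(a, b, "all")
  union_px <- colocalize(a, b, "union")
  expect_identical(all_px$mask_policy, "all")
  expect_identical(union_px$mask_policy, "union")
  expect_lt(union_px$n_pixels, all_px$n_pixels)
  expect_identical(all_px$n_pixels, length(a))
})
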