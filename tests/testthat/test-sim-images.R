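test_that("marker-positive count equals round(fraction * n_cells) exactly", {
  for (frac in c(0.25, 0.5, 0.77)) {
    sim <- generate_micrograph(small_image_spec(seed = 1, fractions = frac))
    expect_identical(sum(sim$ground_truth$marker_1), as.integer(round(frac * 20)))
  }
})

test_that("same spec and seed give bit-identical images", {
  spec <- small_image_spec(seed = 9, noise_sd = 0.05,
                           illumination_gradient_amplitude = 0.3)
  a <- generate_micrograph(spec)
  b <- generate_micrograph(spec)
  expect_identical(a$micrograph$channels, b$micrograph$channels)
  expect_identical(a$ground_truth, b$ground_truth)
  d <- generate_micrograph(small_image_spec(seed = 10, noise_sd = 0.05,
                                            illumination_gradient_amplitude = 0.3))
  expect_false(identical(a$micrograph$channels$nuclei,
                         d$micrograph$channels$nuclei))
})

test_that("two-marker co-expression approaches the requested correlation", {
  for (rho in c(-0.5, 0, 0.8)) {
    sim <- generate_micrograph(small_image_spec(
      seed = 5, n_cells = 40L, fractions = c(0.5, 0.5),
      coexpression_pcc_target = rho, mean_cell_area_px = 150,
      area_dispersion_px = 30))
    realized <- attr(sim$ground_truth, "realized_coexpression_pcc")
    expect_lt(abs(realized - rho), 0.25)
  }
  # full co-expression with equal fractions lights identical cell sets
  sim <- generate_micrograph(small_image_spec(
    seed = 5, fractions = c(0.5, 0.5), coexpression_pcc_target = 1))
  expect_identical(sim$ground_truth$marker_1, sim$ground_truth$marker_2)
})

test_that("noiseless pipeline recovers the true positive fraction exactly", {
  sim <- generate_micrograph(small_image_spec(seed = 2))
  q <- quantify_micrograph(sim$micrograph)
  expect_identical(q$nuclei$n_nuclei, 20L)
  expect_identical(q$markers$marker_1$n_positive_cells,
                   as.integer(sum(sim$ground_truth$marker_1)))
  expect_equal(q$markers$marker_1$percent_positive_cells, 50)
  true_area <- 100 * attr(sim$ground_truth, "marker_area_px")[1] / (347 * 260)
  expect_equal(q$markers$marker_1$percent_area, true_area, tolerance = 1e-12)
})

test_that("invalid specs are rejected", {
  expect_error(image_sim_spec(n_cells = 0, marker_positive_fraction = 0.5),
               class = "invalid_spec")
  expect_error(image_sim_spec(marker_positive_fraction = 1.2),
               class = "invalid_spec")
  expect_error(image_sim_spec(pixel_size_um = 0), class = "invalid_spec")
})

test_that("micrographs round-trip through multi-page TIFF", {
  sim <- generate_micrograph(small_image_spec(seed = 6, fractions = c(0.5, 0.3)))
  path <- file.path(withr::local_tempdir(), "field.tiff")
  write_micrograph(sim$micrograph, path, sim$ground_truth)
  back <- read_micrograph(path, names(sim$micrograph$channels),
                          sim$micrograph$pixel_size_um)
  expect_identical(names(back$channels), c("nuclei", "marker_1", "marker_2"))
  # 16-bit quantization error only (stored values are clipped to [0, 1])
  stored <- pmin(pmax(sim$micrograph$channels$nuclei, 0), 1)
  expect_lt(max(abs(back$channels$nuclei - stored)), 1 / 65535 + 1e-9)
  expect_true(file.exists(sub("\\.tiff$", "_truth.csv", path)))
})
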