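test_that("all-non-responder sets fluctuate about the baseline only", {
  sim <- generate_trace_set(trace_sim_spec(n_roi = 6, nonresponder_fraction = 1,
                                           noise_sd = 0.02, seed = 4))
  expect_true(all(!sim$ground_truth$responder))
  for (tr in sim$traces)
    expect_lt(max(abs(tr$f - 100)), 100 * 0.02 * 6)   # within 6 SD of F0
})

test_that("noiseless monophasic tail is exactly a * exp(-t/tau)", {
  sim <- generate_trace_set(trace_sim_spec(n_roi = 1, noise_sd = 0,
                                           nonresponder_fraction = 0,
                                           latency_s = 3, decay_tau_s = 60,
                                           seed = 8))
  tr <- sim$traces[[1]]
  peak_t <- 20 + 3 + 6.4                       # stimulus + latency + rise
  tail <- tr$time_s >= peak_t
  y <- tr$f[tail] / 100 - 1
  tp <- tr$time_s[tail] - tr$time_s[tail][1]   # relative to first tail sample
  expect_equal(y, y[1] * exp(-tp / 60), tolerance = 1e-12)
})

test_that("treatment attenuation scales the peak exactly under a shared seed", {
  ctl <- generate_trace_set(trace_sim_spec(n_roi = 4, noise_sd = 0,
                                           nonresponder_fraction = 0, seed = 5))
  trt <- generate_trace_set(trace_sim_spec(n_roi = 4, noise_sd = 0,
                                           nonresponder_fraction = 0,
                                           treatment_attenuation = 0.2, seed = 5))
  for (i in 1:4)
    expect_equal(max(trt$traces[[i]]$f - 100) / max(ctl$traces[[i]]$f - 100),
                 0.2, tolerance = 1e-12)
})

test_that("same spec and seed reproduce traces bit for bit", {
  spec <- trace_sim_spec(n_roi = 5, noise_sd = 0.03, seed = 11)
  a <- generate_trace_set(spec)
  b <- generate_trace_set(spec)
  expect_identical(lapply(a$traces, `[[`, "f"), lapply(b$traces, `[[`, "f"))
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("ground-truth kinetic parameters mirror the generating spec", {
  spec <- trace_sim_spec(n_roi = 10, latency_s = 10, decay_tau_s = 75,
                         rise_duration_s = 5, nonresponder_fraction = 0.3,
                         biphasic_plateau_ratio = 0.6, seed = 3)
  gt <- generate_trace_set(spec)$ground_truth
  expect_identical(sum(!gt$responder), 3L)     # round(0.3 * 10)
  resp <- gt[gt$responder, ]
  expect_true(all(resp$latency_s == 10))
  expect_true(all(resp$decay_tau_s == 75))
  expect_equal(resp$rise_time_10_90_s,
               rep((acos(-0.8) - acos(0.8)) / pi * 5, nrow(resp)))
  expect_true(all(resp$phase == "biphasic"))
  expect_true(all(gt$phase[!gt$responder] == "none"))
})

test_that("inconsistent durations are rejected", {
  expect_error(trace_sim_spec(duration_s = 40, stimulus_time_s = 20,
                              latency_s = 23, rise_duration_s = 6),
               class = "invalid_spec")
})

test_that("trace sets round-trip through wide CSV", {
  sim <- generate_trace_set(trace_sim_spec(n_roi = 3, seed = 2))
  path <- file.path(withr::local_tempdir(), "traces.csv")
  write_trace_set(sim$traces, path, sim$ground_truth)
  back <- read_trace_set(path, stimulus_time_s = 20)
  expect_length(back, 3)
  expect_equal(back[[2]]$f, sim$traces[[2]]$f, tolerance = 1e-9)
  expect_identical(back[[2]]$roi_id, "roi_2")
})
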