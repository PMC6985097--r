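test_that("baseline normalization is exact and gain-free", {
  expect_equal(normalize_f_f0(trace_from_f(rep(5, 50) / 5, f0 = 5))$f_over_f0,
               rep(1, 50))
  # baseline mean 2, later plateau 6 -> normalized plateau 3
  f <- c(rep(2, 21), rep(6, 30))
  norm <- normalize_f_f0(trace_from_f(f))
  expect_equal(norm$f0, 2)
  expect_equal(norm$f_over_f0[30], 3)
  # invariant: mean F/F0 over the baseline window is 1 to machine precision
  set.seed(1)
  for (i in 1:10) {
    tr <- trace_from_f(rlnorm(60, 1, 0.2))
    nm <- normalize_f_f0(tr)
    inb <- nm$time_s <= 20
    expect_equal(mean(nm$f_over_f0[inb]), 1, tolerance = 1e-12)
  }
  expect_error(normalize_f_f0(trace_from_f(c(rep(0, 21), rep(1, 10)))),
               class = "normalization_error")
})

test_that("low-pass filter preserves DC, attenuates, and adds no phase lag", {
  const <- lowpass(normalize_f_f0(trace_from_f(rep(3, 100) / 3, f0 = 3)))
  expect_equal(const$f_over_f0, rep(1, 100), tolerance = 1e-9)
  # sinusoid at twice the cutoff: amplitude down at least 10-fold
  t <- 0:299
  f <- 10 + sin(2 * pi * 0.4 * t)
  norm <- normalize_f_f0(trace_from_f(f / 10, f0 = 10))
  filt <- lowpass(norm, cutoff_hz = 0.2)
  expect_lt(max(abs(filt$f_over_f0[100:200] - mean(filt$f_over_f0[100:200]))),
            0.1 / 10)
  # zero-phase contract: the step's half-rise point does not move
  st <- c(rep(1, 50), rep(2, 50))
  fs <- lowpass(normalize_f_f0(trace_from_f(st)), cutoff_hz = 0.2)
  half <- approx(fs$f_over_f0[45:60], fs$time_s[45:60],
                 xout = (1 + max(fs$f_over_f0)) / 2 / fs$f_over_f0[1])$y
  expect_equal(half, 49.5, tolerance = 0.2)
  expect_error(lowpass(norm, cutoff_hz = 0.5), class = "invalid_parameter")
})

test_that("non-responders and responders are told apart with correct onsets", {
  nr <- generate_trace_set(trace_sim_spec(n_roi = 1, nonresponder_fraction = 1,
                                          noise_sd = 0.02, seed = 6))
  f <- extract_features(nr$traces[[1]])
  expect_false(f$responder)
  expect_true(is.na(f$latency_s))
  expect_identical(f$phase, "none")
  # noiseless responder with latency 5: onset within one sample of truth
  re <- generate_trace_set(trace_sim_spec(n_roi = 1, nonresponder_fraction = 0,
                                          latency_s = 5, noise_sd = 0, seed = 6))
  fr <- extract_features(re$traces[[1]])
  expect_true(fr$responder)
  expect_lt(abs(fr$onset_time_s - 25), 1)
})

test_that("rise time matches closed-form values on constructed shapes", {
  # linear ramp baseline->peak over 10 s: RT = (0.9 - 0.1) * 10 = 8
  ramp <- c(rep(1, 21), 1 + (1:10) / 10, rep(2, 20))
  rt <- rise_time(normalize_f_f0(trace_from_f(ramp)), onset_time_s = 20)
  expect_equal(rt$rise_time_s, 8)
  expect_equal(rt$peak_amplitude, 1)
  # single-sample step: RT bounded by one sample interval
  step <- c(rep(1, 25), rep(2, 25))
  rts <- rise_time(normalize_f_f0(trace_from_f(step)), onset_time_s = 23)
  expect_lte(rts$rise_time_s, 1)
  # simulator rise shape, unfiltered and noiseless: within 2% of truth
  sim <- generate_trace_set(trace_sim_spec(n_roi = 1, nonresponder_fraction = 0,
                                           noise_sd = 0, seed = 2))
  norm <- normalize_f_f0(sim$traces[[1]])
  rtu <- rise_time(norm, sim$ground_truth$onset_time_s[1])
  expect_equal(rtu$rise_time_s, sim$ground_truth$rise_time_10_90_s[1],
               tolerance = 0.02)
  expect_error(rise_time(norm, NA_real_), class = "undefined_feature")
})

test_that("exponential decay fit recovers tau and flags degenerate tails", {
  # pure noiseless tail a = 1, tau = 60
  t <- 0:299
  f <- ifelse(t < 25, 1, 1 + exp(-(t - 25) / 60))
  fit <- fit_decay(normalize_f_f0(trace_from_f(f)), peak_time_s = 25)
  expect_true(fit$fit_ok)
  expect_equal(fit$tau_s, 60, tolerance = 1e-3)
  expect_equal(fit$a, 1, tolerance = 1e-3)
  expect_lte(fit$t_end_s, 300)
  # flat post-peak plateau: tau diverges and is flagged
  flat <- c(rep(1, 21), rep(2, 280))
  ff <- fit_decay(normalize_f_f0(trace_from_f(flat)), peak_time_s = 21)
  expect_false(ff$fit_ok)
  expect_true(is.na(ff$tau_s))
})

test_that("fitted tau increases strictly with the true tau (noiseless)", {
  taus <- c(40, 60, 80, 120)
  fitted <- sapply(taus, function(tau) {
    sim <- generate_trace_set(trace_sim_spec(n_roi = 1, nonresponder_fraction = 0,
                                             decay_tau_s = tau, noise_sd = 0,
                                             latency_s = 3, seed = 1))
    extract_features(sim$traces[[1]])$decay_tau_s
  })
  expect_true(all(diff(fitted) > 0))
})

test_that("AUC equals closed-form areas of simple pulses", {
  # rectangle: height 1 (F/F0 2 vs baseline 1), width 10 s
  rect <- c(rep(1, 21), rep(2, 11), rep(1, 19))
  norm <- normalize_f_f0(trace_from_f(rect))
  expect_equal(compute_auc(norm, 21, 31), 10)
  # triangle: height 2, base 10 s -> area 10
  tri <- c(rep(1, 21), 1 + 2 * (1:5) / 5, 1 + 2 * (4:0) / 5, rep(1, 20))
  expect_equal(compute_auc(normalize_f_f0(trace_from_f(tri)), 20, 31), 10)
  # zero amplitude
  expect_equal(compute_auc(normalize_f_f0(trace_from_f(rep(1, 60))), 20, 50), 0)
})

test_that("phase classification follows the sustained half-amplitude rule", {
  # single exponential: never re-crosses half -> monophasic
  t <- 0:299
  mono <- ifelse(t < 23, 1, 1 + exp(-(t - 23) / 60))
  expect_identical(classify_phase(normalize_f_f0(trace_from_f(mono)), 23, 1),
                   "monophasic")
  # simulated plateau 0.6 of peak: stays above half -> biphasic
  sim <- generate_trace_set(trace_sim_spec(n_roi = 1, nonresponder_fraction = 0,
                                           biphasic_plateau_ratio = 0.6,
                                           noise_sd = 0, seed = 4))
  expect_identical(extract_features(sim$traces[[1]])$phase, "biphasic")
  # re-rise above half sustained 25 s -> biphasic
  f <- c(rep(1, 21), 2, 1.6, 1.2, rep(1.7, 26), rep(1, 30))
  expect_identical(classify_phase(normalize_f_f0(trace_from_f(f)), 21, 1),
                   "biphasic")
  # plateau exactly at half, shorter than d_sustain -> monophasic
  g <- c(rep(1, 21), 2, 1.9, 1.7, rep(1.5, 15), rep(1, 40))
  expect_identical(classify_phase(normalize_f_f0(trace_from_f(g)), 21, 1),
                   "monophasic")
})

test_that("kinetic features are invariant to a positive gain on the raw trace", {
  sim <- generate_trace_set(trace_sim_spec(n_roi = 1, nonresponder_fraction = 0,
                                           noise_sd = 0.02, seed = 9))
  tr <- sim$traces[[1]]
  scaled <- calcium_trace(tr$time_s, 7.3 * tr$f, tr$stimulus_time_s)
  f1 <- extract_features(tr)
  f2 <- extract_features(scaled)
  for (field in c("latency_s", "rise_time_s", "peak_amplitude", "auc",
                  "decay_tau_s"))
    expect_equal(f1[[field]], f2[[field]], tolerance = 1e-6)
  expect_identical(f1$phase, f2$phase)
  expect_equal(f2$f0, 7.3 * f1$f0, tolerance = 1e-9)
})

test_that("a corrupt trace is flagged without aborting the batch", {
  sim <- generate_trace_set(trace_sim_spec(n_roi = 3, seed = 5))
  sim$traces[[2]]$f[100:110] <- NaN
  batch <- extract_features_batch(sim$traces)
  expect_identical(nrow(batch), 3L)
  expect_true(is.na(batch$error[1]) && is.na(batch$error[3]))
  expect_false(is.na(batch$error[2]))
})

test_that("group summaries report response rates and SEM conventions", {
  sim <- generate_trace_set(trace_sim_spec(n_roi = 10,
                                           nonresponder_fraction = 0.2,
                                           noise_sd = 0.02, seed = 12))
  feats <- extract_features_batch(sim$traces)
  summ <- summarize_response_rates(feats, group_cols = character(0))
  expect_equal(summ$percent_nonresponsive, 20)
  expect_identical(summ$n, 10L)
  # treated group shows the stunted amplitude the antagonist emulation forces
  trt <- extract_features_batch(generate_trace_set(
    trace_sim_spec(n_roi = 10, nonresponder_fraction = 0.2, noise_sd = 0.02,
                   treatment_attenuation = 0.2, seed = 12))$traces)
  expect_lt(mean(trt$peak_amplitude, na.rm = TRUE),
            mean(feats$peak_amplitude, na.rm = TRUE))
  # single-trace group: SEM undefined
  one <- summarize_response_rates(feats[1, , drop = FALSE],
                                  group_cols = character(0))
  expect_true(is.na(one$auc_sem))
})
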