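## Synthetic ATP-evoked calcium trace generator.
##
## A responding ROI follows F(t) = F0 * (1 + A * s(t)) + noise, where s is 0
## until stimulus + latency, rises as a raised cosine to 1 over the rise
## duration, then decays as (1 - p) * exp(-dt/tau) + p. The raised-cosine
## rise keeps the waveform band-limited (real somatic Ca2+ transients are
## smooth), and has a closed-form 10-90% rise time of
## (acos(-0.8) - acos(0.8)) / pi * rise_duration ~= 0.5903 * rise_duration.

RISE_10_90_FACTOR <- (acos(-0.8) - acos(0.8)) / pi

#' Specification for a set of simulated calcium traces
#'
#' Defaults emulate the recordings the analysis was designed for: 5-10 ROIs
#' per coverslip recorded for 300 s at 1 Hz, agonist applied at 20 s, onset
#' latency around 23 s, decay time constant around 80 s, a 10-90% rise time
#' near 3.8 s, and roughly one in five cells not responding.
#'
#' @param n_roi number of ROIs (traces) in the set.
#' @param duration_s recording length in seconds (default 300).
#' @param sample_interval_s sampling interval in seconds (> 0; default 1, an
#'   acquisition rate typical for widefield Ca2+ spectrofluorometry).
#' @param baseline_f0 resting fluorescence in arbitrary units (> 0).
#' @param stimulus_time_s time of agonist (ATP) application (default 20 s,
#'   the end of the baseline window).
#' @param latency_s delay (>= 0) from stimulus to transient initiation.
#' @param rise_duration_s duration (> 0) of the raised-cosine rise; the true
#'   10-90% rise time is `0.5903 * rise_duration_s`.
#' @param peak_amplitude_ratio peak `F/F0 - 1` of an untreated responder
#'   (> 0); individual ROIs jitter this by a uniform factor in \[0.9, 1.1\].
#' @param decay_tau_s exponential decay time constant in seconds (> 0).
#' @param biphasic_plateau_ratio plateau level `p` in \[0, 1) as a fraction
#'   of peak amplitude; 0 gives a monophasic single-exponential decay, while
#'   `p >= 0.5` holds the decayed signal above half of peak (a sustained,
#'   biphasic response).
#' @param nonresponder_fraction fraction in \[0, 1\] of ROIs that show no
#'   transient; the realized count is `round(fraction * n_roi)`.
#' @param treatment_attenuation multiplicative amplitude factor in \[0, 1\]
#'   emulating antagonist treatment (1 = untreated; smaller values give the
#'   stunted responses seen under purinoceptor blockade).
#' @param noise_sd per-sample additive Gaussian noise, in `F/F0` units.
#' @param seed integer; reproducible bit for bit.
#' @return an object of class `trace_sim_spec`.
#' @seealso [generate_trace_set()]
#' @export
trace_sim_spec <- function(n_roi = 8L, duration_s = 300, sample_interval_s = 1,
                           baseline_f0 = 100, stimulus_time_s = 20,
                           latency_s = 23, rise_duration_s = 6.4,
                           peak_amplitude_ratio = 1, decay_tau_s = 80,
                           biphasic_plateau_ratio = 0,
                           nonresponder_fraction = 0.2,
                           treatment_attenuation = 1,
                           noise_sd = 0.02, seed = 1L) {
  check_scalar(n_roi, "n_roi", 1, Inf, integer = TRUE)
  check_scalar(duration_s, "duration_s", 0, Inf, allow_equal = FALSE)
  check_scalar(sample_interval_s, "sample_interval_s", 0, Inf, allow_equal = FALSE)
  check_scalar(baseline_f0, "baseline_f0", 0, Inf, allow_equal = FALSE)
  check_scalar(stimulus_time_s, "stimulus_time_s", 0, duration_s)
  check_scalar(latency_s, "latency_s", 0, Inf)
  check_scalar(rise_duration_s, "rise_duration_s", 0, Inf, allow_equal = FALSE)
  check_scalar(peak_amplitude_ratio, "peak_amplitude_ratio", 0, Inf, allow_equal = FALSE)
  check_scalar(decay_tau_s, "decay_tau_s", 0, Inf, allow_equal = FALSE)
  check_scalar(biphasic_plateau_ratio, "biphasic_plateau_ratio", 0, 1 - 1e-12)
  check_scalar(nonresponder_fraction, "nonresponder_fraction", 0, 1)
  check_scalar(treatment_attenuation, "treatment_attenuation", 0, 1)
  check_scalar(noise_sd, "noise_sd", 0, Inf)
  check_scalar(seed, "seed", -Inf, Inf, integer = TRUE)
  if (duration_s < stimulus_time_s + latency_s + rise_duration_s)
    stop_aq("duration_s must cover stimulus_time_s + latency_s + rise_duration_s",
            "invalid_spec")
  structure(list(n_roi = as.integer(n_roi), duration_s = duration_s,
                 sample_interval_s = sample_interval_s,
                 baseline_f0 = baseline_f0, stimulus_time_s = stimulus_time_s,
                 latency_s = latency_s, rise_duration_s = rise_duration_s,
                 peak_amplitude_ratio = peak_amplitude_ratio,
                 decay_tau_s = decay_tau_s,
                 biphasic_plateau_ratio = biphasic_plateau_ratio,
                 nonresponder_fraction = nonresponder_fraction,
                 treatment_attenuation = treatment_attenuation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trace_sim_spec")
}

#' Single-ROI calcium fluorescence trace
#'
#' @param time_s strictly increasing sample times in seconds.
#' @param f raw fluorescence values, one per sample.
#' @param stimulus_time_s agonist application time, inside the recording.
#' @param roi_id identifier for the ROI.
#' @param metadata optional named list of group labels (DIV, treatment, ...).
#' @return an object of class `calcium_trace`.
#' @export
calcium_trace <- function(time_s, f, stimulus_time_s, roi_id = "roi_1",
                          metadata = list()) {
  if (length(time_s) != length(f) || length(f) < 2L)
    stop_aq("time_s and f must have equal length >= 2", "invalid_spec")
  if (any(diff(time_s) <= 0))
    stop_aq("time_s must be strictly increasing", "invalid_spec")
  if (stimulus_time_s < time_s[1] || stimulus_time_s > time_s[length(time_s)])
    stop_aq("stimulus_time_s must lie within the recording", "invalid_spec")
  structure(list(time_s = as.numeric(time_s), f = as.numeric(f),
                 stimulus_time_s = stimulus_time_s,
                 roi_id = as.character(roi_id), metadata = metadata),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %s: %d samples, %.4g-%.4g s, stimulus at %g s\n",
              x$roi_id, length(x$f), x$time_s[1], x$time_s[length(x$time_s)],
              x$stimulus_time_s))
  invisible(x)
}

## normalized response shape s(t) in [0, 1]
transient_shape <- function(t, onset, rise, tau, plateau) {
  s <- numeric(length(t))
  rising <- t >= onset & t < onset + rise
  s[rising] <- (1 - cos(pi * (t[rising] - onset) / rise)) / 2
  decaying <- t >= onset + rise
  s[decaying] <- (1 - plateau) * exp(-(t[decaying] - onset - rise) / tau) + plateau
  s
}

#' Simulate a set of calcium traces with ground truth
#'
#' @param spec a [trace_sim_spec()].
#' @return list with components:
#'   \describe{
#'     \item{traces}{list of [calcium_trace()] objects.}
#'     \item{ground_truth}{data frame with one row per ROI: `responder`,
#'       `latency_s`, `onset_time_s`, `rise_time_10_90_s`, `peak_amplitude`
#'       (true peak `F/F0 - 1`), `decay_tau_s`, `plateau_ratio`, and the
#'       generative `phase` (`monophasic`, `biphasic`, or `none`). Kinetic
#'       fields are `NA` for non-responders. The generating `spec` is
#'       attached as an attribute.}
#'   }
#' @examples
#' sim <- generate_trace_set(trace_sim_spec(n_roi = 5, noise_sd = 0, seed = 3))
#' sim$ground_truth[, c("roi_id", "responder", "latency_s")]
#' @export
generate_trace_set <- function(spec) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  with_seed(spec$seed, {
    t <- seq(0, spec$duration_s, by = spec$sample_interval_s)
    n <- spec$n_roi
    n_nr <- round(spec$nonresponder_fraction * n)
    nonresp <- rep(FALSE, n)
    if (n_nr > 0) nonresp[sample.int(n, n_nr)] <- TRUE
    amp <- spec$peak_amplitude_ratio * spec$treatment_attenuation *
      runif(n, 0.9, 1.1)
    onset <- spec$stimulus_time_s + spec$latency_s
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      s <- if (nonresp[i]) numeric(length(t))
           else amp[i] * transient_shape(t, onset, spec$rise_duration_s,
                                         spec$decay_tau_s,
                                         spec$biphasic_plateau_ratio)
      f <- spec$baseline_f0 * (1 + s)
      if (spec$noise_sd > 0)
        f <- f + spec$baseline_f0 * rnorm(length(t), sd = spec$noise_sd)
      traces[[i]] <- calcium_trace(t, f, spec$stimulus_time_s,
                                   roi_id = sprintf("roi_%d", i))
    }
    gt <- data.frame(
      roi_id = sprintf("roi_%d", seq_len(n)),
      responder = !nonresp,
      latency_s = ifelse(nonresp, NA_real_, spec$latency_s),
      onset_time_s = ifelse(nonresp, NA_real_, onset),
      rise_time_10_90_s = ifelse(nonresp, NA_real_,
                                 RISE_10_90_FACTOR * spec$rise_duration_s),
      peak_amplitude = ifelse(nonresp, NA_real_, amp),
      decay_tau_s = ifelse(nonresp, NA_real_, spec$decay_tau_s),
      plateau_ratio = ifelse(nonresp, NA_real_, spec$biphasic_plateau_ratio),
      phase = ifelse(nonresp, "none",
                     ifelse(spec$biphasic_plateau_ratio > 0,
                            "biphasic", "monophasic")))
    attr(gt, "spec") <- spec
    list(traces = traces, ground_truth = gt)
  })
}

#' Write / read calcium traces as wide CSV
#'
#' The wide format has a `time_s` column followed by one column per ROI.
#'
#' @param traces list of [calcium_trace()] sharing a time base.
#' @param path output CSV path.
#' @param ground_truth optional data frame written to `<path>_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_trace_set <- function(traces, path, ground_truth = NULL) {
  tt <- traces[[1]]$time_s
  df <- data.frame(time_s = tt)
  for (tr in traces) {
    stopifnot(identical(tr$time_s, tt))
    df[[tr$roi_id]] <- tr$f
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(ground_truth))
    utils::write.csv(ground_truth,
                     paste0(tools::file_path_sans_ext(path), "_truth.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_set
#' @param stimulus_time_s agonist application time for all ROIs in the file.
#' @param metadata optional named list attached to every trace.
#' @export
read_trace_set <- function(path, stimulus_time_s = 20, metadata = list()) {
  if (!file.exists(path))
    stop_aq(sprintf("input trace file not found: %s", path), "missing_input")
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop_aq("trace CSV must contain a 'time_s' column", "invalid_spec")
  rois <- setdiff(names(df), "time_s")
  lapply(rois, function(id)
    calcium_trace(df$time_s, df[[id]], stimulus_time_s, roi_id = id,
                  metadata = metadata))
}
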