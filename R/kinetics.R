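## Decomposition of ATP-evoked Ca2+ transients.
##
## The feature chain is: normalize to the pre-stimulus baseline (F/F0),
## zero-phase low-pass filter, detect the transient onset against baseline
## statistics, then measure 10-90% rise time, area under the curve, the
## exponential decay time constant tau (f(t) = a * exp(-t/tau) fitted from
## the peak to the end of the experiment, 300 s, shrinking the window where
## the normalized fit error reaches 10%), and classify the waveform as
## monophasic or biphasic by whether the decay sustains a response at or
## above half of the peak amplitude.

#' Normalize a fluorescence trace to its pre-stimulus baseline
#'
#' `F/F0` normalization: each sample is divided by the mean fluorescence
#' over the baseline window (0-20 s by default, before agonist addition),
#' cancelling the arbitrary gain of the recording.
#'
#' @param trace a [calcium_trace()].
#' @param baseline_window length-2 numeric, the baseline time window in
#'   seconds; defaults to `c(0, stimulus_time_s)`.
#' @return an object of class `normalized_trace`: `time_s`, `f_over_f0`,
#'   `f0`, plus the trace's stimulus time, ROI id and metadata.
#' @export
normalize_f_f0 <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(baseline_window))
    baseline_window <- c(trace$time_s[1], trace$stimulus_time_s)
  inb <- trace$time_s >= baseline_window[1] & trace$time_s <= baseline_window[2]
  if (sum(inb) < 2L)
    stop_aq("need >= 2 samples in the baseline window", "normalization_error")
  f0 <- mean(trace$f[inb])
  if (!is.finite(f0) || f0 <= 0)
    stop_aq("baseline mean must be positive for F/F0 normalization",
            "normalization_error")
  structure(list(time_s = trace$time_s, f_over_f0 = trace$f / f0, f0 = f0,
                 stimulus_time_s = trace$stimulus_time_s,
                 baseline_window = baseline_window,
                 roi_id = trace$roi_id, metadata = trace$metadata,
                 filtered = FALSE),
            class = "normalized_trace")
}

## odd (point-reflection) padding keeps level and slope continuous at the
## ends, so filtfilt startup transients stay out of the data
reflect_pad_filtfilt <- function(flt, x) {
  n <- length(x)
  padlen <- min(n - 1L, 24L)
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase low-pass filter of a normalized trace
#'
#' Second-order Butterworth filter applied forward and backward
#' (zero phase; the effective magnitude response is the square of the
#' single-pass response). Non-uniformly sampled traces are first linearly
#' resampled to their median interval. The DC level is preserved.
#'
#' @param norm a [normalize_f_f0()] result.
#' @param cutoff_hz cutoff frequency in Hz (default 0.2, comfortably above
#'   the tens-of-seconds timescale of astrocytic Ca2+ transients at 1 Hz
#'   sampling); must be below the Nyquist frequency.
#' @return a `normalized_trace` with filtered `f_over_f0` (and a uniform
#'   time base if resampling occurred).
#' @export
lowpass <- function(norm, cutoff_hz = 0.2) {
  stopifnot(inherits(norm, "normalized_trace"))
  check_scalar(cutoff_hz, "cutoff_hz", 0, Inf, allow_equal = FALSE)
  dt <- diff(norm$time_s)
  if (max(dt) - min(dt) > 1e-9 * stats::median(dt)) {
    dtu <- stats::median(dt)
    tt <- seq(norm$time_s[1], norm$time_s[length(norm$time_s)], by = dtu)
    norm$f_over_f0 <- stats::approx(norm$time_s, norm$f_over_f0, xout = tt)$y
    norm$time_s <- tt
    dt <- diff(tt)
  }
  fs <- 1 / dt[1]
  if (cutoff_hz >= fs / 2)
    stop_aq(sprintf("cutoff %.3g Hz is at or above Nyquist (%.3g Hz)",
                    cutoff_hz, fs / 2), "invalid_parameter")
  flt <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  norm$f_over_f0_raw <- norm$f_over_f0
  norm$f_over_f0 <- reflect_pad_filtfilt(flt, norm$f_over_f0)
  norm$filtered <- TRUE
  norm
}

#' Detect whether (and when) a trace responds to the stimulus
#'
#' A trace is a responder when the post-stimulus signal exceeds the baseline
#' mean plus `k` baseline standard deviations (with an absolute floor
#' `min_delta` guarding the noiseless limit) for at least `m` consecutive
#' samples. The baseline SD is taken from the unfiltered baseline samples:
#' they are uncorrelated, so the estimate is stable with a short baseline,
#' and a threshold in raw-noise units stays conservative on the smoothed
#' trace, whose autocorrelated noise would otherwise produce frequent
#' spurious multi-sample excursions. The onset is the threshold crossing
#' immediately preceding the excursion, linearly interpolated between
#' samples.
#'
#' @param norm a filtered `normalized_trace`.
#' @param k baseline-SD multiplier (default 3).
#' @param m required consecutive supra-threshold samples (default 3).
#' @param min_delta absolute minimum excursion above baseline in `F/F0`
#'   units (default 0.01).
#' @return list with `responder` (logical) and `onset_time_s` (`NA` for
#'   non-responders), plus the `threshold` used.
#' @export
detect_response <- function(norm, k = 3, m = 3L, min_delta = 0.01) {
  stopifnot(inherits(norm, "normalized_trace"))
  inb <- norm$time_s >= norm$baseline_window[1] &
         norm$time_s <= norm$baseline_window[2]
  bmean <- mean(norm$f_over_f0[inb])
  bsd <- if (!is.null(norm$f_over_f0_raw)) stats::sd(norm$f_over_f0_raw[inb])
         else stats::sd(norm$f_over_f0[inb])
  thr <- bmean + max(k * bsd, min_delta)
  post <- which(norm$time_s > norm$stimulus_time_s)
  above <- norm$f_over_f0[post] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= m)
  if (!length(hit))
    return(list(responder = FALSE, onset_time_s = NA_real_, threshold = thr))
  first <- post[ends[hit[1]] - r$lengths[hit[1]] + 1L]
  onset <- norm$time_s[first]
  if (first > 1L && norm$f_over_f0[first - 1L] < thr) {
    f0v <- norm$f_over_f0[first - 1L]; f1v <- norm$f_over_f0[first]
    onset <- norm$time_s[first - 1L] +
      (thr - f0v) / (f1v - f0v) * (norm$time_s[first] - norm$time_s[first - 1L])
  }
  list(responder = TRUE, onset_time_s = onset, threshold = thr)
}

## first time the trace crosses `level` upward at or after index `from`,
## linearly interpolated between samples
first_crossing <- function(tt, ff, level, from = 1L) {
  n <- length(ff)
  for (i in seq(from, n)) {
    if (ff[i] >= level) {
      if (i == 1L || ff[i - 1] >= level) return(tt[i])
      return(tt[i - 1] + (level - ff[i - 1]) / (ff[i] - ff[i - 1]) *
               (tt[i] - tt[i - 1]))
    }
  }
  NA_real_
}

#' 10-90% rise time of a transient
#'
#' Time between the first crossings of 10% and 90% of the peak amplitude
#' (peak minus baseline level, with the baseline at `F/F0 = 1` by
#' construction), crossings linearly interpolated between samples.
#'
#' @param norm a filtered `normalized_trace`.
#' @param onset_time_s onset from [detect_response()].
#' @return list with `rise_time_s`, `t10_s`, `t90_s`, `peak_time_s`,
#'   `peak_amplitude` (peak `F/F0 - 1`).
#' @export
rise_time <- function(norm, onset_time_s) {
  stopifnot(inherits(norm, "normalized_trace"))
  if (is.na(onset_time_s))
    stop_aq("rise time undefined for a non-responder", "undefined_feature")
  after <- which(norm$time_s >= onset_time_s)
  ipk <- after[which.max(norm$f_over_f0[after])]
  peak <- norm$f_over_f0[ipk]
  amp <- peak - 1
  if (amp <= 0)
    stop_aq("no positive peak after onset", "undefined_feature")
  i0 <- after[1]
  t10 <- first_crossing(norm$time_s, norm$f_over_f0, 1 + 0.1 * amp, i0)
  t90 <- first_crossing(norm$time_s, norm$f_over_f0, 1 + 0.9 * amp, i0)
  list(rise_time_s = t90 - t10, t10_s = t10, t90_s = t90,
       peak_time_s = norm$time_s[ipk], peak_amplitude = amp)
}

fit_exponential <- function(tp, y, tau_bound) {
  pos <- y > 1e-9
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ tp[pos])
    tau0 <- -1 / unname(coef(lf)[2]); a0 <- exp(unname(coef(lf)[1]))
  } else { tau0 <- NA; a0 <- NA }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(diff(range(tp)) / 2, 1)
  if (!is.finite(a0) || a0 <= 0) a0 <- max(y[1], 1e-3)
  tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-tp / tau),
                      start = list(a = a0, tau = min(tau0, tau_bound)),
                      lower = c(1e-9, 1e-6), upper = c(Inf, 10 * tau_bound),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

#' Fit the exponential decay of a transient
#'
#' Fits `f(t) = a * exp(-t/tau)` to the baseline-subtracted signal from the
#' peak to the end of the experiment. The end is taken at
#' `t_end_max` (300 s) or earlier where the normalized fit error (RMSE of
#' the fit divided by peak amplitude) reaches `error_max` (10%): the window
#' is shrunk until the error stays below the limit.
#'
#' @param norm a filtered `normalized_trace`.
#' @param peak_time_s peak time from [rise_time()].
#' @param t_end_max latest end of the fit window in seconds (default 300).
#' @param error_max maximum normalized RMSE (default 0.1).
#' @param tau_bound tau values beyond this (default 1e4 s) are treated as a
#'   non-decaying tail and flagged as a fit failure.
#' @return list with `a`, `tau_s`, `fit_error` (normalized RMSE),
#'   `t_end_s`, and `fit_ok`; on failure `tau_s` is `NA` and `fit_ok` is
#'   `FALSE`.
#' @export
fit_decay <- function(norm, peak_time_s, t_end_max = 300, error_max = 0.1,
                      tau_bound = 1e4) {
  stopifnot(inherits(norm, "normalized_trace"))
  if (is.na(peak_time_s))
    stop_aq("decay fit undefined for a non-responder", "undefined_feature")
  sel <- which(norm$time_s >= peak_time_s &
               norm$time_s <= min(t_end_max, max(norm$time_s)))
  if (length(sel) < 5L)
    stop_aq("need >= 5 samples after the peak", "undefined_feature")
  tp <- norm$time_s[sel] - peak_time_s
  y <- norm$f_over_f0[sel] - 1
  amp <- y[1]
  if (amp <= 0)
    stop_aq("peak amplitude must be positive", "undefined_feature")
  ## shrink the window from the full experiment until the error is < max
  n <- length(sel)
  ends <- unique(round(seq(n, 5L, length.out = min(n - 4L, 40L))))
  for (ne in ends) {
    fit <- fit_exponential(tp[1:ne], y[1:ne], tau_bound)
    if (is.null(fit)) next
    cf <- coef(fit)
    err <- sqrt(mean(residuals(fit)^2)) / amp
    if (err < error_max) {
      if (cf[["tau"]] > tau_bound)
        return(list(a = cf[["a"]], tau_s = NA_real_, fit_error = err,
                    t_end_s = peak_time_s + tp[ne], fit_ok = FALSE))
      return(list(a = cf[["a"]], tau_s = cf[["tau"]], fit_error = err,
                  t_end_s = peak_time_s + tp[ne], fit_ok = TRUE))
    }
  }
  list(a = NA_real_, tau_s = NA_real_, fit_error = NA_real_,
       t_end_s = peak_time_s + tp[n], fit_ok = FALSE)
}

#' Area under the transient curve
#'
#' Trapezoidal integral of the baseline-subtracted signal
#' (`F/F0 - 1`, clipped below at 0) between onset and `t_end_s`, with the
#' integration bounds interpolated exactly.
#'
#' @param norm a filtered `normalized_trace`.
#' @param onset_time_s,t_end_s integration bounds in seconds.
#' @return the area in `F/F0 * s` (arbitrary units).
#' @export
compute_auc <- function(norm, onset_time_s, t_end_s) {
  stopifnot(inherits(norm, "normalized_trace"))
  if (is.na(onset_time_s))
    stop_aq("AUC undefined for a non-responder", "undefined_feature")
  t_end_s <- min(t_end_s, max(norm$time_s))
  inside <- norm$time_s > onset_time_s & norm$time_s < t_end_s
  tt <- c(onset_time_s, norm$time_s[inside], t_end_s)
  yy <- c(stats::approx(norm$time_s, norm$f_over_f0, onset_time_s)$y,
          norm$f_over_f0[inside],
          stats::approx(norm$time_s, norm$f_over_f0, t_end_s)$y)
  yy <- pmax(yy - 1, 0)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Classify a transient as monophasic or biphasic
#'
#' A response is biphasic when, after the decay first reaches half of the
#' peak amplitude, the signal remains at or re-rises to at least
#' half-amplitude for a sustained duration of `d_sustain` seconds or more
#' (a decay that never reaches half-amplitude within the analysis window is
#' itself a sustained response). Otherwise it is monophasic.
#'
#' @param norm a filtered `normalized_trace`.
#' @param peak_time_s,peak_amplitude peak location and amplitude from
#'   [rise_time()].
#' @param d_sustain minimum sustained duration in seconds (default 20).
#' @param t_end_max end of the analysis window (default 300 s).
#' @return `"monophasic"` or `"biphasic"`.
#' @export
classify_phase <- function(norm, peak_time_s, peak_amplitude,
                           d_sustain = 20, t_end_max = 300) {
  stopifnot(inherits(norm, "normalized_trace"))
  if (is.na(peak_time_s))
    stop_aq("phase undefined for a non-responder", "undefined_feature")
  half <- 1 + 0.5 * peak_amplitude
  sel <- which(norm$time_s >= peak_time_s &
               norm$time_s <= min(t_end_max, max(norm$time_s)))
  tt <- norm$time_s[sel]; ff <- norm$f_over_f0[sel]
  below <- which(ff < half)
  if (!length(below))   # never decays to half: sustained by itself
    return(if (tt[length(tt)] - tt[1] >= d_sustain) "biphasic" else "monophasic")
  i0 <- below[1]
  if (i0 >= length(ff)) return("monophasic")
  at <- ff[i0:length(ff)] >= half
  ta <- tt[i0:length(ff)]
  r <- rle(at)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values))
    if (ta[ends[j]] - ta[starts[j]] >= d_sustain) return("biphasic")
  "monophasic"
}

#' Extract all kinetic features from one trace
#'
#' Runs the full chain normalize -> low-pass -> onset detection -> rise
#' time -> AUC -> decay fit -> phase classification. Non-responders
#' short-circuit with phase `"none"` and `NA` kinetic fields; errors are
#' captured in the `error` field so a batch never aborts.
#'
#' @param trace a [calcium_trace()].
#' @param cutoff_hz low-pass cutoff, see [lowpass()].
#' @param k,m,min_delta onset criterion, see [detect_response()].
#' @param d_sustain biphasic rule, see [classify_phase()].
#' @param t_end_max,error_max,tau_bound decay fit window rule, see
#'   [fit_decay()].
#' @param baseline_window baseline window, see [normalize_f_f0()].
#' @return an object of class `transient_features` (also a one-row list
#'   convertible with `as.data.frame()`): `roi_id`, `responder`,
#'   `latency_s`, `onset_time_s`, `rise_time_s`, `peak_amplitude`,
#'   `peak_time_s`, `auc`, `decay_a`, `decay_tau_s`, `fit_error`,
#'   `t_end_s`, `phase`, `f0`, `error`, plus any scalar metadata fields of
#'   the trace.
#' @export
extract_features <- function(trace, cutoff_hz = 0.2, k = 3, m = 3L,
                             min_delta = 0.01, d_sustain = 20,
                             t_end_max = 300, error_max = 0.1,
                             tau_bound = 1e4, baseline_window = NULL) {
  out <- list(roi_id = if (inherits(trace, "calcium_trace")) trace$roi_id
                       else NA_character_,
              responder = NA, latency_s = NA_real_, onset_time_s = NA_real_,
              rise_time_s = NA_real_, peak_amplitude = NA_real_,
              peak_time_s = NA_real_, auc = NA_real_, decay_a = NA_real_,
              decay_tau_s = NA_real_, fit_error = NA_real_,
              t_end_s = NA_real_, phase = NA_character_, f0 = NA_real_,
              error = NA_character_)
  res <- tryCatch({
    norm <- normalize_f_f0(trace, baseline_window)
    if (anyNA(norm$f_over_f0))
      stop_aq("trace contains missing samples", "corrupt_trace")
    norm <- lowpass(norm, cutoff_hz)
    out$f0 <- norm$f0
    det <- detect_response(norm, k = k, m = m, min_delta = min_delta)
    out$responder <- det$responder
    if (!det$responder) {
      out$phase <- "none"
    } else {
      out$onset_time_s <- det$onset_time_s
      out$latency_s <- det$onset_time_s - norm$stimulus_time_s
      rt <- rise_time(norm, det$onset_time_s)
      out$rise_time_s <- rt$rise_time_s
      out$peak_amplitude <- rt$peak_amplitude
      out$peak_time_s <- rt$peak_time_s
      dec <- fit_decay(norm, rt$peak_time_s, t_end_max = t_end_max,
                       error_max = error_max, tau_bound = tau_bound)
      out$decay_a <- dec$a
      out$decay_tau_s <- dec$tau_s
      out$fit_error <- dec$fit_error
      out$t_end_s <- dec$t_end_s
      out$auc <- compute_auc(norm, det$onset_time_s, dec$t_end_s)
      out$phase <- classify_phase(norm, rt$peak_time_s, rt$peak_amplitude,
                                  d_sustain = d_sustain,
                                  t_end_max = t_end_max)
    }
    out
  }, error = function(e) { out$error <- conditionMessage(e); out })
  if (inherits(trace, "calcium_trace"))
    for (nm in names(trace$metadata))
      if (length(trace$metadata[[nm]]) == 1L) res[[nm]] <- trace$metadata[[nm]]
  structure(res, class = "transient_features")
}

#' @export
print.transient_features <- function(x, ...) {
  if (!is.na(x$error)) {
    cat(sprintf("<transient_features> %s: ERROR (%s)\n", x$roi_id, x$error))
  } else if (!isTRUE(x$responder)) {
    cat(sprintf("<transient_features> %s: non-responder\n", x$roi_id))
  } else {
    cat(sprintf(paste0("<transient_features> %s: latency %.2f s, ",
                       "RT %.2f s, peak %.2f, AUC %.1f, tau %.1f s, %s\n"),
                x$roi_id, x$latency_s, x$rise_time_s, x$peak_amplitude,
                x$auc, x$decay_tau_s, x$phase))
  }
  invisible(x)
}

#' @export
as.data.frame.transient_features <- function(x, ...) {
  as.data.frame(lapply(unclass(x), function(v) if (is.null(v)) NA else v),
                stringsAsFactors = FALSE)
}

#' Extract features for a batch of traces
#'
#' @param traces list of [calcium_trace()] objects.
#' @param ... passed to [extract_features()].
#' @return data frame with one row per trace; failed traces carry their
#'   message in the `error` column rather than aborting the batch.
#' @export
extract_features_batch <- function(traces, ...) {
  rows <- lapply(traces, function(tr) as.data.frame(extract_features(tr, ...)))
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  do.call(rbind, rows)
}

#' Group-level response-rate and feature summary
#'
#' @param features data frame from [extract_features_batch()].
#' @param group_cols character vector of grouping columns present in
#'   `features` (e.g. `c("div", "treatment")`); may be empty for a single
#'   pooled group.
#' @return data frame with one row per group: `n`, `n_responders`,
#'   `percent_nonresponsive`, and `mean`/`sem` columns for latency, rise
#'   time, peak amplitude, AUC and decay tau (responders only; SEM is `NA`
#'   for a single observation).
#' @export
summarize_response_rates <- function(features,
                                     group_cols = intersect(
                                       c("div", "treatment"), names(features))) {
  stopifnot(is.data.frame(features))
  ok <- is.na(features$error)
  bad <- sum(!ok)
  if (bad) warning(sprintf("%d trace(s) with errors excluded", bad))
  features <- features[ok, , drop = FALSE]
  if (!nrow(features))
    stop_aq("no analyzable traces", "invalid_spec")
  key <- if (length(group_cols))
    interaction(features[group_cols], drop = TRUE, sep = "/")
  else factor(rep("all", nrow(features)))
  num_feats <- c("latency_s", "rise_time_s", "peak_amplitude", "auc",
                 "decay_tau_s")
  out <- lapply(levels(key), function(g) {
    sub <- features[key == g, , drop = FALSE]
    row <- sub[1, group_cols, drop = FALSE]
    row$n <- nrow(sub)
    row$n_responders <- sum(sub$responder, na.rm = TRUE)
    row$percent_nonresponsive <- 100 * (row$n - row$n_responders) / row$n
    resp <- sub[which(sub$responder), , drop = FALSE]
    for (f in num_feats) {
      v <- resp[[f]][is.finite(resp[[f]])]
      ms <- if (length(v)) mean_sem(v) else list(mean = NA_real_, sem = NA_real_)
      row[[paste0(f, "_mean")]] <- ms$mean
      row[[paste0(f, "_sem")]] <- ms$sem
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
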