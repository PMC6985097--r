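#' Diagnostic plot of a calcium trace
#'
#' Plots the F/F0-normalized (optionally filtered) trace with the stimulus
#' time and, if a [extract_features()] result is supplied, the detected
#' onset, peak, fit window end and the fitted exponential decay.
#'
#' @param x a [calcium_trace()].
#' @param features optional `transient_features` for the same trace.
#' @param cutoff_hz low-pass cutoff for the displayed filtered trace.
#' @param ... passed to [graphics::plot()].
#' @export
plot.calcium_trace <- function(x, features = NULL, cutoff_hz = 0.2, ...) {
  norm <- normalize_f_f0(x)
  filt <- lowpass(norm, cutoff_hz)
  graphics::plot(norm$time_s, norm$f_over_f0, type = "l", col = "grey70",
                 xlab = "time (s)", ylab = "F/F0", main = x$roi_id, ...)
  graphics::lines(filt$time_s, filt$f_over_f0, col = "black")
  graphics::abline(v = x$stimulus_time_s, lty = 2, col = "blue")
  if (!is.null(features) && isTRUE(features$responder)) {
    graphics::abline(v = features$onset_time_s, lty = 3, col = "darkgreen")
    graphics::points(features$peak_time_s, 1 + features$peak_amplitude,
                     pch = 19, col = "red")
    if (is.finite(features$decay_tau_s)) {
      tt <- seq(features$peak_time_s, features$t_end_s, length.out = 100)
      graphics::lines(tt, 1 + features$decay_a *
                        exp(-(tt - features$peak_time_s) / features$decay_tau_s),
                      col = "red", lty = 2)
    }
  }
  invisible(x)
}
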