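#' Otsu threshold of an intensity image
#'
#' Computes the histogram threshold that maximises the between-class variance
#' of the two resulting intensity populations (Otsu's method). Candidate
#' thresholds are the boundaries of `n_bins` equal-width histogram bins
#' spanning the observed intensity range; ties in the between-class variance
#' are broken toward the lower threshold. Pixels strictly above the returned
#' value are foreground.
#'
#' @param channel numeric matrix (or vector) of intensities, all finite.
#' @param n_bins number of histogram bins (default 256).
#' @return a single numeric threshold, strictly inside the intensity range.
#' @examples
#' img <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
#' otsu_threshold(img)
#' @export
otsu_threshold <- function(channel, n_bins = 256L) {
  x <- as.numeric(channel)
  if (length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stop_aq("channel must be non-empty with finite intensities", "invalid_spec")
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop_aq("constant image: no separating threshold exists", "degenerate_image")
  n_bins <- as.integer(n_bins)
  ## bin index in 1..n_bins; right-closed so max lands in the top bin
  idx <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w <- cumsum(counts)                      # class-0 pixel count for cut after bin k
  m <- cumsum(counts * mids)               # class-0 intensity mass
  n <- w[n_bins]; mtot <- m[n_bins]
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- m[k][valid] / w0[valid]
  mu1 <- (mtot - m[k][valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  best <- which.max(bcv)                   # first maximum = lowest threshold
  lo + best * (hi - lo) / n_bins           # upper edge of bin `best`
}
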