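# shared fixture builders: everything is generated in code at test time

# small, fast image spec; the reduced field keeps segmentation quick while
# preserving the blob geometry of the full-size default
small_image_spec <- function(seed = 1L, n_cells = 20L,
                             fractions = 0.5, noise_sd = 0,
                             mean_cell_area_px = 300,
                             area_dispersion_px = 60, ...) {
  image_sim_spec(width_px = 347L, height_px = 260L, pixel_size_um = 0.64,
                 n_cells = n_cells, marker_positive_fraction = fractions,
                 mean_cell_area_px = mean_cell_area_px,
                 area_dispersion_px = area_dispersion_px,
                 noise_sd = noise_sd, seed = seed, ...)
}

# render an image of Gaussian-profile discs directly (independent of the
# package's simulator internals)
disc_image <- function(h, w, cx, cy, r) {
  img <- matrix(0, h, w)
  for (i in seq_along(cx)) {
    s2 <- (r[i] / sqrt(2 * log(2)))^2
    for (row in seq_len(h)) for (col in seq_len(w)) {
      d2 <- (row - cy[i])^2 + (col - cx[i])^2
      if (d2 <= r[i]^2) img[row, col] <- max(img[row, col], exp(-d2 / (2 * s2)))
    }
  }
  img
}

# build a calcium_trace with 1 Hz sampling from a normalized shape vector
trace_from_f <- function(f, stimulus_time_s = 20, f0 = 1) {
  calcium_trace(seq_along(f) - 1, f * f0, stimulus_time_s)
}

# brute-force Otsu oracle: naive between-class variance over every cut of
# the same 256-bin histogram, computed with plain means
otsu_brute_force <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  idx <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  v <- mids[idx]
  best_k <- NA_integer_; best_var <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    g0 <- v[idx <= k]; g1 <- v[idx > k]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (bcv > best_var + 1e-15) { best_var <- bcv; best_k <- k }
  }
  lo + best_k * (hi - lo) / n_bins
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
mw_enumerate_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  r <- rank(pooled)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  lower <- mean(us <= u_obs); upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}
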