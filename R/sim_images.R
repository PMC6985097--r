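## Synthetic micrograph generator.
##
## Cells are rendered as Gaussian-profile discs: intensity exp(-d^2 / 2s^2)
## inside radius r, exactly 0 outside, with s chosen so the profile equals
## 0.5 at the rim. The footprint (d <= r) therefore has a controllable pixel
## area and a soft interior gradient while keeping a crisp, recoverable
## boundary: on a clean image every foreground pixel is >= 0.5 x background
## separation, so histogram thresholding recovers the footprint exactly.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483629))
  eval.parent(substitute(expr))
}

#' Specification for a synthetic multichannel micrograph
#'
#' Describes one simulated field of view: image geometry, number of cells,
#' which fraction of them expresses each marker, the tendency of the two
#' markers to be co-expressed by the same cells, cell size statistics, and
#' the corruption applied last (uneven illumination and detector noise).
#'
#' @param width_px,height_px image size in pixels (defaults match a x20
#'   widefield acquisition, 1388 x 1040).
#' @param pixel_size_um physical pixel size in micrometres (> 0). Default
#'   0.32 um/px, a typical value for a x20 objective on a standard camera.
#' @param n_cells number of cells in the field (>= 0).
#' @param marker_positive_fraction numeric vector of length 1 or 2: the
#'   fraction of cells expressing each marker, each in \[0, 1\]. The realized
#'   positive count is exactly `round(fraction * n_cells)`.
#' @param coexpression_pcc_target target correlation in \[-1, 1\] between the
#'   two markers' cell-membership indicators (ignored for a single marker).
#'   Achieved through a latent bivariate Bernoulli assignment; the realized
#'   value is reported in the ground truth rather than guaranteed exactly.
#' @param mean_cell_area_px,area_dispersion_px mean and standard deviation
#'   (both > 0) of the per-cell marker footprint area, drawn from a Gamma
#'   distribution. Nuclei get one quarter of the cell area.
#' @param illumination_gradient_amplitude amplitude (>= 0) of a multiplicative
#'   left-to-right linear illumination ramp `1 + a * (2x/width - 1)`, clipped
#'   at zero.
#' @param background_level ambient background intensity (stray light plus
#'   camera offset) added before the gradient is applied; the gradient only
#'   becomes visible in empty regions through this term.
#' @param noise_sd standard deviation (>= 0) of additive per-pixel Gaussian
#'   noise, on the \[0, 1\] intensity scale; applied last, then clipped at 0.
#' @param seed integer; makes the output reproducible bit for bit.
#' @return an object of class `image_sim_spec`.
#' @seealso [generate_micrograph()]
#' @export
image_sim_spec <- function(width_px = 1388L, height_px = 1040L,
                           pixel_size_um = 0.32, n_cells = 150L,
                           marker_positive_fraction = 0.5,
                           coexpression_pcc_target = 0,
                           mean_cell_area_px = 600,
                           area_dispersion_px = 150,
                           illumination_gradient_amplitude = 0,
                           background_level = 0.02,
                           noise_sd = 0, seed = 1L) {
  check_scalar(width_px, "width_px", 8, Inf, integer = TRUE)
  check_scalar(height_px, "height_px", 8, Inf, integer = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", 0, Inf, allow_equal = FALSE)
  check_scalar(n_cells, "n_cells", 0, Inf, integer = TRUE)
  if (!is.numeric(marker_positive_fraction) ||
      !length(marker_positive_fraction) %in% 1:2 ||
      any(marker_positive_fraction < 0 | marker_positive_fraction > 1))
    stop_aq("marker_positive_fraction must be 1 or 2 values in [0, 1]",
            "invalid_spec")
  check_scalar(coexpression_pcc_target, "coexpression_pcc_target", -1, 1)
  check_scalar(mean_cell_area_px, "mean_cell_area_px", 0, Inf, allow_equal = FALSE)
  check_scalar(area_dispersion_px, "area_dispersion_px", 0, Inf, allow_equal = FALSE)
  check_scalar(illumination_gradient_amplitude, "illumination_gradient_amplitude", 0, Inf)
  check_scalar(background_level, "background_level", 0, Inf)
  check_scalar(noise_sd, "noise_sd", 0, Inf)
  check_scalar(seed, "seed", -Inf, Inf, integer = TRUE)
  if (n_cells == 0 && any(marker_positive_fraction > 0))
    stop_aq("n_cells = 0 is inconsistent with a positive marker fraction",
            "invalid_spec")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 marker_positive_fraction = marker_positive_fraction,
                 coexpression_pcc_target = coexpression_pcc_target,
                 mean_cell_area_px = mean_cell_area_px,
                 area_dispersion_px = area_dispersion_px,
                 illumination_gradient_amplitude = illumination_gradient_amplitude,
                 background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_sim_spec")
}

#' Multichannel micrograph container
#'
#' @param channels named list of numeric matrices with identical dimensions
#'   and non-negative intensities; roles are `nuclei`, `marker_1`, and
#'   optionally `marker_2`.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param metadata optional named list (DIV timepoint, marker names,
#'   replicate id, ...).
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(channels, pixel_size_um, metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) || !length(channels))
    stop_aq("channels must be a non-empty named list", "invalid_spec")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_aq("all channels must be matrices of identical dimensions", "invalid_spec")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop_aq("channel intensities must be non-negative", "invalid_spec")
  check_scalar(pixel_size_um, "pixel_size_um", 0, Inf, allow_equal = FALSE)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 metadata = metadata), class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<micrograph> %d x %d px (%.3g um/px), channels: %s\n",
              d[2], d[1], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

## Draw blob radii, place centres so nuclei stay disjoint.
place_cells <- function(n, r_nuc, r_cell, w, h) {
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    margin <- r_cell[i] + 2
    if (2 * margin >= w || 2 * margin >= h)
      stop_aq("cell larger than field: reduce mean_cell_area_px", "invalid_spec")
    ok <- FALSE
    for (try in seq_len(5000L)) {
      x <- runif(1, margin, w - margin); y <- runif(1, margin, h - margin)
      if (i == 1L) { ok <- TRUE }
      else {
        j <- seq_len(i - 1L)
        ok <- all((cx[j] - x)^2 + (cy[j] - y)^2 >
                    (r_nuc[j] + r_nuc[i] + 3)^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok)
      stop_aq("could not place cells without overlap: field too dense",
              "invalid_spec")
  }
  cbind(x = cx, y = cy)
}

## Render Gaussian-profile discs into an h x w matrix; returns the image and
## per-blob footprint pixel counts. Overlaps combine by per-pixel maximum.
render_blobs <- function(h, w, cx, cy, r) {
  img <- matrix(0, h, w)
  area <- integer(length(cx))
  for (i in seq_along(cx)) {
    s2 <- (r[i] / sqrt(2 * log(2)))^2      # rim value exp(-r^2/2s^2) = 0.5
    c0 <- ceiling(max(1, cx[i] - r[i])); c1 <- floor(min(w, cx[i] + r[i]))
    r0 <- ceiling(max(1, cy[i] - r[i])); r1 <- floor(min(h, cy[i] + r[i]))
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows - cy[i])^2, (cols - cx[i])^2, "+")
    inside <- d2 <= r[i]^2
    prof <- ifelse(inside, exp(-d2 / (2 * s2)), 0)
    img[rows, cols] <- pmax(img[rows, cols], prof)
    area[i] <- sum(inside)
  }
  list(img = img, area_px = area)
}

## Latent bivariate Bernoulli marker assignment hitting exact marginal counts
## and approaching the requested membership correlation (phi coefficient).
assign_markers <- function(n, fractions, rho) {
  k <- round(fractions * n)
  m <- matrix(FALSE, n, length(fractions))
  if (length(fractions) == 1L) {
    m[sample.int(n, k[1]), 1] <- TRUE
    return(m)
  }
  p1 <- k[1] / n; p2 <- k[2] / n
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- if (denom > 0) p1 * p2 + rho * denom else p1 * p2
  n11 <- round(p11 * n)
  n11 <- max(max(0L, k[1] + k[2] - n), min(n11, min(k)))
  ord <- sample.int(n)                    # random cell order
  both <- ord[seq_len(n11)]
  only1 <- ord[seq_len(k[1] - n11) + n11]
  only2 <- ord[seq_len(k[2] - n11) + k[1]]
  m[c(both, only1), 1] <- TRUE
  m[c(both, only2), 2] <- TRUE
  m
}

#' Simulate a ground-truthed multichannel micrograph
#'
#' Generates a nuclei channel plus one or two marker channels according to an
#' [image_sim_spec()]: cells are placed without nuclear overlap, a marker
#' channel lights exactly `round(fraction * n_cells)` cells, and pairwise
#' marker co-expression is sampled toward the requested correlation. A
#' multiplicative illumination gradient and additive Gaussian noise are
#' applied last; the ground truth records the true labels and footprint
#' areas before this corruption.
#'
#' @param spec an [image_sim_spec()].
#' @return a list with components:
#'   \describe{
#'     \item{micrograph}{a [micrograph()] with channels `nuclei`, `marker_1`
#'       and (if two fractions were given) `marker_2`.}
#'     \item{ground_truth}{data frame with one row per cell: centroid
#'       (`x`, `y`, 1-based pixel coordinates), `nucleus_area_px`,
#'       `cell_area_px`, and logical `marker_1`/`marker_2` membership.
#'       Attributes: `marker_area_px` (true per-channel union footprint in
#'       pixels), `realized_coexpression_pcc`, and the generating `spec`.}
#'   }
#' @examples
#' sim <- generate_micrograph(image_sim_spec(
#'   width_px = 256, height_px = 256, n_cells = 12,
#'   mean_cell_area_px = 300, area_dispersion_px = 60, seed = 7))
#' sum(sim$ground_truth$marker_1)   # exactly round(0.5 * 12) = 6
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  n_markers <- length(spec$marker_positive_fraction)
  w <- spec$width_px; h <- spec$height_px; n <- spec$n_cells
  with_seed(spec$seed, {
    sh <- (spec$mean_cell_area_px / spec$area_dispersion_px)^2
    sc <- spec$area_dispersion_px^2 / spec$mean_cell_area_px
    cell_area <- if (n) rgamma(n, shape = sh, scale = sc) else numeric(0)
    cell_area <- pmax(cell_area, 20)       # floor: keep blobs resolvable
    r_cell <- sqrt(cell_area / pi)
    r_nuc <- r_cell / 2                    # nuclei take 1/4 of the cell area
    pos <- place_cells(n, r_nuc, r_cell, w, h)
    membership <- assign_markers(n, spec$marker_positive_fraction,
                                 spec$coexpression_pcc_target)
    nuc <- render_blobs(h, w, pos[, 1], pos[, 2], r_nuc)
    channels <- list(nuclei = nuc$img)
    marker_area_total <- integer(n_markers)
    cell_area_px <- integer(n)
    for (ch in seq_len(n_markers)) {
      sel <- which(membership[, ch])
      mk <- render_blobs(h, w, pos[sel, 1], pos[sel, 2], r_cell[sel])
      channels[[paste0("marker_", ch)]] <- mk$img
      marker_area_total[ch] <- sum(mk$img > 0)
      cell_area_px[sel] <- mk$area_px
    }
    realized_pcc <- NA_real_
    if (n_markers == 2L && n >= 2L &&
        stats::sd(membership[, 1]) > 0 && stats::sd(membership[, 2]) > 0)
      realized_pcc <- cor(membership[, 1], membership[, 2])
    ## corruption: ambient background, illumination ramp, detector noise
    grad <- 1 + spec$illumination_gradient_amplitude *
      (2 * (seq_len(w) - 1) / (w - 1) - 1)
    grad <- pmax(grad, 0)
    gmat <- matrix(grad, h, w, byrow = TRUE)
    channels <- lapply(channels, function(img) {
      img <- (img + spec$background_level) * gmat
      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
      pmax(img, 0)
    })
    gt <- data.frame(cell_id = seq_len(n),
                     x = if (n) pos[, 1] else numeric(0),
                     y = if (n) pos[, 2] else numeric(0),
                     nucleus_area_px = nuc$area_px,
                     cell_area_px = cell_area_px)
    for (ch in seq_len(n_markers))
      gt[[paste0("marker_", ch)]] <- membership[, ch]
    attr(gt, "marker_area_px") <- marker_area_total
    attr(gt, "realized_coexpression_pcc") <- realized_pcc
    attr(gt, "spec") <- spec
    list(micrograph = micrograph(channels, spec$pixel_size_um,
                                 metadata = list(seed = spec$seed)),
         ground_truth = gt)
  })
}

#' Write / read a micrograph as a multi-page TIFF
#'
#' One page per channel, in the order of `names(x$channels)`; intensities are
#' clipped to \[0, 1\] and stored as 16-bit. The channel-role order is
#' restored from `roles` on reading.
#'
#' @param x a [micrograph()].
#' @param path output TIFF path.
#' @param ground_truth optional ground-truth data frame, written as CSV next
#'   to the image (`<path>_truth.csv`).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(x, path, ground_truth = NULL) {
  stopifnot(inherits(x, "micrograph"))
  pages <- lapply(x$channels, function(ch) pmin(pmax(ch, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (!is.null(ground_truth))
    utils::write.csv(ground_truth,
                     paste0(tools::file_path_sans_ext(path), "_truth.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_micrograph
#' @param roles character vector naming each TIFF page's channel role, e.g.
#'   `c("nuclei", "marker_1")`.
#' @param pixel_size_um physical pixel size of the stored image.
#' @export
read_micrograph <- function(path, roles, pixel_size_um) {
  if (!file.exists(path))
    stop_aq(sprintf("input image not found: %s", path), "missing_input")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (length(roles) != length(pages))
    stop_aq("number of roles must match number of TIFF pages", "invalid_spec")
  names(pages) <- roles
  micrograph(pages, pixel_size_um, metadata = list(source = path))
}
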