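## Thresholding with Pearson-correlation quality control.
##
## The QC loop mirrors routine practice for immunofluorescence
## quantification: threshold with Otsu, overlay the raw channel on the
## binary mask, and accept the mask only if the Pearson correlation between
## the two is at least 0.8. A failing image is re-thresholded after
## rolling-ball-style background subtraction (grayscale opening); if that
## still fails, the threshold is swept over the corrected histogram and the
## mask maximising the QC correlation is kept.

#' Threshold a channel with Pearson-correlation quality control
#'
#' @param channel numeric intensity matrix.
#' @param exclusion_mask optional logical matrix marking debris/artifact
#'   pixels to drop from both the mask and the QC correlation.
#' @param qc_min minimum acceptable raw-vs-mask Pearson correlation
#'   (default 0.8).
#' @param background_radius radius in pixels of the structuring disc used
#'   for background subtraction in the fallback pass (default 50).
#' @param n_sweep number of candidate thresholds swept in the final fallback
#'   stage.
#' @return an object of class `segmentation_result`: a list with `mask`
#'   (logical matrix), `threshold`, `qc_pcc`, `qc_passed`
#'   (`qc_pcc >= qc_min`), `fallback_applied`, and `exclusion_mask`.
#' @examples
#' img <- matrix(0, 64, 64); img[20:30, 20:30] <- 1
#' seg <- threshold_with_qc(img)
#' seg$qc_passed
#' @export
threshold_with_qc <- function(channel, exclusion_mask = NULL, qc_min = 0.8,
                              background_radius = 50L, n_sweep = 64L) {
  if (!is.matrix(channel))
    stop_aq("channel must be a matrix", "invalid_spec")
  incl <- if (is.null(exclusion_mask)) rep(TRUE, length(channel))
          else !as.logical(exclusion_mask)
  if (!is.null(exclusion_mask) && length(incl) != length(channel))
    stop_aq("exclusion mask must match channel shape", "invalid_spec")
  if (sum(incl) < 2L)
    stop_aq("fewer than 2 pixels remain after exclusion", "degenerate_image")

  qc_of <- function(raw, mask) {
    tryCatch(pearson_cc(raw, mask * 1, mask = incl),
             astroquant_error = function(e) NA_real_)
  }
  apply_thr <- function(img, thr) {
    m <- img > thr
    m[!incl] <- FALSE
    m
  }

  thr <- otsu_threshold(channel[incl])
  mask <- apply_thr(channel, thr)
  qc <- qc_of(channel, mask)
  fallback <- FALSE

  if (is.na(qc) || qc < qc_min) {
    fallback <- TRUE
    ## rolling-ball-style background removal: grayscale opening estimates
    ## the smooth background, which is subtracted before re-thresholding
    brush <- EBImage::makeBrush(2L * as.integer(background_radius) + 1L, "disc")
    bg <- EBImage::opening(channel, brush)
    corrected <- pmax(channel - bg, 0)
    thr2 <- tryCatch(otsu_threshold(corrected[incl]),
                     astroquant_error = function(e) NA_real_)
    ## after background correction the corrected channel is the image the
    ## threshold is computed from, so it is also the overlay the QC scores
    if (!is.na(thr2)) {
      mask2 <- apply_thr(corrected, thr2)
      qc2 <- qc_of(corrected, mask2)
      if (!is.na(qc2) && (is.na(qc) || qc2 > qc)) {
        thr <- thr2; mask <- mask2; qc <- qc2
      }
    }
    if (is.na(qc) || qc < qc_min) {
      ## last resort: sweep thresholds, keep the mask the QC score prefers
      cand <- stats::quantile(corrected[incl],
                              probs = seq(0.05, 0.995, length.out = n_sweep),
                              names = FALSE)
      for (tc in unique(cand)) {
        mc <- apply_thr(corrected, tc)
        q <- qc_of(corrected, mc)
        if (!is.na(q) && (is.na(qc) || q > qc)) {
          thr <- tc; mask <- mc; qc <- q
        }
      }
    }
  }
  if (is.na(qc))
    stop_aq("quality control undefined: channel or mask constant",
            "degenerate_image")
  structure(list(mask = mask, threshold = thr, qc_pcc = qc,
                 qc_passed = qc >= qc_min, fallback_applied = fallback,
                 exclusion_mask = if (is.null(exclusion_mask)) NULL
                                  else as.logical(exclusion_mask) |>
                                       matrix(nrow(channel), ncol(channel))),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> threshold %.4g, QC PCC %.3f (%s)%s, %d fg px\n",
    x$threshold, x$qc_pcc, if (x$qc_passed) "passed" else "FAILED",
    if (x$fallback_applied) ", fallback applied" else "", sum(x$mask)))
  invisible(x)
}

#' Count nuclei in a counterstained channel
#'
#' Segments the nuclei channel ([threshold_with_qc()]), fills holes, splits
#' touching nuclei by one round of distance-transform watershed, removes
#' components below `min_size_px`, and returns the count with centroids.
#' Residual merges that the watershed does not separate count as one
#' nucleus.
#'
#' @param nuclei_channel numeric matrix (nuclei counterstain).
#' @param exclusion_mask optional logical artifact mask.
#' @param min_size_px minimum component size in pixels (default 30).
#' @param watershed_tolerance minimum object-height separation passed to the
#'   watershed; larger values split less.
#' @param ... passed to [threshold_with_qc()].
#' @return list with `n_nuclei`, `centroids` (matrix with columns `x`, `y`;
#'   1-based pixel coordinates), `labels` (integer label matrix) and
#'   `segmentation` (the [threshold_with_qc()] result).
#' @export
count_nuclei <- function(nuclei_channel, exclusion_mask = NULL,
                         min_size_px = 30L, watershed_tolerance = 1, ...) {
  if (!is.null(exclusion_mask) && all(as.logical(exclusion_mask)))
    return(list(n_nuclei = 0L,
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("x", "y"))),
                labels = matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)),
                segmentation = NULL))
  seg <- threshold_with_qc(nuclei_channel, exclusion_mask = exclusion_mask, ...)
  mask <- EBImage::fillHull(seg$mask * 1)
  if (sum(mask) == 0L)
    return(list(n_nuclei = 0L,
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("x", "y"))),
                labels = matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)),
                segmentation = seg))
  labels <- EBImage::watershed(EBImage::distmap(mask),
                               tolerance = watershed_tolerance)
  labels <- EBImage::imageData(labels)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_size_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  n <- length(keep)
  cent <- matrix(numeric(0), 0, 2)
  if (n > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    cent <- cbind(tapply(idx[, 2], lab, mean),   # x = column
                  tapply(idx[, 1], lab, mean))   # y = row
  }
  colnames(cent) <- c("x", "y")
  list(n_nuclei = n, centroids = cent, labels = labels, segmentation = seg)
}
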