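#' Quantify marker-positive cells and area coverage
#'
#' A cell is marker-positive when a nucleus centroid falls inside a marker
#' mask component of at least `min_component_px` pixels — counting cells
#' anchored to nuclei rather than stain fragments, with the nuclei count as
#' the denominator for the percentage of marker-positive cells.
#'
#' @param marker_seg a [threshold_with_qc()] result for the marker channel.
#' @param nuclei_centroids matrix with columns `x`, `y` (from
#'   [count_nuclei()]).
#' @param pixel_size_um physical pixel size in micrometres, used to convert
#'   the positive-cell count to cells per mm^2.
#' @param min_component_px minimum marker component size in pixels
#'   (default 30).
#' @return an object of class `marker_quantification`: `n_nuclei`,
#'   `n_positive_cells`, `percent_positive_cells`, `percent_area` (marker
#'   mask pixels as a percentage of unexcluded field pixels),
#'   `percent_area_per_avg_cell` (`percent_area / n_positive_cells`, 0 when
#'   no cell is positive), `cells_per_mm2`, and the denominator policy in
#'   `denominator` (`"nuclei"`).
#' @examples
#' img <- matrix(0, 64, 64); img[10:30, 10:30] <- 1
#' seg <- threshold_with_qc(img)
#' quantify_marker(seg, cbind(x = 20, y = 20), pixel_size_um = 0.32)
#' @export
quantify_marker <- function(marker_seg, nuclei_centroids, pixel_size_um,
                            min_component_px = 30L) {
  stopifnot(inherits(marker_seg, "segmentation_result"))
  check_scalar(pixel_size_um, "pixel_size_um", 0, Inf, allow_equal = FALSE)
  n_nuclei <- nrow(nuclei_centroids)
  if (is.null(n_nuclei) || n_nuclei == 0L)
    stop_aq("no nuclei: percentage of positive cells undefined",
            "undefined_percentage")
  mask <- marker_seg$mask
  incl <- if (is.null(marker_seg$exclusion_mask)) rep(TRUE, length(mask))
          else !marker_seg$exclusion_mask
  n_field <- sum(incl)
  labels <- EBImage::bwlabel(mask * 1)
  labels <- EBImage::imageData(labels)
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  big <- which(sizes >= min_component_px)
  ## positive iff the (rounded) centroid pixel carries a large component
  rr <- pmin(pmax(round(nuclei_centroids[, "y"]), 1L), nrow(mask))
  cc <- pmin(pmax(round(nuclei_centroids[, "x"]), 1L), ncol(mask))
  lab_at <- labels[cbind(rr, cc)]
  n_pos <- sum(lab_at %in% big)
  pct_area <- 100 * sum(mask & incl) / n_field
  pct_per_cell <- if (n_pos > 0) pct_area / n_pos else 0
  field_mm2 <- n_field * (pixel_size_um / 1000)^2
  structure(list(n_nuclei = as.integer(n_nuclei),
                 n_positive_cells = as.integer(n_pos),
                 percent_positive_cells = 100 * n_pos / n_nuclei,
                 percent_area = pct_area,
                 percent_area_per_avg_cell = pct_per_cell,
                 cells_per_mm2 = n_pos / field_mm2,
                 denominator = "nuclei"),
            class = "marker_quantification")
}

#' @export
print.marker_quantification <- function(x, ...) {
  cat(sprintf(paste0(
    "<marker_quantification> %d/%d cells positive (%.1f%%), ",
    "%.1f cells/mm2, %.2f%% area (%.3f%% per avg cell)\n"),
    x$n_positive_cells, x$n_nuclei, x$percent_positive_cells,
    x$cells_per_mm2, x$percent_area, x$percent_area_per_avg_cell))
  invisible(x)
}

#' Co-localization of two marker channels
#'
#' Pearson correlation ([pearson_cc()]) over a pixel set chosen by
#' `mask_policy`: `"all"` uses every unexcluded pixel of the field (the
#' default), `"union"` restricts to pixels inside the Otsu mask of either
#' channel, focusing the statistic on stained regions.
#'
#' @param marker_a,marker_b co-registered numeric intensity matrices.
#' @param mask_policy `"all"` or `"union"`.
#' @param exclusion_mask optional logical artifact mask.
#' @param channel_names length-2 character vector naming the pair.
#' @return an object of class `colocalization_result`: `pcc`, `channels`,
#'   `n_pixels`, `mask_policy`.
#' @export
colocalize <- function(marker_a, marker_b, mask_policy = c("all", "union"),
                       exclusion_mask = NULL,
                       channel_names = c("marker_1", "marker_2")) {
  mask_policy <- match.arg(mask_policy)
  if (!identical(dim(marker_a), dim(marker_b)))
    stop_aq("channels must be co-registered (same dimensions)", "invalid_spec")
  incl <- if (is.null(exclusion_mask)) matrix(TRUE, nrow(marker_a), ncol(marker_a))
          else !matrix(as.logical(exclusion_mask), nrow(marker_a), ncol(marker_a))
  sel <- incl
  if (mask_policy == "union") {
    ma <- marker_a > otsu_threshold(marker_a[incl])
    mb <- marker_b > otsu_threshold(marker_b[incl])
    sel <- incl & (ma | mb)
  }
  r <- pearson_cc(marker_a, marker_b, mask = sel)
  structure(list(pcc = r, channels = channel_names,
                 n_pixels = sum(sel), mask_policy = mask_policy),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf("<colocalization_result> %s vs %s: PCC %.3f (%d px, policy %s)\n",
              x$channels[1], x$channels[2], x$pcc, x$n_pixels, x$mask_policy))
  invisible(x)
}

#' Full single-image marker quantification
#'
#' Convenience wrapper running nuclei counting, marker segmentation and
#' quantification, and (when two marker channels are present)
#' co-localization, on one [micrograph()].
#'
#' @param img a [micrograph()] with a `nuclei` channel and `marker_*`
#'   channels.
#' @param exclusion_mask optional logical artifact mask.
#' @param mask_policy co-localization pixel policy, see [colocalize()].
#' @param ... passed to [count_nuclei()] / [threshold_with_qc()].
#' @return list with `nuclei` ([count_nuclei()] output), `markers` (named
#'   list of [quantify_marker()] results), `segmentations`, and `coloc`
#'   (a [colocalize()] result or `NULL`).
#' @export
quantify_micrograph <- function(img, exclusion_mask = NULL,
                                mask_policy = "all", ...) {
  stopifnot(inherits(img, "micrograph"))
  if (!"nuclei" %in% names(img$channels))
    stop_aq("micrograph lacks a 'nuclei' channel", "invalid_spec")
  nuc <- count_nuclei(img$channels$nuclei, exclusion_mask = exclusion_mask, ...)
  marker_names <- grep("^marker_", names(img$channels), value = TRUE)
  segs <- list(); quants <- list()
  for (mn in marker_names) {
    segs[[mn]] <- threshold_with_qc(img$channels[[mn]],
                                    exclusion_mask = exclusion_mask)
    quants[[mn]] <- quantify_marker(segs[[mn]], nuc$centroids,
                                    img$pixel_size_um)
  }
  coloc <- NULL
  if (length(marker_names) >= 2L)
    coloc <- colocalize(img$channels[[marker_names[1]]],
                        img$channels[[marker_names[2]]],
                        mask_policy = mask_policy,
                        exclusion_mask = exclusion_mask,
                        channel_names = marker_names[1:2])
  list(nuclei = nuc, markers = quants, segmentations = segs, coloc = coloc)
}
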