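#' Pearson correlation coefficient between two intensity images
#'
#' Evaluates
#' \deqn{r = \frac{\sum_i (R_i - \bar R)(G_i - \bar G)}
#'                {\sqrt{\sum_i (R_i - \bar R)^2 \sum_i (G_i - \bar G)^2}}}
#' over the (optionally masked) pixel set, the standard co-localization
#' statistic for two fluorescence channels: +1 for perfectly co-expressed
#' markers, -1 for mutually exclusive expression, 0 for no relationship.
#'
#' @param a,b numeric arrays of identical shape.
#' @param mask optional logical array of the same shape; only `TRUE` pixels
#'   enter the sum.
#' @return correlation coefficient in \[-1, 1\].
#' @examples
#' pearson_cc(c(1, 2, 3, 4), c(2, 4, 6, 8))   # 1
#' pearson_cc(c(1, 2, 3, 4), c(1, 3, 2, 4))   # 0.8
#' @export
pearson_cc <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop_aq("channels must have identical shapes", "invalid_spec")
  a <- as.numeric(a); b <- as.numeric(b)
  if (!is.null(mask)) {
    m <- as.logical(mask)
    if (length(m) != length(a))
      stop_aq("mask must match channel shape", "invalid_spec")
    keep <- which(m)
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 2L)
    stop_aq("need at least 2 pixels after masking", "invalid_spec")
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da * da); vb <- sum(db * db)
  if (va == 0 || vb == 0)
    stop_aq("constant input: correlation undefined", "undefined_correlation")
  r <- sum(da * db) / sqrt(va * vb)
  ## guard tiny floating overshoot
  max(-1, min(1, r))
}
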