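#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

## Internal argument checks -------------------------------------------------

stop_aq <- function(msg, class) {
  stop(structure(class = c(class, "astroquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_aq(sprintf("'%s' must be a finite numeric scalar", name), "invalid_spec")
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok)
    stop_aq(sprintf("'%s' = %g is outside [%g, %g]", name, x, lower, upper),
            "invalid_spec")
  if (integer && x != round(x))
    stop_aq(sprintf("'%s' must be an integer", name), "invalid_spec")
  invisible(x)
}

## Seed fan-out: one global seed yields independent per-stage substreams.
## Kept below 2^31 so the result is always a valid R integer seed.
substream_seed <- function(seed, stage, index = 0L) {
  stages <- c(images = 101L, traces = 211L, stats = 307L, pipeline = 401L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 1009 + off * 9973 + index) %% 2147483629)
}

#' Significance stars for an adjusted p-value
#'
#' Maps a p-value to the conventional star annotation:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `"ns"` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
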