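#' Mean and standard error of the mean
#'
#' @param values numeric vector, n >= 1, finite.
#' @return list with `mean`, `sem` (sample SD / sqrt(n); `NA` when n = 1)
#'   and `n`.
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop_aq("values must be a non-empty finite numeric vector", "invalid_spec")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Omnibus one-way ANOVA across the groups, followed by all pairwise
#' two-sided t comparisons using the pooled ANOVA residual variance, with
#' Bonferroni adjustment (raw p multiplied by the number of pairs, capped
#' at 1). Stars are assigned from the adjusted p-values.
#'
#' @param groups named list of numeric vectors, >= 2 groups with >= 2
#'   finite values each.
#' @return an object of class `comparison_result`: `test`, `statistic`
#'   (the omnibus F), `p_value`, `pairwise` (data frame with raw and
#'   adjusted p plus stars), and `stars` for the omnibus test.
#' @examples
#' anova_bonferroni(list(a = c(1, 2, 3), b = c(1.5, 2.5, 2),
#'                       c = c(10, 11, 12)))
#' @export
anova_bonferroni <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_aq("need >= 2 groups", "invalid_spec")
  if (is.null(names(groups)))
    names(groups) <- paste0("group_", seq_along(groups))
  for (g in names(groups)) {
    v <- groups[[g]]
    if (length(v) < 2L || any(!is.finite(v)))
      stop_aq(sprintf("group '%s' needs >= 2 finite values", g), "invalid_spec")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(values ~ labels)
  tab <- stats::anova(fit)
  fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  mse <- tab[["Mean Sq"]][2]
  dfe <- tab[["Df"]][2]
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tstat <- (means[[a]] - means[[b]]) /
      sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    praw <- 2 * stats::pt(-abs(tstat), dfe)
    data.frame(group_a = a, group_b = b, t = tstat, p_raw = praw,
               stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- pmin(pw$p_raw * n_pairs, 1)
  pw$stars <- significance_stars(pw$p_adjusted)
  structure(list(test = "one-way ANOVA + Bonferroni post hoc",
                 statistic = fstat, p_value = p, pairwise = pw,
                 stars = significance_stars(p)),
            class = "comparison_result")
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact null distribution for small samples without ties; normal
#' approximation with tie correction otherwise. Completely tied data (all
#' values identical across both groups) yields p = 1 with a flag.
#'
#' @param group_a,group_b numeric vectors, each n >= 1.
#' @return an object of class `comparison_result`: `test`, `statistic`
#'   (the U statistic for `group_a`), `p_value`, `exact` (logical),
#'   `tied` flag, and `stars`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b) || any(!is.finite(c(a, b))))
    stop_aq("both groups must be non-empty and finite", "invalid_spec")
  if (length(unique(c(a, b))) == 1L) {
    return(structure(list(test = "Mann-Whitney", tied = TRUE,
                          statistic = length(a) * length(b) / 2,
                          p_value = 1, exact = FALSE,
                          stars = significance_stars(1)),
                     class = "comparison_result"))
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- !has_ties && length(a) < 50 && length(b) < 50
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  structure(list(test = "Mann-Whitney", tied = FALSE,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 exact = exact, stars = significance_stars(wt$p.value)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g %s\n",
              x$test, x$statistic, x$p_value, x$stars))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Bonferroni-adjusted):\n")
    for (j in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s vs %s: p = %.4g %s\n",
                  x$pairwise$group_a[j], x$pairwise$group_b[j],
                  x$pairwise$p_adjusted[j], x$pairwise$stars[j]))
  }
  invisible(x)
}

#' Choose and run the appropriate group comparison
#'
#' Applies ANOVA with Bonferroni post hoc for >= 3 groups with per-group
#' n >= 5 that pass a Shapiro-Wilk normality screen (alpha 0.05 on each
#' group), and the Mann-Whitney test otherwise (pairwise for > 2 groups is
#' not attempted; the first two groups are compared). The choice is
#' recorded in the result.
#'
#' @param groups named list of numeric vectors.
#' @param alpha normality-screen significance level.
#' @return a `comparison_result` with an extra `choice_reason` field.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  normal_ok <- function(v) length(v) >= 3 && length(unique(v)) > 1 &&
    stats::shapiro.test(v)$p.value >= alpha
  if (length(groups) >= 3L && all(lengths(groups) >= 5L) &&
      all(vapply(groups, normal_ok, logical(1)))) {
    res <- anova_bonferroni(groups)
    res$choice_reason <- ">=3 groups, n>=5 each, normality screen passed"
  } else {
    res <- mann_whitney(groups[[1]], groups[[2]])
    res$choice_reason <- "small/non-normal or two groups"
  }
  res
}

#' Assemble tidy report tables from pipeline results
#'
#' Builds the group-level summary tables (marker quantification,
#' co-localization, calcium kinetics) with mean +/- SEM, n and significance
#' stars, and writes them as CSV plus a machine-readable JSON summary and a
#' run-metadata log. Absent sections are omitted without error.
#'
#' @param quantifications optional data frame of per-image marker rows
#'   (needs columns `marker`, numeric measurement columns, and grouping
#'   columns such as `div`).
#' @param colocalizations optional data frame with `pcc` and grouping
#'   columns.
#' @param features optional per-ROI feature data frame from
#'   [extract_features_batch()].
#' @param output_dir directory to write into (created if needed); `NULL`
#'   returns the tables without writing.
#' @param group_cols grouping columns to summarize over.
#' @param run_info optional named list recorded in the metadata log
#'   (seed, config, ...).
#' @return named list of data frames (`markers`, `colocalization`,
#'   `kinetics` as available), invisibly when writing.
#' @export
build_report <- function(quantifications = NULL, colocalizations = NULL,
                         features = NULL, output_dir = NULL,
                         group_cols = c("marker", "div", "treatment"),
                         run_info = list()) {
  if (is.null(quantifications) && is.null(colocalizations) && is.null(features))
    stop_aq("at least one input table is required", "invalid_spec")
  summarize_tbl <- function(df, value_cols) {
    gcols <- intersect(group_cols, names(df))
    key <- if (length(gcols)) interaction(df[gcols], drop = TRUE, sep = "/")
           else factor(rep("all", nrow(df)))
    rows <- lapply(levels(key), function(g) {
      sub <- df[key == g, , drop = FALSE]
      row <- sub[1, gcols, drop = FALSE]
      row$n <- nrow(sub)
      for (vc in intersect(value_cols, names(df))) {
        v <- sub[[vc]][is.finite(sub[[vc]])]
        ms <- if (length(v)) mean_sem(v) else list(mean = NA_real_, sem = NA_real_)
        row[[paste0(vc, "_mean")]] <- ms$mean
        row[[paste0(vc, "_sem")]] <- ms$sem
      }
      row
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  }
  out <- list()
  if (!is.null(quantifications))
    out$markers <- summarize_tbl(quantifications,
                                 c("n_positive_cells", "cells_per_mm2",
                                   "percent_positive_cells", "percent_area",
                                   "percent_area_per_avg_cell"))
  if (!is.null(colocalizations))
    out$colocalization <- summarize_tbl(colocalizations, "pcc")
  if (!is.null(features))
    out$kinetics <- summarize_response_rates(
      features, intersect(setdiff(group_cols, "marker"), names(features)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(output_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    meta <- c(list(package = "astroquant",
                   version = as.character(utils::packageVersion("astroquant")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   tables = names(out)),
              run_info)
    jsonlite::write_json(c(meta, list(summary = out)),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
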