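#' Published benchmark metrics for the seven-level cascade
#'
#' Per-level held-out test metrics reported for this cascade design on
#' the Cohen et al. multi-cancer plasma cohort, distributed with the
#' package as a plain-text reference table. Rows cover the
#' majority-voting feature selection at vote thresholds 2, 3 (the
#' deployed setting) and 4, and four metaheuristic feature-selection
#' baselines (EVO, FLA, FOX, RIME) whose selected-feature metric tables
#' the comparison harness consumes as data. All metrics are proportions
#' in \[0, 1\]; `n_selected` is the size of the selected feature panel at
#' that level.
#'
#' These tables are inputs for the aggregation and rank-comparison
#' machinery ([aggregate_levels()], [friedman_ranks()]); the package
#' never asserts their derived summaries as constants.
#'
#' @return A tibble: `method`, `threshold` (NA for the baselines),
#'   `level`, `n_selected`, `acc`, `precision`, `recall`, `f1`,
#'   `specificity`, `ba`, `auc`.
#' @export
#' @examples
#' aggregate_levels(published_level_metrics())
published_benchmarks <- function() {
  path <- system.file("extdata", "benchmark_level_metrics.csv",
                      package = "liquidcascade", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_benchmarks
#' @param threshold Vote threshold of the majority-voting rows to return
#'   (2, 3 or 4; default 3, the deployed setting).
#' @export
published_level_metrics <- function(threshold = 3) {
  b <- published_benchmarks()
  out <- b[b$method == "majority_voting" & b$threshold == threshold, , drop = FALSE]
  if (nrow(out) == 0) stop("no published rows at threshold ", threshold)
  dplyr::arrange(out, .data$level)
}

#' @rdname published_benchmarks
#' @param metric Metric column to pivot into a method-by-level matrix
#'   (`"acc"`, `"f1"` or `"ba"`).
#' @export
published_selector_matrix <- function(metric = "acc") {
  b <- published_benchmarks()
  stopifnot(metric %in% c("acc", "precision", "recall", "f1",
                          "specificity", "ba", "auc"))
  keep <- b$method != "majority_voting" | (!is.na(b$threshold) & b$threshold == 3)
  b <- b[keep, c("method", "level", metric)]
  wide <- tidyr::pivot_wider(b, names_from = "level",
                             values_from = dplyr::all_of(metric))
  m <- as.matrix(wide[setdiff(names(wide), "method")])
  rownames(m) <- wide$method
  m[order(match(rownames(m), c("majority_voting", "evo", "fla", "fox", "rime"))), ,
    drop = FALSE]
}
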