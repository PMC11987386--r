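#' Majority-vote feature selection over six scorers
#'
#' Runs the six selectors — information value, chi-square, random-forest
#' importance, extra-trees importance, recursive feature elimination and
#' L1-penalized linear selection — on a binary-labeled table. The four
#' score-producing methods each keep the top half of features
#' (`floor(N/2)`, ties broken by name) by absolute score; RFE and L1
#' contribute their `floor(N/2)`-feature sets directly. A feature's vote
#' count is the number of methods keeping it, and the selected set is
#' every feature with at least `threshold` votes (default 3, the
#' "three or more" consensus rule).
#'
#' A scorer that fails outright abstains (with a warning naming it),
#' reducing the attainable vote count; if more than two scorers abstain
#' the aggregation errors.
#'
#' @param data Binary-labeled data frame whose `label` column's first
#'   factor level is the positive class.
#' @param label Class column name (default `"class"`).
#' @param features Optional subset of feature columns to score.
#' @param threshold Minimum votes for selection (default 3).
#' @param seed Integer seed for the tree-based scorers.
#' @param n_keep Per-method kept-set size; defaults to `floor(N/2)`
#'   (21 on the 43-feature panel).
#' @return A `vote_tally`: a tibble with one row per feature (six score /
#'   kept-flag columns, `votes`, `selected`), with the threshold, kept-set
#'   size and any abstaining scorers in attributes.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   class_sizes = c(Normal = 60, Colorectum = 40, Breast = 30)), seed = 1)
#' lv <- build_cascade(cohort)[[1]]
#' tally <- vote_select(lv$data, threshold = 3, seed = 1)
#' sum(tally$selected)
vote_select <- function(data, label = "class", features = NULL,
                        threshold = 3, seed = 1, n_keep = NULL) {
  probe <- selector_xy(data, label, features)
  feats <- colnames(probe$x)
  if (length(feats) < 2) stop("need at least 2 features to vote over")
  n_keep <- as.integer(n_keep %||% (length(feats) %/% 2L))
  seeds <- derive_seeds(seed, 2)

  top_half <- function(scores) {
    ord <- order(-abs(scores), names(scores))
    names(scores)[ord][seq_len(n_keep)]
  }
  runs <- list(
    iv = function() top_half(suppressWarnings(
      iv_scores(data, label, features))),
    chi_square = function() top_half(suppressWarnings(
      chi_square_scores(data, label, features))),
    forest = function() top_half(
      forest_importance(data, label, features, seed = seeds[1])),
    extra_trees = function() top_half(
      extra_trees_importance(data, label, features, seed = seeds[2])),
    rfe = function() rfe_select(data, label, features, n_keep = n_keep)$selected,
    l1 = function() suppressWarnings(
      l1_select(data, label, features, n_keep = n_keep)$selected)
  )

  kept <- list()
  abstained <- character(0)
  for (m in names(runs)) {
    res <- tryCatch(runs[[m]](), error = function(e) e)
    if (inherits(res, "error")) {
      warning("scorer '", m, "' abstained: ", conditionMessage(res))
      abstained <- c(abstained, m)
    } else {
      kept[[m]] <- res
    }
  }
  if (length(abstained) > 2) {
    stop("majority vote aborted: ", length(abstained),
         " scorers abstained (", paste(abstained, collapse = ", "), ")")
  }

  tally <- tibble::tibble(feature = feats)
  for (m in names(runs)) {
    tally[[paste0("kept_", m)]] <-
      if (m %in% abstained) NA else feats %in% kept[[m]]
  }
  flag_cols <- paste0("kept_", names(runs))
  tally$votes <- rowSums(as.matrix(tally[flag_cols]), na.rm = TRUE)
  tally$selected <- tally$votes >= threshold
  tally <- dplyr::arrange(tally, dplyr::desc(.data$votes), .data$feature)
  structure(tally,
            class = c("vote_tally", class(tally)),
            threshold = threshold, n_keep = n_keep, abstained = abstained)
}

#' Selected features of a vote tally
#'
#' @param tally A `vote_tally`.
#' @param threshold Optional vote threshold overriding the one stored in
#'   the tally (the selected set weakly shrinks as it rises).
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(tally, threshold = NULL) {
  threshold <- threshold %||% attr(tally, "threshold")
  tally$feature[tally$votes >= threshold]
}

#' @export
print.vote_tally <- function(x, ...) {
  cat("Majority-vote feature tally (threshold ", attr(x, "threshold"),
      ", per-method keep ", attr(x, "n_keep"), "): ",
      sum(x$selected), "/", nrow(x), " features selected\n", sep = "")
  if (length(attr(x, "abstained")) > 0) {
    cat("abstained scorers:", paste(attr(x, "abstained"), collapse = ", "), "\n")
  }
  NextMethod()
}
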