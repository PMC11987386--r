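#' Tie-corrected Mann-Whitney AUC
#'
#' Area under the ROC curve computed as the rank-sum (Mann-Whitney)
#' statistic with average ranks for ties — identical to the trapezoidal
#' area over the empirical ROC curve. Invariant to strictly monotone
#' transformations of the scores; reversing the scores gives 1 - AUC.
#'
#' @param truth Binary factor (first level = positive) or logical vector
#'   of positive-class membership.
#' @param score Numeric scores, larger meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
mann_whitney_auc <- function(truth, score) {
  pos <- if (is.logical(truth)) truth else {
    f <- factor(truth)
    f == levels(f)[1]
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: only one class present in truth")
  }
  r <- rank(score)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metric report for binary predictions
#'
#' Computes the confusion counts and the seven-metric panel: accuracy
#' (TP+TN)/N, precision TP/(TP+FP), recall TP/(TP+FN), F1 (harmonic mean
#' of precision and recall), specificity TN/(TN+FP), balanced accuracy
#' (recall+specificity)/2, false positive rate FP/(FP+TN), and — when
#' scores are supplied — AUC via [mann_whitney_auc()]. A metric whose
#' denominator is zero is reported as `NA` and named in the `undefined`
#' column; it is never silently coerced to 0.
#'
#' @param truth Factor of true classes; the first level is positive.
#' @param estimate Factor of predicted classes on the same levels; if
#'   omitted, thresholding `prob` at 0.5.
#' @param prob Optional positive-class scores in \[0, 1\] for AUC.
#' @param scope Tag recorded in the report (`"fold"`, `"test"`,
#'   `"level"`, `"overall"`).
#' @return A one-row metrics tibble: counts, metrics, `scope`,
#'   `undefined`.
#' @export
#' @examples
#' truth <- factor(c("pos", "pos", "neg", "neg"), levels = c("pos", "neg"))
#' binary_metrics(truth, truth, prob = c(0.9, 0.8, 0.2, 0.4))
binary_metrics <- function(truth, estimate = NULL, prob = NULL, scope = "test") {
  truth <- droplevels_keep(truth)
  pos <- levels(truth)[1]
  neg <- levels(truth)[2]
  if (is.null(estimate)) {
    stopifnot(!is.null(prob))
    estimate <- factor(ifelse(prob >= 0.5, pos, neg), levels = levels(truth))
  }
  stopifnot(length(truth) == length(estimate),
            is.null(prob) || length(prob) == length(truth))

  tp <- sum(truth == pos & estimate == pos)
  fp <- sum(truth == neg & estimate == pos)
  tn <- sum(truth == neg & estimate == neg)
  fn <- sum(truth == pos & estimate == neg)

  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    num / den
  }
  acc <- safe_div(tp + tn, tp + fp + fn + tn, "acc")
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  specificity <- safe_div(tn, tn + fp, "specificity")
  ba <- if (is.na(recall) || is.na(specificity)) {
    undefined <- c(undefined, "ba"); NA_real_
  } else (recall + specificity) / 2
  fpr <- safe_div(fp, fp + tn, "fpr")
  auc <- if (is.null(prob)) NA_real_ else mann_whitney_auc(truth == pos, prob)

  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = acc, precision = precision, recall = recall, f1 = f1,
    specificity = specificity, ba = ba, fpr = fpr, auc = auc,
    scope = scope,
    undefined = if (length(undefined) > 0) paste(unique(undefined), collapse = ",") else ""
  )
}

droplevels_keep <- function(truth) {
  truth <- factor(truth)
  if (nlevels(truth) != 2) stop("truth must carry exactly two class levels")
  truth
}

#' Macro-average metric reports across cascade levels
#'
#' The overall performance of the cascade is the unweighted arithmetic
#' mean of each metric across the per-level reports (macro averaging);
#' sample-weighted averaging is available via `weights`. An undefined
#' (`NA`) metric in any input propagates as undefined, with the
#' offending rows named in `undefined`.
#'
#' @param reports A metrics tibble with one row per level (as produced by
#'   [binary_metrics()] or [published_level_metrics()]).
#' @param weights Optional non-negative per-level weights (e.g. level
#'   sizes) for a weighted mean; default unweighted.
#' @return A one-row metrics tibble with `scope = "overall"`.
#' @export
aggregate_levels <- function(reports, weights = NULL) {
  stopifnot(nrow(reports) >= 1)
  metric_cols <- intersect(
    c("acc", "precision", "recall", "f1", "specificity", "ba", "fpr", "auc"),
    names(reports)
  )
  w <- weights %||% rep(1, nrow(reports))
  stopifnot(length(w) == nrow(reports), all(w >= 0), sum(w) > 0)
  out <- tibble::tibble(.rows = 1)
  undef <- character(0)
  for (m in metric_cols) {
    v <- reports[[m]]
    if (anyNA(v)) {
      undef <- c(undef, paste0(m, "[row ", paste(which(is.na(v)), collapse = ","), "]"))
      out[[m]] <- NA_real_
    } else {
      out[[m]] <- sum(w * v) / sum(w)
    }
  }
  out$scope <- "overall"
  out$undefined <- if (length(undef) > 0) paste(undef, collapse = "; ") else ""
  out
}
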