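#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_hline geom_abline labs theme_minimal facet_wrap coord_flip
NULL

#' Points of the empirical ROC curve
#'
#' False-positive rate against true-positive rate at every score
#' threshold, suitable for plotting or CSV export. The trapezoidal area
#' under these points equals [mann_whitney_auc()].
#'
#' @inheritParams mann_whitney_auc
#' @return A tibble: `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(truth, score) {
  pos <- if (is.logical(truth)) truth else {
    f <- factor(truth)
    f == levels(f)[1]
  }
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  purrr::map_dfr(thr, function(t) {
    call_pos <- score >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(call_pos & !pos) / max(sum(!pos), 1),
      tpr = sum(call_pos & pos) / max(sum(pos), 1)
    )
  })
}

#' Plot an ROC curve
#'
#' @inheritParams mann_whitney_auc
#' @return A ggplot object.
#' @export
plot_roc <- function(truth, score) {
  pts <- roc_points(truth, score)
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f)", mann_whitney_auc(truth, score))) +
    theme_minimal()
}

#' @describeIn vote_select Bar chart of vote counts per feature, with the
#'   selection threshold marked.
#' @param object A `vote_tally`.
#' @param ... Ignored.
#' @method autoplot vote_tally
#' @export
autoplot.vote_tally <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(x = .data$feature, y = .data$votes, fill = .data$selected)) +
    geom_col() +
    geom_hline(yintercept = attr(object, "threshold") - 0.5,
               linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "Votes (of 6 scorers)", fill = "Selected") +
    theme_minimal()
}

#' @describeIn friedman_ranks Dot plot of per-method rank sums.
#' @param object A `friedman_ranks`.
#' @param ... Ignored.
#' @method autoplot friedman_ranks
#' @export
autoplot.friedman_ranks <- function(object, ...) {
  d <- tibble::tibble(method = names(object$rank_sums),
                      rank_sum = unname(object$rank_sums))
  d$method <- factor(d$method, levels = d$method[order(d$rank_sum)])
  ggplot(d, aes(x = .data$method, y = .data$rank_sum)) +
    geom_point(size = 3) +
    coord_flip() +
    labs(x = NULL, y = "Friedman rank sum (higher is better)") +
    theme_minimal()
}

#' Bar chart of per-level metrics
#'
#' @param level_metrics A per-level metrics tibble with a `level` column
#'   (e.g. from [evaluate_cascade()] or [published_level_metrics()]).
#' @param metrics Which metric columns to show.
#' @return A ggplot object.
#' @export
plot_level_metrics <- function(level_metrics,
                               metrics = c("acc", "f1", "ba", "auc")) {
  d <- tidyr::pivot_longer(
    level_metrics[c("level", intersect(metrics, names(level_metrics)))],
    -"level", names_to = "metric", values_to = "value"
  )
  ggplot(d, aes(x = factor(.data$level), y = .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric) +
    labs(x = "Cascade level", y = NULL) +
    theme_minimal()
}
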