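#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a cross-validated level model
#'
#' @param x A `level_cv` from [cv_level()].
#' @param ... Ignored.
#' @return The per-fold metrics tibble, one row per fold.
#' @method tidy level_cv
#' @export
tidy.level_cv <- function(x, ...) {
  dplyr::relocate(x$fold_metrics, "fold")
}

#' One-row summary of a cross-validated level model
#'
#' @param x A `level_cv`.
#' @param ... Ignored.
#' @return A tibble with the cross-fold mean and standard deviation of
#'   each metric, plus the member algorithms and final-model policy.
#' @method glance level_cv
#' @export
glance.level_cv <- function(x, ...) {
  m <- x$fold_metrics
  cols <- c("acc", "precision", "recall", "f1", "specificity", "ba", "auc")
  out <- tibble::tibble(.rows = 1)
  for (cl in cols) {
    out[[paste0(cl, "_mean")]] <- mean(m[[cl]])
    out[[paste0(cl, "_sd")]] <- stats::sd(m[[cl]])
  }
  out$k <- x$k
  out$members <- paste(x$spec$members, collapse = "+")
  out$policy <- x$policy
  out
}

#' Tidy a Friedman rank comparison
#'
#' @param x A `friedman_ranks`.
#' @param ... Ignored.
#' @return A tibble: `method`, `rank_sum`, `mean_rank`.
#' @method tidy friedman_ranks
#' @export
tidy.friedman_ranks <- function(x, ...) {
  tibble::tibble(
    method = names(x$rank_sums),
    rank_sum = unname(x$rank_sums),
    mean_rank = unname(x$rank_sums) / x$n_blocks
  )
}

#' One-row summary of a Friedman rank comparison
#'
#' @param x A `friedman_ranks`.
#' @param ... Ignored.
#' @return A tibble: `statistic`, `df`, `p_value`, `n_methods`,
#'   `n_blocks`.
#' @method glance friedman_ranks
#' @export
glance.friedman_ranks <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_methods = x$n_methods, n_blocks = x$n_blocks)
}
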