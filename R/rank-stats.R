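#' Friedman average-rank comparison of methods across blocks
#'
#' Given a method-by-block metric matrix (e.g. accuracy of five
#' feature-selection methods on seven cascade levels), assigns within
#' each block ranks 1..m with the larger metric receiving the larger
#' rank and ties receiving the average rank, sums ranks per method, and
#' computes the tie-corrected Friedman chi-square statistic
#' \deqn{\chi^2_F = \frac{12 \sum_j (R_j - L(m+1)/2)^2}
#'                       {L m (m+1) - \frac{\sum (t^3 - t)}{m - 1}}}
#' with the p-value from the chi-square distribution on m - 1 degrees of
#' freedom. Per block the ranks always sum to m(m+1)/2, and the
#' statistic is invariant to any strictly monotone per-block
#' transformation of the metric.
#'
#' @param values A numeric matrix or data frame, methods in rows
#'   (rownames or a `method` column) and blocks (levels) in columns; no
#'   missing cells.
#' @return A `friedman_ranks` object: `ranks` (method x block average
#'   ranks), `rank_sums` (named, per method), `statistic`, `df`,
#'   `p_value`, `n_methods`, `n_blocks`.
#' @export
#' @examples
#' acc <- rbind(a = c(0.9, 0.8, 0.95), b = c(0.85, 0.8, 0.90))
#' friedman_ranks(acc)$rank_sums
friedman_ranks <- function(values) {
  if (is.data.frame(values)) {
    if ("method" %in% names(values)) {
      rn <- values$method
      values <- as.matrix(values[setdiff(names(values), "method")])
      rownames(values) <- rn
    } else {
      values <- as.matrix(values)
    }
  }
  m <- nrow(values); l <- ncol(values)
  if (m < 2 || l < 2) stop("need at least 2 methods and 2 blocks")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing cell at method '", rownames(values)[idx[1]] %||% idx[1],
         "', block ", idx[2])
  }
  if (is.null(rownames(values))) rownames(values) <- paste0("method", seq_len(m))

  ranks <- apply(values, 2, rank)  # larger value -> larger rank, ties averaged
  rank_sums <- rowSums(ranks)

  tie_term <- sum(apply(values, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  }))
  denom <- l * m * (m + 1) - tie_term / (m - 1)
  numer <- 12 * sum((rank_sums - l * (m + 1) / 2)^2)
  # every block fully tied: no discrimination at all
  statistic <- if (denom == 0) 0 else numer / denom
  p <- stats::pchisq(statistic, df = m - 1, lower.tail = FALSE)

  structure(
    list(ranks = ranks, rank_sums = rank_sums, statistic = statistic,
         df = as.integer(m - 1), p_value = p, n_methods = m, n_blocks = l),
    class = "friedman_ranks"
  )
}

#' @export
print.friedman_ranks <- function(x, ...) {
  cat("Friedman average-rank test:", x$n_methods, "methods x",
      x$n_blocks, "blocks\n")
  cat("rank sums:\n")
  print(x$rank_sums)
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Ranks the absolute nonzero differences (ties averaged; zero
#' differences discarded before ranking) and reports
#' T = min(sum of positive ranks, sum of negative ranks). The two-sided
#' p-value is computed by exact enumeration of all sign assignments when
#' n <= 15 (`mode = "exact"`, the default there), or by the normal
#' approximation with tie-corrected variance and no continuity
#' correction (`mode = "normal"`). Negating all differences leaves both
#' T and p unchanged.
#'
#' @param differences Numeric vector of paired differences (or pass `x`
#'   and `y` to difference them).
#' @param y Optional second sample; differences become `differences - y`.
#' @param mode `"exact"` or `"normal"`; defaults to exact for n <= 15
#'   after zero removal, normal otherwise.
#' @return A list: `statistic` (T), `p_value`, `n` (nonzero
#'   differences), `mode`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 1, 4, 2, 5, 0))  # one zero discarded
wilcoxon_signed_rank <- function(differences, y = NULL, mode = NULL) {
  if (!is.null(y)) differences <- differences - y
  d <- differences[differences != 0]  # zero policy: discard
  n <- length(d)
  if (n == 0) stop("test undefined: all differences are zero")
  mode <- mode %||% (if (n <= 15) "exact" else "normal")
  mode <- match.arg(mode, c("exact", "normal"))

  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  t_stat <- min(w_pos, w_neg)

  if (mode == "exact") {
    if (n > 20) stop("exact enumeration limited to n <= 20")
    # enumerate all 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    t_all <- pmin(w_all, sum(r) - w_all)
    p <- mean(t_all <= t_stat)
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (max(w_pos, w_neg) - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p <- min(1, p)
  }
  list(statistic = t_stat, p_value = p, n = n, mode = mode)
}
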