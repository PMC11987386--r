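#' Build the binary classification cascade by iterative class peeling
#'
#' Decomposes a multi-class cohort into an ordered sequence of binary
#' datasets. Level 1 contrasts Normal against all cancers pooled
#' (positive class "Cancer"). Each subsequent level takes the rows
#' remaining after removing the previous level's positive class, and
#' contrasts the most frequent remaining class against the pooled rest;
#' the final level is a straight two-class contest between the last two
#' classes. Count ties are broken alphabetically. On the default cohort
#' shape this yields seven levels: Normal-vs-Cancer, then Colorectum,
#' Breast, UpperGI, Lung, Pancreas, and Ovary-vs-Liver.
#'
#' @param table A cohort tibble (see [read_cohort()]).
#' @param merge_map Named character vector of label merges applied before
#'   peeling, old -> new. Esophagus and Stomach are always folded into
#'   UpperGI by [validate_cohort()].
#' @return A `cascade` object: a list of levels, each holding `index`,
#'   `positive`, `negative_pool`, `negative_name`, and `data` (the level's
#'   rows with a binary `class` factor whose first level is the positive
#'   class).
#' @export
build_cascade <- function(table, merge_map = NULL) {
  label <- as.character(table$label)
  if (!is.null(merge_map)) {
    hit <- label %in% names(merge_map)
    label[hit] <- unname(merge_map[label[hit]])
  }
  counts <- table(label)
  empty <- setdiff(levels(table$label), names(counts))
  if (length(empty) > 0) {
    warning("dropping class(es) with 0 rows: ", paste(empty, collapse = ", "))
  }
  classes <- names(counts)
  if (length(classes) < 2) stop("need at least 2 non-empty classes")

  levels_out <- list()
  idx <- 1

  make_level <- function(idx, rows, positive, negative_pool, negative_name) {
    data <- table[rows, , drop = FALSE]
    cls <- ifelse(label[rows] == positive, positive, negative_name)
    data$class <- factor(cls, levels = c(positive, negative_name))
    structure(
      list(index = idx, positive = positive, negative_pool = negative_pool,
           negative_name = negative_name, data = data),
      class = "cascade_level"
    )
  }

  if (length(classes) == 2) {
    warning("only 2 classes present: building a single-level cascade")
    ord <- order(-counts, names(counts))
    pos <- classes[ord][1]
    neg <- classes[ord][2]
    lv <- make_level(1, seq_along(label), pos, neg, neg)
    return(structure(list(lv), class = "cascade"))
  }

  remaining <- seq_along(label)
  if ("Normal" %in% classes) {
    # level 1: normal vs pooled cancer; cancers are the majority side
    data <- table[remaining, , drop = FALSE]
    cls <- ifelse(label[remaining] == "Normal", "Normal", "Cancer")
    data$class <- factor(cls, levels = c("Cancer", "Normal"))
    lv <- structure(
      list(index = 1, positive = "Cancer",
           negative_pool = setdiff(classes, "Normal"),
           negative_name = "Normal", data = data),
      class = "cascade_level"
    )
    levels_out[[1]] <- lv
    remaining <- remaining[label[remaining] != "Normal"]
    idx <- 2
  }

  repeat {
    pool <- sort(table(label[remaining]), decreasing = TRUE)
    pool_counts <- as.integer(pool)
    # descending count, ties alphabetical
    nm <- names(pool)[order(-pool_counts, names(pool))]
    if (length(nm) == 2) {
      levels_out[[idx]] <- make_level(idx, remaining, nm[1], nm[2], nm[2])
      break
    }
    pos <- nm[1]
    levels_out[[idx]] <- make_level(idx, remaining, pos, nm[-1], "Other")
    remaining <- remaining[label[remaining] != pos]
    idx <- idx + 1
  }
  structure(levels_out, class = "cascade")
}

#' @export
print.cascade <- function(x, ...) {
  cat("A classification cascade with", length(x), "levels:\n")
  for (lv in x) {
    n <- nrow(lv$data)
    npos <- sum(lv$data$class == lv$positive)
    cat(sprintf("  level %d: %s (%d) vs %s (%d)\n",
                lv$index, lv$positive, npos, lv$negative_name, n - npos))
  }
  invisible(x)
}

#' Stratified train/test split of one cascade level
#'
#' Splits a level's rows into train and test partitions stratified by the
#' binary class: each class contributes `floor(test_fraction * n + 0.5)`
#' rows to the test set. Deterministic under `seed`.
#'
#' @param level A `cascade_level`.
#' @param test_fraction Fraction of each class held out (default 0.10).
#' @param seed Integer seed.
#' @return The level with integer row indices `train` and `test` added.
#' @export
split_level <- function(level, test_fraction = 0.10, seed = 1) {
  stopifnot(inherits(level, "cascade_level"),
            test_fraction > 0, test_fraction < 1)
  y <- level$data$class
  if (any(table(y) < 2)) {
    stop("cannot split level ", level$index, ": a class has fewer than 2 rows")
  }
  test <- with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      n_test <- floor(test_fraction * length(rows) + 0.5)
      n_test <- min(max(n_test, 0), length(rows) - 1)
      sort(sample(rows, n_test))
    }), use.names = FALSE)
  })
  level$test <- sort(test)
  level$train <- setdiff(seq_along(y), level$test)
  level
}

#' Split every level of a cascade
#'
#' Independent stratified splits per level, with per-level seeds derived
#' from one master seed.
#'
#' @param cascade A `cascade`.
#' @inheritParams split_level
#' @return The cascade with train/test indices on every level.
#' @export
split_cascade <- function(cascade, test_fraction = 0.10, seed = 1) {
  seeds <- derive_seeds(seed, length(cascade))
  out <- purrr::map2(cascade, seeds, function(lv, s) {
    split_level(lv, test_fraction = test_fraction, seed = s)
  })
  structure(out, class = "cascade")
}

# Pure routing rule over a vector of per-level positive-class
# probabilities. positives: positive label per level; final_negative: the
# other class of the terminal level. Stops at the first decisive level.
route_decision <- function(probs, positives, final_negative, threshold = 0.5) {
  n_levels <- length(positives)
  stopifnot(length(probs) >= 1)
  if (probs[1] < threshold) {
    return(list(label = "Normal", trace = probs[1]))
  }
  if (n_levels == 1) {
    return(list(label = positives[1], trace = probs[1]))
  }
  for (k in 2:(n_levels - 1)) {
    if (probs[k] >= threshold) {
      return(list(label = positives[k], trace = probs[seq_len(k)]))
    }
  }
  lab <- if (probs[n_levels] >= 0.5) positives[n_levels] else final_negative
  list(label = lab, trace = probs[seq_len(n_levels)])
}

#' Route samples through a trained cascade
#'
#' Inference-time routing: level 1 decides Normal vs Cancer; if the cancer
#' side wins the sample descends, and at each intermediate level it is
#' assigned the level's positive class when the positive probability
#' reaches `threshold` (default 0.5), otherwise it continues. At the
#' terminal level the more probable of the two remaining classes wins.
#' Exactly one of the possible labels is returned for every sample, and
#' the probability trace of every visited level is recorded.
#'
#' @param bundle A trained cascade bundle (see [train_cascade()]).
#' @param newdata A cohort tibble of samples to classify.
#' @param threshold Intermediate-level decision threshold.
#' @return A tibble: `sample_id`, `label_pred`, `n_levels_visited`, and a
#'   `trace` list-column of per-level positive-class probabilities.
#' @export
predict_cascade <- function(bundle, newdata, threshold = 0.5) {
  fits <- bundle$fits
  n_levels <- length(fits)
  positives <- vapply(fits, function(f) f$positive, character(1))
  final_negative <- fits[[n_levels]]$negative_name
  probs <- vapply(fits, function(f) {
    missing <- setdiff(f$features, names(newdata))
    if (length(missing) > 0) {
      stop("level ", f$index, " requires absent feature(s): ",
           paste(missing, collapse = ", "))
    }
    predict_level(f, newdata)
  }, numeric(nrow(newdata)))
  probs <- matrix(probs, nrow = nrow(newdata))
  routed <- lapply(seq_len(nrow(newdata)), function(i) {
    route_decision(probs[i, ], positives, final_negative, threshold)
  })
  tibble::tibble(
    sample_id = newdata$sample_id,
    label_pred = vapply(routed, `[[`, character(1), "label"),
    n_levels_visited = vapply(routed, function(r) length(r$trace), integer(1)),
    trace = lapply(routed, `[[`, "trace")
  )
}
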