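# The six univariate/multivariate feature scorers feeding the majority
# vote. All take a binary-labeled data frame whose `class` column's first
# factor level is the positive class, and score the encoded feature
# matrix (biomarkers numeric; sex/ethnicity small-integer coded).

selector_xy <- function(data, label = "class", features = NULL) {
  stopifnot(label %in% names(data))
  y <- data[[label]]
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  x <- encode_features(data[setdiff(names(data), label)], features)
  list(x = x, y = droplevels(y))
}

#' Weight of evidence and information value with monotonic binning
#'
#' Bins a continuous feature so that the per-bin weight of evidence
#' \eqn{WoE(x_i) = \ln(C1(x_i)/C2(x_i))} is monotone in bin order, where
#' C1 and C2 are the per-bin shares of the positive and negative class.
#' Binning starts from `max_bins` quantile bins and greedily merges
#' adjacent bins violating the overall trend until the WoE sequence is
#' monotone or only `bins` bins remain. Features with fewer than
#' `cardinality` distinct values are binned by value instead. Zero counts
#' are smoothed by 0.5 before proportions are formed, so the log never
#' diverges. The information value is
#' \eqn{IV(X) = \sum_i (C1(x_i) - C2(x_i)) \cdot WoE(x_i) \ge 0}.
#'
#' @param x Numeric feature vector.
#' @param y Binary factor; first level is the positive class.
#' @param cardinality Minimum distinct values for quantile binning (5).
#' @param bins Lower bound on the bin count when merging (3).
#' @param max_bins Initial number of quantile bins (20).
#' @return A list: `iv` (non-negative scalar) and `bins`, a tibble with
#'   per-bin counts, class proportions and WoE.
#' @export
woe_iv <- function(x, y, cardinality = 5, bins = 3, max_bins = 20) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("IV undefined: only one class present")
  pos <- levels(y)[1]
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) == 1) {
    warning("constant feature: IV is 0")
    return(list(iv = 0, bins = bin_table(factor(rep(1, length(x))), y, pos)))
  }

  if (length(unique(x)) < cardinality) {
    grp <- factor(x)
    tab <- bin_table(grp, y, pos)
  } else {
    edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1),
                                    type = 7, names = FALSE))
    grp_idx <- cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE)
    # merge map: bin index -> merged bin id; collapse until WoE monotone
    merge_id <- seq_len(max(grp_idx))
    repeat {
      grp <- factor(merge_id[grp_idx], levels = unique(merge_id))
      tab <- bin_table(grp, y, pos)
      w <- tab$woe
      if (length(w) <= bins || is_monotone(w)) break
      dirn <- if (w[length(w)] >= w[1]) 1 else -1
      viol <- which(dirn * diff(w) < 0)[1]
      # merge the violating pair
      ids <- unique(merge_id)
      merge_id[merge_id == ids[viol + 1]] <- ids[viol]
    }
  }
  iv <- sum((tab$c1 - tab$c2) * tab$woe)
  list(iv = iv, bins = tab)
}

is_monotone <- function(w) {
  all(diff(w) >= 0) || all(diff(w) <= 0)
}

bin_table <- function(grp, y, pos) {
  n_pos <- tapply(y == pos, grp, sum)
  n_neg <- tapply(y != pos, grp, sum)
  n_pos[is.na(n_pos)] <- 0
  n_neg[is.na(n_neg)] <- 0
  sp <- ifelse(n_pos == 0, 0.5, n_pos)
  sn <- ifelse(n_neg == 0, 0.5, n_neg)
  c1 <- sp / sum(sp)
  c2 <- sn / sum(sn)
  tibble::tibble(
    bin = as.character(levels(grp) %||% names(n_pos)),
    n_pos = as.numeric(n_pos), n_neg = as.numeric(n_neg),
    c1 = as.numeric(c1), c2 = as.numeric(c2),
    woe = log(as.numeric(c1) / as.numeric(c2))
  )
}

#' Qualitative strength of an information value
#'
#' Conventional reading of IV scores: below 0.02 unpredictive, 0.02-0.1
#' weak, 0.1-0.3 moderate, 0.3 and above strong.
#'
#' @param iv Numeric IV score(s).
#' @return Character vector of strength labels.
#' @export
iv_strength <- function(iv) {
  cut(iv, breaks = c(-Inf, 0.02, 0.1, 0.3, Inf),
      labels = c("unpredictive", "weak", "moderate", "strong"),
      right = FALSE) |> as.character()
}

#' Per-feature information value scores
#'
#' @param data Binary-labeled data frame; `label` names the class column.
#' @param label Class column name.
#' @param features Optional subset of feature columns.
#' @param ... Passed to [woe_iv()].
#' @return Named numeric vector of IV scores.
#' @export
iv_scores <- function(data, label = "class", features = NULL, ...) {
  d <- selector_xy(data, label, features)
  vapply(colnames(d$x), function(j) woe_iv(d$x[, j], d$y, ...)$iv, numeric(1))
}

#' Chi-square association scores
#'
#' In `"contingency"` mode (default) each continuous feature is
#' dichotomized at its median and scored by the standard Pearson 2x2
#' chi-square against the binary class,
#' \eqn{\chi^2 = N (TZ - VY)^2 / ((T+V)(Y+Z)(T+Y)(V+Z))}, where T, V, Y,
#' Z are the cell counts and N their total; larger means more associated.
#' Degenerate margins score 0 with a warning. In `"frequency"` mode the
#' raw non-negative values are treated as frequencies and compared to
#' their class-prior expectation (the convention of some library
#' routines); features are shifted to be non-negative first.
#'
#' @inheritParams iv_scores
#' @param mode `"contingency"` or `"frequency"`.
#' @return Named numeric vector of chi-square scores.
#' @export
chi_square_scores <- function(data, label = "class", features = NULL,
                              mode = c("contingency", "frequency")) {
  mode <- match.arg(mode)
  d <- selector_xy(data, label, features)
  x <- d$x
  x <- sweep(x, 2, pmin(apply(x, 2, min, na.rm = TRUE), 0), "-")  # shift-to-zero
  y1 <- d$y == levels(d$y)[1]
  vapply(colnames(x), function(j) {
    v <- x[, j]
    if (mode == "frequency") {
      tot <- sum(v)
      if (tot == 0) return(0)
      obs <- c(sum(v[y1]), sum(v[!y1]))
      expd <- tot * c(mean(y1), mean(!y1))
      return(sum((obs - expd)^2 / expd))
    }
    f <- if (length(unique(v)) <= 2) v > min(v) else v > stats::median(v)
    chi2_2x2(sum(f & y1), sum(f & !y1), sum(!f & y1), sum(!f & !y1))
  }, numeric(1))
}

# Pearson chi-square of a 2x2 table with cells
#   T = feature & class, V = feature & !class,
#   Y = !feature & class, Z = !feature & !class
chi2_2x2 <- function(t, v, y, z) {
  n <- t + v + y + z
  margins <- c(t + v, y + z, t + y, v + z)
  if (any(margins == 0)) {
    warning("degenerate margin in 2x2 table: chi-square set to 0")
    return(0)
  }
  n * (t * z - v * y)^2 / prod(margins)
}

#' Random-forest feature importance
#'
#' Fits a 100-tree random forest (Gini splits, bootstrap sampling) and
#' scores features either by mean decrease in Gini impurity, normalized
#' to sum to 1 (`"impurity"`, the default), or by the out-of-bag
#' permutation importance: the mean absolute change in OOB error after
#' permuting the feature within the OOB rows of each tree
#' (`"oob_permutation"`).
#'
#' @inheritParams iv_scores
#' @param flavor Importance flavor.
#' @param n_trees Number of trees (100).
#' @param bootstrap Whether trees are grown on bootstrap resamples; OOB
#'   permutation importance requires this.
#' @param seed Integer seed; scores are deterministic given it.
#' @return Named numeric vector of importances.
#' @export
forest_importance <- function(data, label = "class", features = NULL,
                              flavor = c("impurity", "oob_permutation"),
                              n_trees = 100, bootstrap = TRUE, seed = 1) {
  flavor <- match.arg(flavor)
  if (flavor == "oob_permutation" && !bootstrap) {
    stop("oob_permutation importance requires bootstrap sampling (no OOB rows otherwise)")
  }
  d <- selector_xy(data, label, features)
  fit <- with_seed(seed, randomForest::randomForest(
    x = d$x, y = d$y, ntree = n_trees, replace = bootstrap,
    importance = (flavor == "oob_permutation")
  ))
  if (flavor == "impurity") {
    imp <- fit$importance[, "MeanDecreaseGini"]
    return(imp / sum(imp))
  }
  abs(randomForest::importance(fit, type = 1, scale = FALSE)[, 1])
}

#' Extremely-randomized-trees feature importance
#'
#' As [forest_importance()] with impurity scoring, but split thresholds
#' are drawn at random and trees are grown on the full sample (no
#' bootstrap), the extra-trees recipe. Importances are normalized to sum
#' to 1.
#'
#' @inheritParams forest_importance
#' @return Named numeric vector of importances summing to 1.
#' @export
extra_trees_importance <- function(data, label = "class", features = NULL,
                                   n_trees = 100, seed = 1) {
  d <- selector_xy(data, label, features)
  df <- as.data.frame(d$x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.class <- d$y
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1, importance = "impurity",
    num.threads = 1, seed = seed
  )
  imp <- fit$variable.importance
  names(imp) <- colnames(d$x)
  imp / sum(imp)
}

#' Recursive feature elimination with a ridge-logistic base model
#'
#' Standardizes the features, fits an L2-penalized logistic regression,
#' drops the feature with the smallest absolute coefficient, and repeats
#' (step size 1) until `n_keep` features remain. The penalty strength
#' corresponds to inverse regularization `C` in the
#' sum-of-losses parameterization (ridge weight `1/(n C)` on the mean
#' loss).
#'
#' @inheritParams iv_scores
#' @param n_keep Number of features to retain (21 on the 43-feature
#'   panel).
#' @param C Inverse regularization strength of the base model (1.0).
#' @return A list: `selected` (character), `elimination_order` (features
#'   in the order dropped, least important first).
#' @export
rfe_select <- function(data, label = "class", features = NULL,
                       n_keep = 21, C = 1.0) {
  d <- selector_xy(data, label, features)
  feats <- colnames(d$x)
  if (n_keep >= length(feats)) {
    warning("n_keep >= number of features: keeping all")
    return(list(selected = feats, elimination_order = character(0)))
  }
  y <- as.integer(d$y == levels(d$y)[1])
  dropped <- character(0)
  keep <- feats
  while (length(keep) > n_keep) {
    x <- standardize_matrix(d$x[, keep, drop = FALSE])
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1 / (length(y) * C), standardize = FALSE)
    beta <- abs(as.numeric(fit$beta))
    names(beta) <- keep
    worst <- names(sort(beta))[1]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  list(selected = keep, elimination_order = dropped)
}

#' L1-penalized linear max-margin feature selection
#'
#' Fits a linear classifier with squared-hinge loss and an L1 penalty on
#' standardized features (objective
#' \eqn{\|\beta\|_1 + C \sum_i \max(0, 1 - y_i x_i^\top\beta - b)^2},
#' intercept unpenalized), solved by accelerated proximal gradient
#' descent with soft-thresholding. Features are ranked by
#' \eqn{|\hat\beta|}; exact zeros rank last, ties break by name. Small
#' `C` drives all coefficients to zero, in which case the selection is
#' flagged as degenerate with a warning.
#'
#' @inheritParams rfe_select
#' @param C Inverse regularization strength (0.01: strong sparsity).
#' @param max_iter Iteration cap (1000).
#' @param tol Convergence tolerance on the coefficient update (1e-4).
#' @return A list: `selected`, `beta` (named coefficients), `converged`.
#' @export
l1_select <- function(data, label = "class", features = NULL,
                      C = 0.01, n_keep = 21, max_iter = 1000, tol = 1e-4) {
  d <- selector_xy(data, label, features)
  x <- standardize_matrix(d$x)
  y <- ifelse(d$y == levels(d$y)[1], 1, -1)
  n_keep <- min(n_keep, ncol(x))

  # Lipschitz constant of the smooth part: 2C * sigma_max([X 1])^2
  lip <- 2 * C * (norm(cbind(x, 1), "2")^2)
  beta <- rep(0, ncol(x)); b <- 0
  zb <- beta; zb0 <- b; tk <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    margin <- 1 - y * (x %*% zb + zb0)
    active <- as.numeric(margin > 0)
    g <- -2 * C * crossprod(x, y * pmax(margin, 0))
    g0 <- -2 * C * sum(y * pmax(margin, 0))
    new_beta <- soft_threshold(zb - g / lip, 1 / lip)
    new_b <- zb0 - g0 / lip
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zb <- new_beta + ((tk - 1) / t_next) * (new_beta - beta)
    zb0 <- new_b + ((tk - 1) / t_next) * (new_b - b)
    delta <- max(abs(new_beta - beta), abs(new_b - b))
    beta <- as.numeric(new_beta); b <- new_b; tk <- t_next
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("L1 selection did not converge within ", max_iter,
            " iterations; using final iterate")
  }
  names(beta) <- colnames(x)
  if (all(beta == 0)) {
    warning("all L1 coefficients are zero; selection degenerates to name order")
  }
  ord <- order(-abs(beta), names(beta))
  list(selected = names(beta)[ord][seq_len(n_keep)], beta = beta,
       converged = converged)
}

soft_threshold <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}
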