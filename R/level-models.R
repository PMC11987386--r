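#' Per-level classifier registry
#'
#' Returns the model specification serving a cascade level. The registry
#' defaults reflect which algorithm (or soft-voting ensemble) handles
#' each binary task: level 1 gradient-boosted trees (Normal vs Cancer),
#' level 2 a soft vote of boosted trees and random forest (colorectal),
#' level 3 extra trees + random forest (breast), level 4 extra trees
#' (upper GI), level 5 QDA (lung), level 6 QDA + boosted trees
#' (pancreatic), level 7 random forest (ovarian vs liver).
#'
#' Member hyperparameters are fixed: boosted trees use 100 rounds,
#' learning rate 0.3, max depth 6, min child weight 1, base score 0.5;
#' forests use 100 Gini trees with bootstrap; extra trees 100 trees with
#' random splits and no bootstrap; QDA uses no shrinkage (reg 0),
#' tolerance 1e-4 and data-driven priors.
#'
#' @param index Level index 1..7.
#' @param members Optional character vector overriding the registry, from
#'   `"gbt"`, `"rf"`, `"et"`, `"qda"`.
#' @return A `level_model_spec` list: `index`, `members`, `combination`
#'   (`"single"` or `"soft_vote"`).
#' @export
#' @examples
#' level_model_spec(2)$members
level_model_spec <- function(index, members = NULL) {
  registry <- list(
    `1` = "gbt", `2` = c("gbt", "rf"), `3` = c("et", "rf"), `4` = "et",
    `5` = "qda", `6` = c("qda", "gbt"), `7` = "rf"
  )
  if (!is.null(members)) {
    if (length(members) == 0) stop("member list must not be empty")
    bad <- setdiff(members, c("gbt", "rf", "et", "qda"))
    if (length(bad) > 0) stop("unknown member algorithm(s): ", paste(bad, collapse = ", "))
  } else {
    key <- as.character(index)
    if (!key %in% names(registry)) {
      stop("no registry default for level ", index, "; pass members explicitly")
    }
    members <- registry[[key]]
  }
  structure(
    list(index = index, members = members,
         combination = if (length(members) > 1) "soft_vote" else "single"),
    class = "level_model_spec"
  )
}

fit_member <- function(algo, x, y, seed = 1) {
  pos <- levels(y)[1]
  x <- as.matrix(x)
  model <- switch(
    algo,
    gbt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.3,
                    max_depth = 6, min_child_weight = 1,
                    base_score = 0.5, nthread = 1,
                    seed = as.integer(seed) %% .Machine$integer.max),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == pos), nthread = 1),
      nrounds = 100, verbose = 0
    ),
    rf = with_seed(seed, {
      randomForest::randomForest(x = x, y = y, ntree = 100)
    }),
    et = {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(df)))
      ranger::ranger(
        dependent.variable.name = ".class",
        data = cbind(df, .class = y),
        num.trees = 100, splitrule = "extratrees", num.random.splits = 1,
        replace = FALSE, sample.fraction = 1, probability = TRUE,
        num.threads = 1, seed = seed
      )
    },
    qda = qda_fit(x, y),
    stop("unknown member algorithm: ", algo)
  )
  structure(list(algo = algo, model = model, positive = pos),
            class = "cascade_member")
}

# P(positive class) from one fitted member
predict_member <- function(member, newx) {
  newx <- as.matrix(newx)
  p <- switch(
    member$algo,
    gbt = as.numeric(stats::predict(member$model, newx)),
    rf = unname(stats::predict(member$model, newx, type = "prob")[, member$positive]),
    et = {
      df <- as.data.frame(newx)
      names(df) <- paste0("f", seq_len(ncol(df)))
      unname(stats::predict(member$model, data = df,
                            num.threads = 1)$predictions[, member$positive])
    },
    qda = unname(predict_qda(member$model, newx)[, member$positive])
  )
  p
}

#' Soft-voting combination of member probabilities
#'
#' The unweighted arithmetic mean of the members' positive-class
#' probability vectors; the output is a convex combination, so it lies
#' between the member minimum and maximum row-wise. Members emitting
#' values outside \[0, 1\] violate the probability contract and error.
#'
#' @param member_probs A numeric matrix (rows = samples, columns =
#'   members) or a list of equal-length probability vectors.
#' @return Numeric vector of averaged positive-class probabilities.
#' @export
#' @examples
#' soft_vote_proba(cbind(a = c(0.6, 0.1), b = c(0.8, 0.3)))
soft_vote_proba <- function(member_probs) {
  if (is.list(member_probs) && !is.data.frame(member_probs)) {
    member_probs <- do.call(cbind, member_probs)
  }
  member_probs <- as.matrix(member_probs)
  if (any(member_probs < -1e-9 | member_probs > 1 + 1e-9, na.rm = TRUE)) {
    stop("member probabilities outside [0, 1]: contract violation")
  }
  rowMeans(member_probs)
}

#' Fit a level's model on a binary-labeled table
#'
#' Encodes the requested features, fits every member of the spec and
#' wraps them for soft-vote prediction.
#'
#' @param data Binary-labeled data frame (`class` column, positive class
#'   first).
#' @param spec A [level_model_spec()].
#' @param features Feature columns to use (e.g. a vote-selected panel).
#' @param label Class column name.
#' @param seed Integer seed (fans out per member).
#' @return A `level_fit`.
#' @export
fit_level <- function(data, spec, features = NULL, label = "class", seed = 1) {
  d <- selector_xy(data, label, features)
  seeds <- derive_seeds(seed, length(spec$members))
  members <- purrr::map2(spec$members, seeds, function(algo, s) {
    fit_member(algo, d$x, d$y, seed = s)
  })
  structure(
    list(index = spec$index, spec = spec, members = members,
         features = colnames(d$x), positive = levels(d$y)[1],
         negative_name = levels(d$y)[2]),
    class = "level_fit"
  )
}

#' Positive-class probability from a fitted level
#'
#' @param fit A `level_fit`.
#' @param newdata Data frame containing the fit's feature columns.
#' @return Numeric vector of P(positive class).
#' @export
predict_level <- function(fit, newdata) {
  x <- encode_features(newdata, fit$features)
  x <- x[, fit$features, drop = FALSE]
  probs <- vapply(fit$members, predict_member, numeric(nrow(x)), newx = x)
  soft_vote_proba(matrix(probs, nrow = nrow(x)))
}

#' Stratified k-fold cross-validation of a level model
#'
#' Splits the rows into `k` stratified folds, fits the spec on each
#' training portion, and scores the held-out fold with the full metric
#' set ([binary_metrics()]). The final returned model follows `policy`:
#' `"refit_all"` (default) refits on every row; `"best_fold"` keeps the
#' fold model with the highest held-out AUC (ties broken by accuracy,
#' then fold index).
#'
#' @inheritParams fit_level
#' @param k Number of folds (10).
#' @param policy Final-model policy.
#' @return A `level_cv`: `fold_metrics` tibble (one row per fold), `fit`
#'   (the final `level_fit`), `policy`, `spec`.
#' @export
cv_level <- function(data, spec, features = NULL, label = "class",
                     k = 10, seed = 1, policy = c("refit_all", "best_fold")) {
  policy <- match.arg(policy)
  y <- droplevels(factor(data[[label]]))
  if (any(table(y) < k)) {
    stop("stratification impossible: a class has fewer than k = ", k,
         " rows; reduce k or resample")
  }
  seeds <- derive_seeds(seed, k + 2)
  folds <- with_seed(seeds[k + 1], {
    f <- integer(length(y))
    for (cl in levels(y)) {
      rows <- which(y == cl)
      f[rows] <- sample(rep(seq_len(k), length.out = length(rows)))
    }
    f
  })

  fold_fits <- vector("list", k)
  fold_metrics <- purrr::map_dfr(seq_len(k), function(i) {
    train <- data[folds != i, , drop = FALSE]
    hold <- data[folds == i, , drop = FALSE]
    fit <- fit_level(train, spec, features, label, seed = seeds[i])
    fold_fits[[i]] <<- fit
    p <- predict_level(fit, hold)
    truth <- factor(hold[[label]], levels = levels(y))
    est <- factor(ifelse(p >= 0.5, levels(y)[1], levels(y)[2]), levels = levels(y))
    m <- binary_metrics(truth, est, prob = p, scope = "fold")
    m$fold <- i
    m
  })

  fit <- if (policy == "refit_all") {
    fit_level(data, spec, features, label, seed = seeds[k + 2])
  } else {
    ord <- order(-fold_metrics$auc, -fold_metrics$acc, fold_metrics$fold)
    fold_fits[[fold_metrics$fold[ord[1]]]]
  }
  structure(
    list(spec = spec, fold_metrics = fold_metrics, fit = fit,
         policy = policy, k = k),
    class = "level_cv"
  )
}
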