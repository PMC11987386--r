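BUNDLE_VERSION <- "1"

#' Select features and train models for every cascade level
#'
#' For each level: runs [vote_select()] (on the training rows by
#' default, or on the full level dataset with
#' `select_scope = "full"`, the leakage-prone ordering some published
#' analyses use), then 10-fold cross-validates the level's registry
#' model on the training rows restricted to the selected features.
#'
#' @param cascade A split `cascade` (see [split_cascade()]).
#' @param threshold Vote threshold for feature selection (default 3).
#' @param k Cross-validation folds (default 10).
#' @param seed Master seed; per-level seeds are derived from it.
#' @param policy Final-model policy, see [cv_level()].
#' @param select_scope `"train"` (default) or `"full"`.
#' @param specs Optional list of [level_model_spec()] overrides, indexed
#'   by level.
#' @return A `cascade_bundle`: `fits` (per-level `level_fit`), `cv`
#'   (per-level `level_cv`), `tallies` (per-level `vote_tally`), and a
#'   `manifest` recording seeds, settings and categorical encodings.
#' @export
train_cascade <- function(cascade, threshold = 3, k = 10, seed = 17,
                          policy = c("refit_all", "best_fold"),
                          select_scope = c("train", "full"), specs = NULL) {
  policy <- match.arg(policy)
  select_scope <- match.arg(select_scope)
  if (is.null(cascade[[1]]$train)) {
    stop("cascade has no train/test split; call split_cascade() first")
  }
  seeds <- matrix(derive_seeds(seed, 2 * length(cascade)), ncol = 2)

  tallies <- list(); cvs <- list(); fits <- list()
  for (i in seq_along(cascade)) {
    lv <- cascade[[i]]
    train_data <- lv$data[lv$train, , drop = FALSE]
    sel_data <- if (select_scope == "train") train_data else lv$data
    tally <- vote_select(sel_data, threshold = threshold, seed = seeds[i, 1])
    feats <- selected_features(tally)
    if (length(feats) < 2) feats <- tally$feature  # degenerate consensus: keep all
    spec <- if (!is.null(specs) && length(specs) >= i && !is.null(specs[[i]])) {
      specs[[i]]
    } else {
      level_model_spec(lv$index)
    }
    cv <- cv_level(train_data, spec, features = feats, k = k,
                   seed = seeds[i, 2], policy = policy)
    tallies[[i]] <- tally
    cvs[[i]] <- cv
    fits[[i]] <- cv$fit
  }
  manifest <- list(
    version = BUNDLE_VERSION,
    n_levels = length(cascade),
    levels = lapply(cascade, function(lv) {
      list(index = lv$index, positive = lv$positive,
           negative = lv$negative_name, n = nrow(lv$data))
    }),
    settings = list(threshold = threshold, k = k, seed = seed,
                    policy = policy, select_scope = select_scope),
    encodings = list(sex = stats::setNames(0:1, sex_levels()),
                     ethnicity = stats::setNames(0:4, ethnicity_levels()))
  )
  structure(list(fits = fits, cv = cvs, tallies = tallies, manifest = manifest),
            class = "cascade_bundle")
}

#' Evaluate a trained bundle on the cascade's held-out test rows
#'
#' Scores each level's final model on that level's test partition with
#' the full metric panel, and macro-averages across levels.
#'
#' @param bundle A `cascade_bundle` from [train_cascade()].
#' @param cascade The split `cascade` the bundle was trained on.
#' @return A list: `level_metrics` (tibble, one row per level) and
#'   `overall` (one-row macro average, see [aggregate_levels()]).
#' @export
evaluate_cascade <- function(bundle, cascade) {
  level_metrics <- purrr::map_dfr(seq_along(cascade), function(i) {
    lv <- cascade[[i]]
    fit <- bundle$fits[[i]]
    test <- lv$data[lv$test, , drop = FALSE]
    p <- predict_level(fit, test)
    truth <- test$class
    est <- factor(ifelse(p >= 0.5, levels(truth)[1], levels(truth)[2]),
                  levels = levels(truth))
    m <- binary_metrics(truth, est, prob = p, scope = "test")
    m$level <- lv$index
    m$positive <- lv$positive
    m$n_selected <- length(bundle$fits[[i]]$features)
    m
  })
  list(level_metrics = level_metrics,
       overall = aggregate_levels(level_metrics))
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. Defaults mirror the
#' deployed settings: upper-GI merge, vote threshold 3, 90/10 stratified
#' split, 10-fold cross-validation, refit-on-all-training final models.
#'
#' @param input Optional path to a cohort CSV; when `NULL` a synthetic
#'   cohort is simulated from `cohort` instead.
#' @param cohort A [cohort_config()] for simulation.
#' @param threshold Vote threshold.
#' @param test_fraction Held-out fraction per level.
#' @param k CV folds.
#' @param policy Final-model policy.
#' @param select_scope Feature-selection scope, see [train_cascade()].
#' @param seed Master seed; every stage's randomness derives from it.
#' @param out_dir Optional directory for artifacts (cohort, tallies,
#'   metrics, manifest).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, cohort = cohort_config(),
                            threshold = 3, test_fraction = 0.10, k = 10,
                            policy = "refit_all", select_scope = "train",
                            seed = 17, out_dir = NULL) {
  structure(
    list(input = input, cohort = cohort, threshold = threshold,
         test_fraction = test_fraction, k = k, policy = policy,
         select_scope = select_scope, seed = seed, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full cascade pipeline
#'
#' simulate/load -> build cascade -> split -> vote-select -> train with
#' cross-validation -> evaluate on held-out rows -> macro-aggregate.
#' Deterministic: two runs with the same config and seed produce
#' identical reports. When `out_dir` is set, the cohort, per-level vote
#' tallies (JSON), per-level and overall metrics (CSV + JSON) and a run
#' manifest are written there.
#'
#' @param config A [pipeline_config()].
#' @return A list: `cohort`, `cascade`, `bundle`, `level_metrics`,
#'   `overall`, `fold_metrics` (per level), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 3)
  cohort <- if (is.null(config$input)) {
    simulate_cohort(config$cohort, seed = seeds[1])
  } else {
    read_cohort(config$input)
  }
  cascade <- build_cascade(cohort)
  cascade <- split_cascade(cascade, test_fraction = config$test_fraction,
                           seed = seeds[2])
  bundle <- train_cascade(cascade, threshold = config$threshold, k = config$k,
                          seed = seeds[3], policy = config$policy,
                          select_scope = config$select_scope)
  ev <- evaluate_cascade(bundle, cascade)
  fold_metrics <- purrr::map_dfr(seq_along(bundle$cv), function(i) {
    fm <- bundle$cv[[i]]$fold_metrics
    fm$level <- cascade[[i]]$index
    fm
  })
  result <- list(cohort = cohort, cascade = cascade, bundle = bundle,
                 level_metrics = ev$level_metrics, overall = ev$overall,
                 fold_metrics = fold_metrics, config = config)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(out_dir, "cohort.csv"))
  for (i in seq_along(result$bundle$tallies)) {
    jsonlite::write_json(
      as.data.frame(result$bundle$tallies[[i]]),
      file.path(out_dir, sprintf("tally_level%d.json", i)),
      auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_csv(result$level_metrics, file.path(out_dir, "level_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(result$fold_metrics, file.path(out_dir, "fold_metrics.csv"),
                   progress = FALSE)
  jsonlite::write_json(as.list(result$overall),
                       file.path(out_dir, "overall_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Persist and restore a trained cascade bundle
#'
#' `save_bundle()` writes a directory with a JSON manifest (bundle
#' version, level order, settings, categorical encodings) and one
#' serialized model file per level; `load_bundle()` restores it,
#' erroring on a missing manifest or an incompatible bundle version.
#' The round trip is exact: a restored bundle reproduces the original
#' predictions bit-identically.
#'
#' @param bundle A `cascade_bundle`.
#' @param path Bundle directory.
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()`
#'   returns the `cascade_bundle`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "cascade_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(bundle$fits)) {
    fit <- bundle$fits[[i]]
    # boosters hold external pointers; serialize them to raw bytes first
    fit$members <- lapply(fit$members, function(mb) {
      if (mb$algo == "gbt") {
        mb$model <- xgboost::xgb.save.raw(mb$model)
      }
      mb
    })
    saveRDS(fit, file.path(path, sprintf("level%02d_fit.rds", i)))
    saveRDS(bundle$cv[[i]]$fold_metrics,
            file.path(path, sprintf("level%02d_fold_metrics.rds", i)))
    saveRDS(bundle$tallies[[i]], file.path(path, sprintf("level%02d_tally.rds", i)))
  }
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no bundle manifest found at ", path)
  }
  manifest <- jsonlite::read_json(manifest_path)
  if (!identical(as.character(manifest$version), BUNDLE_VERSION)) {
    stop("incompatible bundle version '", manifest$version,
         "' (this build reads version ", BUNDLE_VERSION, ")")
  }
  n <- manifest$n_levels
  fits <- list(); cvs <- list(); tallies <- list()
  for (i in seq_len(n)) {
    fit <- readRDS(file.path(path, sprintf("level%02d_fit.rds", i)))
    fit$members <- lapply(fit$members, function(mb) {
      if (mb$algo == "gbt") {
        mb$model <- xgboost::xgb.load.raw(mb$model)
      }
      mb
    })
    fits[[i]] <- fit
    cvs[[i]] <- list(fold_metrics = readRDS(
      file.path(path, sprintf("level%02d_fold_metrics.rds", i))))
    tallies[[i]] <- readRDS(file.path(path, sprintf("level%02d_tally.rds", i)))
  }
  structure(list(fits = fits, cv = cvs, tallies = tallies, manifest = manifest),
            class = "cascade_bundle")
}
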