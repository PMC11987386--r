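test_that("the registry serves the documented per-level models", {
  expect_identical(level_model_spec(1)$members, "gbt")
  expect_identical(level_model_spec(2)$members, c("gbt", "rf"))
  expect_identical(level_model_spec(3)$members, c("et", "rf"))
  expect_identical(level_model_spec(4)$members, "et")
  expect_identical(level_model_spec(5)$members, "qda")
  expect_identical(level_model_spec(6)$members, c("qda", "gbt"))
  expect_identical(level_model_spec(7)$members, "rf")
  expect_identical(level_model_spec(2)$combination, "soft_vote")
  expect_identical(level_model_spec(5)$combination, "single")
  expect_error(level_model_spec(9), "registry")
  expect_error(level_model_spec(1, members = character(0)), "empty")
  expect_error(level_model_spec(1, members = "catboost"), "unknown")
})

test_that("soft voting is the plain mean and a convex combination", {
  expect_equal(soft_vote_proba(cbind(c(0.6), c(0.8))), 0.7)
  # idempotent on identical members
  p <- stats::runif(10)
  expect_equal(soft_vote_proba(cbind(p, p, p)), p)
  # three-member hand oracle on a 5-row fixture
  m <- cbind(a = c(0.1, 0.5, 0.9, 0.2, 0.7),
             b = c(0.3, 0.4, 0.8, 0.6, 0.5),
             c = c(0.2, 0.9, 0.7, 0.4, 0.6))
  expect_equal(soft_vote_proba(m), (m[, 1] + m[, 2] + m[, 3]) / 3)
  expect_true(all(soft_vote_proba(m) >= apply(m, 1, min)))
  expect_true(all(soft_vote_proba(m) <= apply(m, 1, max)))
  expect_error(soft_vote_proba(cbind(c(0.5), c(1.4))), "contract")
})

test_that("QDA matches MASS::qda posteriors at reg = 0", {
  skip_if_not_installed("MASS")
  set.seed(2)
  n <- 300
  x <- rbind(matrix(stats::rnorm(n * 2, 0), n, 2),
             matrix(stats::rnorm(n * 2, 1.5, 1.4), n, 2))
  y <- factor(rep(c("a", "b"), each = n), levels = c("a", "b"))
  fit <- liquidcascade:::qda_fit(x, y)
  newx <- matrix(stats::rnorm(100), 50, 2)
  mine <- liquidcascade:::predict_qda(fit, newx)
  oracle <- stats::predict(MASS::qda(x, y), newx)$posterior
  expect_equal(unname(mine), unname(oracle[, c("a", "b")]), tolerance = 1e-8)
})

test_that("QDA approaches the Bayes rate on known Gaussians", {
  set.seed(5)
  n <- 10000
  draw <- function(n) rbind(
    cbind(stats::rnorm(n, -1), stats::rnorm(n)),
    cbind(stats::rnorm(n, 1), stats::rnorm(n))
  )
  y <- factor(rep(c("a", "b"), each = n), levels = c("a", "b"))
  fit <- liquidcascade:::qda_fit(draw(n), y)
  test_x <- draw(n)
  pred <- ifelse(liquidcascade:::predict_qda(fit, test_x)[, "a"] >= 0.5, "a", "b")
  err <- mean(pred != y)
  bayes <- stats::pnorm(-1)  # means two sd apart, equal priors
  expect_lt(abs(err - bayes), 0.02)
})

test_that("singular covariance triggers the regularized fallback", {
  set.seed(3)
  x <- cbind(stats::rnorm(40), stats::rnorm(40))
  x <- cbind(x, x[, 1])  # exactly collinear third column
  y <- factor(rep(c("a", "b"), each = 20), levels = c("a", "b"))
  expect_warning(fit <- liquidcascade:::qda_fit(x, y), "reg = 1e-6")
  p <- liquidcascade:::predict_qda(fit, x)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 40))
})

test_that("cross-validation aggregates folds and is deterministic", {
  set.seed(21)
  y <- factor(rep(c("pos", "neg"), each = 50), levels = c("pos", "neg"))
  d <- tibble::tibble(
    sep = as.numeric(y == "pos"),  # discrete, exactly separable
    noise1 = stats::rnorm(100), noise2 = stats::rnorm(100),
    class = y)
  cv <- cv_level(d, level_model_spec(1), k = 5, seed = 31)
  expect_identical(nrow(cv$fold_metrics), 5L)
  # per-fold BA identity holds exactly
  expect_equal(cv$fold_metrics$ba,
               (cv$fold_metrics$recall + cv$fold_metrics$specificity) / 2)
  # glance equals hand aggregation of the fold table
  g <- glance(cv)
  expect_equal(g$acc_mean, mean(cv$fold_metrics$acc))
  expect_equal(g$auc_sd, stats::sd(cv$fold_metrics$auc))
  # linearly separable level: every fold is perfect
  expect_equal(cv$fold_metrics$acc, rep(1, 5))
  expect_equal(g$acc_sd, 0)

  cv2 <- cv_level(d, level_model_spec(1), k = 5, seed = 31)
  expect_equal(cv$fold_metrics, cv2$fold_metrics)
  # tidy returns folds first
  expect_identical(names(tidy(cv))[1], "fold")
})

test_that("stratification failure is reported, not silently degraded", {
  d <- toy_binary(n = 30, seed = 2)
  d$class[d$class == "pos"] <- "neg"
  d$class[1:3] <- "pos"
  expect_error(cv_level(d, level_model_spec(1), k = 10, seed = 1),
               "stratification")
})

test_that("soft-vote level fits stay within their members' range", {
  co <- small_cohort(n_normal = 80, n_cancer = 60, seed = 41)
  lv <- suppressWarnings(build_cascade(co))[[1]]
  fit <- fit_level(lv$data, level_model_spec(2), seed = 11)
  p_vote <- predict_level(fit, lv$data)
  x <- liquidcascade:::encode_features(lv$data, fit$features)[, fit$features]
  p_members <- vapply(fit$members, liquidcascade:::predict_member,
                      numeric(nrow(lv$data)), newx = x)
  expect_true(all(p_vote >= apply(p_members, 1, min) - 1e-12))
  expect_true(all(p_vote <= apply(p_members, 1, max) + 1e-12))
  expect_equal(p_vote, rowMeans(p_members))
})

test_that("best-fold policy returns the top-AUC fold model", {
  d <- toy_binary(n = 80, seed = 51)
  d$sep <- d$sep + stats::rnorm(80, sd = 0.8)  # make folds imperfect
  cv <- cv_level(d, level_model_spec(7), k = 4, seed = 3, policy = "best_fold")
  expect_s3_class(cv$fit, "level_fit")
  expect_identical(cv$policy, "best_fold")
})
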