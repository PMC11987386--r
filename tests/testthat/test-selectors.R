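test_that("WoE/IV matches the two-bin hand oracle", {
  # bin A: 80 pos / 20 neg; bin B: 20 pos / 80 neg (100 per class)
  x <- c(rep(0, 100), rep(1, 100))
  y <- factor(c(rep("pos", 80), rep("neg", 20), rep("pos", 20), rep("neg", 80)),
              levels = c("pos", "neg"))
  res <- woe_iv(x, y)
  expect_equal(res$bins$c1, c(0.8, 0.2))
  expect_equal(res$bins$c2, c(0.2, 0.8))
  expect_equal(res$iv, 0.6 * log(4) - 0.6 * log(1 / 4), tolerance = 1e-12)

  # equal class proportions in every bin -> WoE 0 per bin, IV 0
  y_flat <- factor(rep(c("pos", "neg"), 100), levels = c("pos", "neg"))
  res0 <- woe_iv(x, y_flat)
  expect_equal(res0$bins$woe, c(0, 0))
  expect_equal(res0$iv, 0)
})

test_that("IV is non-negative and bins come out monotone", {
  set.seed(7)
  y <- factor(rep(c("pos", "neg"), each = 250), levels = c("pos", "neg"))
  for (i in 1:20) {
    x <- stats::rnorm(500) + ifelse(y == "pos", stats::runif(1, -1, 1), 0)
    res <- woe_iv(x, y)
    expect_gte(res$iv, 0)
    w <- res$bins$woe
    expect_true(all(diff(w) >= -1e-12) || all(diff(w) <= 1e-12) ||
                  nrow(res$bins) <= 3)
  }
  # IV strength labels
  expect_identical(iv_strength(c(0.01, 0.05, 0.25, 0.5)),
                   c("unpredictive", "weak", "moderate", "strong"))
  # constant feature: IV 0 with warning
  y2 <- factor(rep(c("pos", "neg"), 50), levels = c("pos", "neg"))
  expect_warning(res <- woe_iv(rep(1, 100), y2), "constant")
  expect_equal(res$iv, 0)
  expect_error(woe_iv(stats::rnorm(10), factor(rep("pos", 10))), "one class")
})

test_that("chi-square matches textbook 2x2 arithmetic", {
  chi2 <- liquidcascade:::chi2_2x2
  # perfect association: chi-square equals N
  expect_equal(chi2(50, 0, 0, 50), 100)
  # independence: 0
  expect_equal(chi2(25, 25, 25, 25), 0)
  # against a direct observed-vs-expected computation
  counts <- matrix(c(30, 10, 20, 40), 2, byrow = TRUE)
  oracle <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  expect_equal(chi2(30, 10, 20, 40), unname(oracle$statistic), tolerance = 1e-12)
  # degenerate margin scores 0 with a warning
  expect_warning(z <- chi2(0, 0, 30, 70), "degenerate")
  expect_equal(z, 0)
})

test_that("chi-square feature scores rank a separator first", {
  d <- toy_binary(n = 200, seed = 3)
  sc <- chi_square_scores(d)
  expect_identical(names(which.max(sc)), "sep")
  # frequency mode agrees with its own expectation arithmetic
  sf <- chi_square_scores(d, mode = "frequency")
  v <- d$sep - min(d$sep)
  y1 <- d$class == "pos"
  obs <- c(sum(v[y1]), sum(v[!y1]))
  expd <- sum(v) * c(mean(y1), 1 - mean(y1))
  expect_equal(unname(sf[["sep"]]), sum((obs - expd)^2 / expd))
})

test_that("tree importances find a perfect predictor and are seeded", {
  d <- toy_binary(n = 120, seed = 5)
  fi <- forest_importance(d, seed = 4)
  expect_identical(names(which.max(fi)), "sep")
  expect_equal(sum(fi), 1, tolerance = 1e-12)
  expect_identical(fi, forest_importance(d, seed = 4))

  pi <- forest_importance(d, flavor = "oob_permutation", seed = 4)
  expect_identical(names(which.max(pi)), "sep")
  expect_error(forest_importance(d, flavor = "oob_permutation", bootstrap = FALSE),
               "bootstrap")

  ei <- extra_trees_importance(d, seed = 4)
  expect_identical(names(which.max(ei)), "sep")
  expect_equal(sum(ei), 1, tolerance = 1e-12)
  expect_identical(ei, extra_trees_importance(d, seed = 4))
})

test_that("pure-noise features get near-uniform forest importances", {
  set.seed(10)
  n <- 2000
  d <- tibble::as_tibble(matrix(stats::rnorm(n * 10), n, 10,
                                dimnames = list(NULL, paste0("x", 1:10))))
  d$class <- factor(sample(c("pos", "neg"), n, replace = TRUE),
                    levels = c("pos", "neg"))
  fi <- forest_importance(d, seed = 1)
  expect_lt(max(fi) / min(fi), 3)
})

test_that("RFE keeps the dominant feature and orders by coefficient size", {
  d <- toy_binary(n = 200, seed = 8)
  res <- rfe_select(d, n_keep = 1)
  expect_identical(res$selected, "sep")
  expect_length(res$elimination_order, 3)

  # n_keep >= N keeps everything with a warning
  expect_warning(all_kept <- rfe_select(d, n_keep = 10), "keeping all")
  expect_setequal(all_kept$selected, c("sep", "noise1", "noise2", "noise3"))

  # first elimination = smallest |coefficient| of a single standardized fit
  xy <- liquidcascade:::selector_xy(d, "class", NULL)
  x <- liquidcascade:::standardize_matrix(xy$x)
  yy <- as.integer(xy$y == "pos")
  fit <- glmnet::glmnet(x, yy, family = "binomial", alpha = 0,
                        lambda = 1 / length(yy), standardize = FALSE)
  first_out <- names(sort(abs(fit$beta[, 1])))[1]
  expect_identical(res$elimination_order[1], first_out)
})

test_that("L1 selection is sparse, seeded by data only, and monotone in C", {
  d <- toy_binary(n = 200, seed = 12)
  strong <- l1_select(d, C = 0.01, n_keep = 2)
  expect_identical(strong$selected[1], "sep")

  weak <- l1_select(d, C = 1.0, n_keep = 2)
  expect_lte(sum(strong$beta != 0), sum(weak$beta != 0))

  # C -> 0: everything shrinks to zero, flagged
  expect_warning(null_fit <- l1_select(d, C = 1e-8, n_keep = 2), "zero")
  expect_true(all(null_fit$beta == 0))

  # on separable data with mild regularization the separator is nonzero
  expect_gt(abs(weak$beta[["sep"]]), 0)
})
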