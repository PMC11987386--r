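test_that("metric identities hold on random confusion matrices", {
  set.seed(14)
  for (i in 1:50) {
    n <- 200
    truth <- factor(sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.4, 0.6)),
                    levels = c("pos", "neg"))
    prob <- stats::runif(n)
    m <- binary_metrics(truth, prob = prob)
    expect_equal(m$acc, (m$tp + m$tn) / (m$tp + m$fp + m$fn + m$tn))
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    expect_equal(m$ba, (m$recall + m$specificity) / 2)
    expect_equal(m$fpr, m$fp / (m$fp + m$tn))
    expect_true(all(unlist(m[c("acc", "precision", "recall", "f1",
                               "specificity", "ba", "fpr", "auc")]) >= 0))
    expect_true(all(unlist(m[c("acc", "precision", "recall", "f1",
                               "specificity", "ba", "fpr", "auc")]) <= 1))
  }
})

test_that("perfect predictions score 1 everywhere", {
  truth <- factor(rep(c("pos", "neg"), 10), levels = c("pos", "neg"))
  m <- binary_metrics(truth, truth, prob = ifelse(truth == "pos", 0.9, 0.1))
  expect_equal(unlist(m[c("acc", "precision", "recall", "f1",
                          "specificity", "ba", "auc")]),
               c(acc = 1, precision = 1, recall = 1, f1 = 1,
                 specificity = 1, ba = 1, auc = 1))
  expect_equal(m$fpr, 0)
})

test_that("zero denominators are flagged undefined, never silent zeros", {
  truth <- factor(c("pos", "pos", "neg", "neg"), levels = c("pos", "neg"))
  est <- factor(rep("neg", 4), levels = c("pos", "neg"))  # no predicted positives
  m <- binary_metrics(truth, est)
  expect_true(is.na(m$precision))
  expect_match(m$undefined, "precision")
  # undefined inputs propagate through aggregation with provenance
  agg <- aggregate_levels(dplyr::bind_rows(m, m))
  expect_true(is.na(agg$precision))
  expect_match(agg$undefined, "precision")
  expect_false(is.na(agg$acc))
})

test_that("AUC equals the brute-force pairwise Mann-Whitney oracle", {
  set.seed(8)
  for (i in 1:20) {
    n <- 10
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    score <- sample(seq_len(6), n, replace = TRUE)  # force ties
    # exhaustive pairwise comparison with half-credit ties
    pairs <- expand.grid(p = which(pos), q = which(!pos))
    oracle <- mean(ifelse(score[pairs$p] > score[pairs$q], 1,
                          ifelse(score[pairs$p] == score[pairs$q], 0.5, 0)))
    expect_equal(mann_whitney_auc(pos, score), oracle, tolerance = 1e-12)
  }
})

test_that("AUC invariances: monotone transforms, reversal, pROC agreement", {
  skip_if_not_installed("pROC")
  set.seed(9)
  pos <- rep(c(TRUE, FALSE), each = 30)
  score <- stats::rnorm(60) + pos
  a <- mann_whitney_auc(pos, score)
  expect_equal(mann_whitney_auc(pos, exp(score)), a)
  expect_equal(mann_whitney_auc(pos, rank(score)), a)
  expect_equal(mann_whitney_auc(pos, -score), 1 - a)
  oracle <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = score, quiet = TRUE, direction = "<")))
  expect_equal(a, oracle, tolerance = 1e-12)
  # trapezoidal area over roc_points agrees too
  pts <- roc_points(pos, score)
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  expect_equal(trap, a, tolerance = 1e-12)
  expect_error(mann_whitney_auc(rep(TRUE, 5), stats::rnorm(5)), "one class")
})

test_that("macro aggregation is the plain mean and permutation-invariant", {
  reports <- dplyr::bind_rows(
    binary_metrics(factor(c("p", "p", "n", "n"), levels = c("p", "n")),
                   factor(c("p", "p", "n", "n"), levels = c("p", "n"))),
    binary_metrics(factor(c("p", "p", "n", "n"), levels = c("p", "n")),
                   factor(c("p", "n", "n", "n"), levels = c("p", "n")))
  )
  agg <- aggregate_levels(reports)
  expect_equal(agg$acc, mean(reports$acc))
  expect_equal(agg$acc, (1 + 0.75) / 2)
  shuffled <- aggregate_levels(reports[2:1, ])
  expect_equal(agg$acc, shuffled$acc)
  # identical reports aggregate to themselves
  same <- aggregate_levels(reports[c(1, 1), ])
  expect_equal(same$acc, reports$acc[1])
  # weighted option
  w <- aggregate_levels(reports, weights = c(3, 1))
  expect_equal(w$acc, (3 * 1 + 1 * 0.75) / 4)
})

test_that("assay cost model prices panels correctly", {
  full <- assay_cost(biomarker_panel())
  expect_equal(full$cost_usd, 193.5)
  expect_equal(full$hours, 97.5)
  expect_identical(full$n_assays, 39L)

  empty <- assay_cost(character(0))
  expect_equal(empty$cost_usd, 0)
  expect_equal(empty$hours, 0)

  routine <- assay_cost(c("AFP", "CA 19-9", "CA 125", "CEA", "Prolactin", "CA 15-3"))
  expect_equal(routine$cost_usd, 12)
  expect_equal(routine$hours, 15)

  expect_error(assay_cost("NotAMarker"), "NotAMarker")
})
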