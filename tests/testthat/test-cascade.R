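test_that("default cohort peels into seven levels in count order", {
  co <- simulate_cohort(cohort_config(), seed = 21)
  cas <- build_cascade(co)
  expect_length(cas, 7)
  expect_identical(vapply(cas, function(l) l$positive, character(1)),
                   c("Cancer", "Colorectum", "Breast", "UpperGI",
                     "Lung", "Pancreas", "Ovary"))
  expect_identical(cas[[7]]$negative_name, "Liver")
  # terminal level holds exactly the last two classes
  expect_identical(nrow(cas[[7]]$data), 54L + 44L)

  # conservation: each cancer class is resolved exactly once — peeled
  # positives at levels 2..6 plus both classes of the terminal contest
  pos_counts <- vapply(cas[-1], function(l) sum(l$data$class == l$positive),
                       numeric(1))
  expect_identical(sum(pos_counts) + nrow(cas[[7]]$data) - pos_counts[6], 1005)
  # monotone shrinkage
  sizes <- vapply(cas, function(l) nrow(l$data), numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("degenerate class structures are handled", {
  co <- multiclass_cohort()
  # empty classes are dropped with a warning
  expect_warning(cas <- build_cascade(co), "0 rows")
  expect_length(cas, 3)

  # two-class input gives a single level, positive = larger class
  two <- co[co$label %in% c("Normal", "Colorectum"), ]
  two$label <- droplevels(two$label)
  expect_warning(cas2 <- build_cascade(two), "single-level")
  expect_length(cas2, 1)
  expect_identical(cas2[[1]]$positive, "Normal")  # 120 > 80
})

test_that("stratified split hits per-class test counts and is deterministic", {
  co <- simulate_cohort(cohort_config(), seed = 22)
  lv <- build_cascade(co)[[1]]
  lv <- split_level(lv, test_fraction = 0.10, seed = 99)
  test_classes <- table(lv$data$class[lv$test])
  expect_identical(as.integer(test_classes[["Normal"]]), 81L)
  expect_identical(as.integer(test_classes[["Cancer"]]), 101L)
  # train and test partition the rows
  expect_identical(sort(c(lv$train, lv$test)), seq_len(nrow(lv$data)))

  again <- split_level(build_cascade(co)[[1]], test_fraction = 0.10, seed = 99)
  expect_identical(lv$test, again$test)
  other <- split_level(build_cascade(co)[[1]], test_fraction = 0.10, seed = 100)
  expect_false(identical(lv$test, other$test))
})

test_that("half split of a balanced 10+10 level is exactly 5+5", {
  co <- small_cohort(n_normal = 10, n_cancer = 10, seed = 1)
  lv <- suppressWarnings(build_cascade(co))[[1]]
  lv <- split_level(lv, test_fraction = 0.5, seed = 3)
  expect_identical(as.integer(table(lv$data$class[lv$test])), c(5L, 5L))
})

test_that("split errors when a class cannot be partitioned", {
  co <- small_cohort(n_normal = 30, n_cancer = 30, seed = 2)
  lv <- suppressWarnings(build_cascade(co))[[1]]
  lv$data <- lv$data[c(which(lv$data$class == "Cancer"),
                       which(lv$data$class == "Normal")[1]), ]
  expect_error(split_level(lv, seed = 1), "fewer than 2")
})

test_that("routing follows the threshold rule and is exhaustive", {
  positives <- c("Cancer", "Colorectum", "Breast", "UpperGI",
                 "Lung", "Pancreas", "Ovary")
  route <- function(p) liquidcascade:::route_decision(p, positives, "Liver")

  # early exit at level 1
  r <- route(c(0.1, rep(0.9, 6)))
  expect_identical(r$label, "Normal")
  expect_length(r$trace, 1)

  # descend two levels then stop at breast
  r <- route(c(0.9, 0.2, 0.8, rep(0, 4)))
  expect_identical(r$label, "Breast")
  expect_length(r$trace, 3)

  # full descent, terminal argmax picks the negative side
  r <- route(c(0.9, rep(0.2, 5), 0.3))
  expect_identical(r$label, "Liver")
  expect_length(r$trace, 7)
  r <- route(c(0.9, rep(0.2, 5), 0.6))
  expect_identical(r$label, "Ovary")

  # exhaustive and exclusive over random traces
  set.seed(42)
  labs <- replicate(200, route(stats::runif(7))$label)
  expect_true(all(labs %in% c("Normal", positives[-1], "Liver")))
})

test_that("trained cascade routes samples end to end", {
  co <- multiclass_cohort(seed = 31)
  cas <- suppressWarnings(build_cascade(co))
  cas <- split_cascade(cas, seed = 7)
  bundle <- train_cascade(cas, k = 5, seed = 13)
  test_rows <- co[1:20, ]
  routed <- predict_cascade(bundle, test_rows)
  expect_tibble(routed)
  expect_identical(nrow(routed), 20L)
  expect_true(all(routed$label_pred %in% c("Normal", "Colorectum", "Breast", "Lung")))
  expect_true(all(routed$n_levels_visited >= 1 & routed$n_levels_visited <= 3))

  # a missing feature is a routing error naming it
  broken <- test_rows[setdiff(names(test_rows), "age")]
  expect_error(predict_cascade(bundle, broken), "age")
})
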