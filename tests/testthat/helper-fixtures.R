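# Fixtures are built in code; nothing is read from disk.

# a small two-class cohort with planted signal in the cancer class
small_cohort <- function(n_normal = 120, n_cancer = 80, seed = 1,
                         effect = 1.5) {
  cfg <- cohort_config(
    class_sizes = c(Normal = n_normal, Colorectum = n_cancer),
    effect_size = effect
  )
  suppressWarnings(simulate_cohort(cfg, seed = seed))
}

# a binary-labeled table with named features and a clean separator column
toy_binary <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("pos", "neg"), each = n / 2), levels = c("pos", "neg"))
  tibble::tibble(
    sep = ifelse(y == "pos", 1, 0) + stats::rnorm(n, sd = 0.05),
    noise1 = stats::rnorm(n),
    noise2 = stats::rnorm(n),
    noise3 = stats::rnorm(n),
    class = y
  )
}

# four-class cohort used by cascade tests (all seven registry levels are
# exercised by the pipeline tests instead)
multiclass_cohort <- function(seed = 1) {
  cfg <- cohort_config(class_sizes = c(
    Normal = 120, Colorectum = 80, Breast = 50, Lung = 40
  ))
  suppressWarnings(simulate_cohort(cfg, seed = seed))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
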