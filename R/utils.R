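#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#' @importFrom tibble tibble as_tibble
NULL

# Closed label vocabulary, ordered by the default class sizes (descending
# within the cancers) so cascade peeling order on the default cohort is
# also the vocabulary order.
cancer_labels <- function() {
  c("Colorectum", "Breast", "UpperGI", "Lung", "Pancreas", "Ovary", "Liver")
}

all_labels <- function() c("Normal", cancer_labels())

sex_levels <- function() c("female", "male")

ethnicity_levels <- function() {
  c("Caucasian", "Asian", "Black", "Hispanic", "Other")
}

# Fan a single user-facing seed out into independent per-stage seeds.
# set.seed on the master seed, then draw n 31-bit integers; stage i of a
# rerun with the same master seed always receives the same sub-seed, so
# stages can be rerun in isolation reproducibly.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

# z-score columns of a numeric matrix; constant columns map to 0 rather
# than NaN (selectors must tolerate degenerate features).
standardize_matrix <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  scale(x, center = mu, scale = sd)[, , drop = FALSE]
}

# Feature matrix for model fitting/selection: numeric biomarkers plus
# encoded demographics. sex -> {0,1}, ethnicity -> integer codes in
# vocabulary order (the encoding is recorded in bundle manifests).
encode_features <- function(table, features = NULL) {
  cols <- setdiff(names(table), c("sample_id", "label", "class"))
  if (!is.null(features)) cols <- intersect(cols, features)
  out <- lapply(table[cols], function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    if (is.factor(col) || is.character(col)) {
      col <- as.character(col)
      if (all(col %in% sex_levels() | is.na(col))) {
        return(as.numeric(match(col, sex_levels()) - 1))
      }
      return(as.numeric(match(col, ethnicity_levels()) - 1))
    }
    as.numeric(col)
  })
  m <- do.call(cbind, out)
  colnames(m) <- cols
  rownames(m) <- NULL
  m
}

is_binary_class <- function(y) {
  length(unique(y[!is.na(y)])) == 2
}
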