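# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

default_informative_map <- function(effect = 1) {
  plant <- function(markers) stats::setNames(rep(effect, length(markers)), markers)
  list(
    Colorectum = plant(c("CEA", "CA19-9", "TIMP-1", "OPN", "HGF")),
    Breast     = plant(c("CA 15-3", "sHER2/sEGFR2/sErbB2", "Prolactin", "Leptin", "FGF2")),
    UpperGI    = plant(c("TGFa", "Midkine", "CD44", "G-CSF", "IL-8")),
    Lung       = plant(c("CYFRA 21-1", "NSE", "sEGFR", "GDF15", "IL-6")),
    Pancreas   = plant(c("CA19-9", "OPG", "AXL", "Angiopoietin-2", "Mesothelin")),
    Ovary      = plant(c("CA-125", "HE4", "Follistatin", "Kallikrein-6", "Endoglin")),
    Liver      = plant(c("AFP", "OPN", "DKK1", "sFas", "Thrombospondin-2"))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of the Cohen et al. multi-cancer plasma
#' cohort: 1,817 samples split over one control and seven cancer classes
#' (Normal 812, Colorectum 388, Breast 209, UpperGI 113, Lung 104,
#' Pancreas 93, Ovary 54, Liver 44), right-skewed non-negative biomarker
#' concentrations, demographics matching the published marginals, and an
#' omega score computed from simulated per-well mutation evidence.
#'
#' Each cancer class carries a set of planted informative biomarkers whose
#' log-concentration is shifted upward by `effect_size` log-standard
#' deviations; these are the ground truth the feature-selection stage is
#' expected to recover.
#'
#' @param class_sizes Named integer vector, label -> row count.
#' @param informative_map Named list, label -> named numeric vector of
#'   per-marker log-scale shifts (in units of `noise_sd`).
#' @param effect_size Default shift used when `informative_map` is not
#'   given, in log-standard-deviation units.
#' @param noise_sd Log-scale dispersion of biomarker concentrations.
#' @param omega_shift Strength of the cfDNA mutation signal in cancer
#'   rows: how strongly the normal-distribution p-value is depressed,
#'   raising the omega score in expectation.
#' @param n_wells Sequencing wells per sample.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(class_sizes = NULL, informative_map = NULL,
                          effect_size = 1, noise_sd = 1,
                          omega_shift = 1.5, n_wells = 4) {
  class_sizes <- class_sizes %||% c(
    Normal = 812, Colorectum = 388, Breast = 209, UpperGI = 113,
    Lung = 104, Pancreas = 93, Ovary = 54, Liver = 44
  )
  if (any(class_sizes < 0)) stop("class counts must be non-negative")
  bad <- setdiff(names(class_sizes), all_labels())
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  informative_map <- informative_map %||% default_informative_map(effect_size)
  stopifnot(all(unlist(lapply(informative_map, is.finite))))
  structure(
    list(class_sizes = class_sizes, informative_map = informative_map,
         noise_sd = noise_sd, omega_shift = omega_shift, n_wells = n_wells),
    class = "cohort_config"
  )
}

#' Simulate a liquid-biopsy cohort with planted signal
#'
#' Draws biomarker concentrations log-normally (per-marker baseline on the
#' log scale, dispersion `noise_sd`), shifts each class's planted
#' informative markers by the configured effect, samples demographics from
#' published-cohort-like marginals (controls mean age 49, cancers 63;
#' breast and ovarian cancers female), and computes a per-sample omega
#' score via [omega_score()] from simulated wells: cancer rows have their
#' normal-distribution p-values stochastically depressed, so their omega
#' scores are positive in expectation.
#'
#' The output is deterministic given `seed`; class counts are exact, not
#' stochastic. The planted ground truth is attached as
#' `attr(x, "planted")`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; fully determines the output.
#' @return A validated cohort tibble (see [read_cohort()]).
#' @export
#' @examples
#' small <- cohort_config(class_sizes = c(Normal = 40, Colorectum = 25, Breast = 15))
#' cohort <- simulate_cohort(small, seed = 1)
#' table(cohort$label)
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  sizes <- config$class_sizes[config$class_sizes > 0]
  if (length(sizes) < 2) stop("at least 2 classes with nonzero counts are required")
  with_seed(seed, {
    labels <- rep(names(sizes), times = sizes)
    n <- length(labels)
    markers <- biomarker_panel()
    p <- length(markers)

    # per-marker baseline log-concentration: fixed spread so assays live on
    # different scales, as real panels do (ng/mL vs pg/mL ranges)
    baseline <- stats::setNames(seq(0, 4, length.out = p), markers)
    logx <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p,
                   dimnames = list(NULL, markers))
    logx <- sweep(logx, 2, baseline[markers], "+")
    for (cls in intersect(names(config$informative_map), labels)) {
      shift <- config$informative_map[[cls]]
      keep <- intersect(names(shift), markers)
      rows <- which(labels == cls)
      for (mk in keep) {
        logx[rows, mk] <- logx[rows, mk] + shift[[mk]] * config$noise_sd
      }
    }
    x <- exp(logx)

    is_cancer <- labels != "Normal"
    age <- ifelse(is_cancer,
                  stats::rnorm(n, 63, 12),
                  stats::rnorm(n, 49, 14))
    age <- round(pmin(pmax(age, 17), 93))
    sex <- ifelse(stats::runif(n) < ifelse(is_cancer, 543 / 1005, 378 / 812),
                  "female", "male")
    sex[labels %in% c("Breast", "Ovary")] <- "female"
    eth_cancer <- c(675, 301, 14, 1, 14) / 1005
    eth_normal <- c(332, 22, 154, 76, 228) / 812
    ethnicity <- vapply(seq_len(n), function(i) {
      pr <- if (is_cancer[i]) eth_cancer else eth_normal
      sample(ethnicity_levels(), 1, prob = pr)
    }, character(1))

    omega <- vapply(seq_len(n), function(i) {
      uid <- stats::rpois(config$n_wells, 500) + 1
      p_base <- stats::runif(config$n_wells, 0.05, 1)
      if (is_cancer[i]) {
        p_normal <- p_base * exp(-config$omega_shift * stats::rexp(config$n_wells))
        p_cancer <- p_base
      } else {
        p_normal <- p_base
        p_cancer <- stats::runif(config$n_wells, 0.05, 1)
      }
      omega_score(uid, p_cancer = p_cancer, p_normal = p_normal)
    }, numeric(1))

    out <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
    out$sample_id <- sprintf("S%04d", seq_len(n))
    out$age <- age
    out$sex <- sex
    out$ethnicity <- ethnicity
    out$omega_score <- omega
    out$label <- labels
    out <- validate_cohort(out)
    attr(out, "planted") <- config$informative_map[names(config$informative_map) %in% labels]
    out
  })
}

#' Flag biomarker cells missing completely at random
#'
#' Each of the 39 biomarker cells is independently set to `NA` with
#' probability `rate`; labels, demographics and omega scores are left
#' untouched. Missing-at-random or informative mechanisms are out of
#' scope.
#'
#' @param table A cohort tibble.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed for the mask.
#' @return The cohort with missing biomarker cells flagged `NA`.
#' @export
inject_missingness <- function(table, rate, seed = 1) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)")
  }
  if (rate == 0) return(table)
  with_seed(seed, {
    for (bm in biomarker_panel()) {
      mask <- stats::runif(nrow(table)) < rate
      table[[bm]][mask] <- NA_real_
    }
    table
  })
}

#' k-nearest-neighbour imputation of missing biomarker cells
#'
#' Replaces each missing biomarker cell by the mean of that biomarker over
#' the k nearest samples, with distances computed as scaled Euclidean
#' distance on standardized features, ignoring coordinates that are
#' missing in either row of a pair. Observed cells are never altered.
#'
#' @param table A cohort tibble, possibly with `NA` biomarker cells.
#' @param k Number of neighbours (default 5).
#' @return The cohort with no remaining missing biomarker cells.
#' @export
impute_knn <- function(table, k = 5) {
  stopifnot(k >= 1)
  markers <- biomarker_panel()
  x <- as.matrix(table[markers])
  if (!anyNA(x)) return(table)
  all_missing <- markers[colSums(!is.na(x)) == 0]
  if (length(all_missing) > 0) {
    stop("cannot impute: feature(s) missing in every row: ",
         paste(all_missing, collapse = ", "))
  }

  feats <- cbind(x, encode_features(table, c("age", "sex", "ethnicity", "omega_score")))
  z <- standardize_matrix_na(feats)
  w <- !is.na(z)
  a <- z
  a[!w] <- 0
  sq <- a * a
  # pairwise sum over mutually observed coords of (zi - zj)^2, rescaled by
  # the fraction of usable coordinates (nan-Euclidean convention)
  cross <- tcrossprod(a)
  ssum <- sq %*% t(w) + w %*% t(sq) - 2 * cross
  nobs <- w %*% t(w)
  d2 <- ifelse(nobs > 0, ncol(z) * ssum / nobs, Inf)
  diag(d2) <- Inf

  need <- which(rowSums(is.na(x)) > 0)
  for (i in need) {
    nb <- order(d2[i, ])
    for (j in which(is.na(x[i, ]))) {
      donors <- nb[!is.na(x[nb, j])]
      donors <- donors[seq_len(min(k, length(donors)))]
      x[i, j] <- mean(x[donors, j])
    }
  }
  table[markers] <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
  table
}

# standardize columns using observed-cell means/sds, keeping NAs
standardize_matrix_na <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[sd == 0 | !is.finite(sd)] <- 1
  scale(x, center = mu, scale = sd)[, , drop = FALSE]
}
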