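#' Read and validate a liquid-biopsy cohort table
#'
#' Reads a CSV/TSV with one row per blood sample: the 39 plasma protein
#' biomarker concentrations, age, sex, ethnicity, the cfDNA omega score and
#' a class label. Column names are matched against the canonical panel
#' spelling via [normalize_biomarker_names()], so dialects such as
#' "CA 15–3" (en-dash) are accepted. Biomarker cells that are empty or
#' "NA" are flagged missing (`NA`), not imputed; imputation is an explicit
#' pipeline stage ([impute_knn()]).
#'
#' Rows whose label is outside the closed nine-class vocabulary
#' (Normal plus the seven cancer classes, with Esophagus/Stomach accepted
#' and mapped to UpperGI) are dropped with a warning naming the offending
#' labels.
#'
#' @param path Path to a delimited file with a header row.
#' @param schema Optional named list remapping column roles, e.g.
#'   `list(label = "diagnosis", age = "Age")`. Roles: `sample_id`, `age`,
#'   `sex`, `ethnicity`, `omega_score`, `label`.
#' @return A validated cohort tibble (a "feature table"): `sample_id`,
#'   one column per panel biomarker, `age`, `sex`, `ethnicity`,
#'   `omega_score`, `label`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA"))
  validate_cohort(raw, schema = schema)
}

#' Coerce and validate a data frame as a cohort feature table
#'
#' @param data A data frame with biomarker, demographic, omega-score and
#'   label columns.
#' @inheritParams read_cohort
#' @return A validated cohort tibble; see [read_cohort()].
#' @export
validate_cohort <- function(data, schema = NULL) {
  data <- tibble::as_tibble(data)
  schema <- schema %||% list()
  for (role in names(schema)) {
    if (!schema[[role]] %in% names(data)) {
      stop("schema maps role '", role, "' to absent column '", schema[[role]], "'")
    }
    names(data)[names(data) == schema[[role]]] <- role
  }
  names(data) <- ifelse(
    names(data) %in% c("sample_id", "age", "sex", "ethnicity", "omega_score", "label"),
    names(data), normalize_biomarker_names(names(data))
  )

  required <- c(biomarker_panel(), "age", "sex", "ethnicity", "omega_score", "label")
  absent <- setdiff(required, names(data))
  if (length(absent) > 0) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }
  if (!"sample_id" %in% names(data)) {
    data$sample_id <- sprintf("S%04d", seq_len(nrow(data)))
  }
  if (anyDuplicated(data$sample_id)) stop("sample_id values must be unique")

  for (bm in biomarker_panel()) {
    col <- data[[bm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        stop("non-numeric value in biomarker '", bm, "' at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      col <- num
    }
    if (any(!is.na(col) & (col < 0 | !is.finite(col)))) {
      stop("biomarker '", bm, "' has negative or non-finite values")
    }
    data[[bm]] <- col
  }

  data$label <- as.character(data$label)
  data$label[data$label %in% c("Esophagus", "Stomach")] <- "UpperGI"
  bad_labels <- setdiff(unique(data$label), all_labels())
  if (length(bad_labels) > 0) {
    n_bad <- sum(data$label %in% bad_labels)
    warning("dropping ", n_bad, " row(s) with unknown label(s): ",
            paste(bad_labels, collapse = ", "))
    data <- data[!data$label %in% bad_labels, , drop = FALSE]
  }
  data$label <- factor(data$label, levels = all_labels())
  data$sex <- factor(as.character(data$sex), levels = sex_levels())
  data$ethnicity <- factor(as.character(data$ethnicity), levels = ethnicity_levels())
  data$age <- as.numeric(data$age)
  data$omega_score <- as.numeric(data$omega_score)

  dplyr::select(data, "sample_id", dplyr::all_of(biomarker_panel()),
                "age", "sex", "ethnicity", "omega_score", "label")
}

#' Write a cohort table to CSV
#'
#' Full-precision round trip: `read_cohort(write_cohort(x, f))` preserves
#' all values.
#'
#' @param table A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Count missing biomarker cells in a cohort
#'
#' @param table A cohort tibble.
#' @return A tibble with `n_cells`, `n_missing` and `rate` over the
#'   39 biomarker columns only (demographics and labels excluded).
#' @export
missingness_summary <- function(table) {
  m <- as.matrix(table[biomarker_panel()])
  tibble::tibble(
    n_cells = length(m),
    n_missing = sum(is.na(m)),
    rate = sum(is.na(m)) / length(m)
  )
}

#' Omega score from per-well mutation evidence
#'
#' The cfDNA mutation signal of one plasma sample is summarized across its
#' sequencing wells as
#' \deqn{\Omega = \sum_i \frac{u_i}{\sum_j u_j} \, \ln\frac{p^C_i}{p^N_i}}
#' where \eqn{u_i} is the count of unique identifier (UID) sequences in
#' well \eqn{i} and \eqn{p^C_i}, \eqn{p^N_i} are the p-values of the
#' sample's mutant-allele frequency in the cancer and normal MAF
#' distributions of that well. Wells with more UID templates carry
#' proportionally more weight; the score is invariant to uniform rescaling
#' of the UID counts and flips sign when the two p-value sets are swapped.
#'
#' @param wells A data frame with columns `uid_count`, `p_cancer`,
#'   `p_normal` (one row per well), or three separate vectors passed as
#'   `uid_count`, `p_cancer`, `p_normal`.
#' @param p_cancer,p_normal Per-well p-values in (0, 1], used when `wells`
#'   is a numeric vector of UID counts.
#' @return The omega score, a single real number.
#' @export
#' @examples
#' omega_score(data.frame(uid_count = c(3, 1),
#'                        p_cancer = c(0.01, 0.5),
#'                        p_normal = c(0.5, 0.5)))
omega_score <- function(wells, p_cancer = NULL, p_normal = NULL) {
  if (is.data.frame(wells)) {
    uid_count <- wells$uid_count
    p_cancer <- wells$p_cancer
    p_normal <- wells$p_normal
  } else {
    uid_count <- wells
  }
  if (length(uid_count) < 1) stop("at least one well is required")
  stopifnot(length(p_cancer) == length(uid_count),
            length(p_normal) == length(uid_count))
  if (any(p_cancer <= 0) || any(p_normal <= 0)) {
    stop("p-values must be strictly positive")
  }
  total <- sum(uid_count)
  if (!is.finite(total) || total <= 0) stop("total UID count must be positive")
  w <- uid_count / total
  sum(w * log(p_cancer / p_normal))
}
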