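#' The 39-marker plasma protein panel
#'
#' Names of the 39 plasma protein biomarkers measured in the Cohen et al.
#' multi-cancer cohort, in canonical spelling. Together with age, sex,
#' ethnicity and the cfDNA omega score these form the 43 features the
#' cascade consumes.
#'
#' @return A character vector of length 39.
#' @export
#' @examples
#' length(biomarker_panel())
biomarker_panel <- function() {
  c(
    "AFP", "Angiopoietin-2", "AXL", "CA-125", "CA 15-3", "CA19-9", "CD44",
    "CEA", "CYFRA 21-1", "DKK1", "Endoglin", "FGF2", "Follistatin",
    "G-CSF", "Galectin-3", "GDF15", "HE4", "HGF", "IL-6", "IL-8",
    "Kallikrein-6", "Leptin", "Mesothelin", "Midkine", "Myeloperoxidase",
    "NSE", "OPG", "OPN", "PAR", "Prolactin", "sEGFR", "sFas",
    "sHER2/sEGFR2/sErbB2", "SHBG", "sPECAM-1", "TGFa",
    "Thrombospondin-2", "TIMP-1", "TIMP-2"
  )
}

#' Normalize biomarker names to the canonical panel spelling
#'
#' Published tables mix typographic dialects for the same assay: hyphen vs
#' en-dash ("CA 15-3" vs "CA 15–3"), spaced vs unspaced ("CA 19-9" vs
#' "CA19-9", "CA 125" vs "CA-125"). This maps any such variant onto the
#' spelling used by [biomarker_panel()]; names with no known variant pass
#' through unchanged.
#'
#' @param x Character vector of biomarker names.
#' @return Character vector of the same length, canonical spellings.
#' @export
#' @examples
#' normalize_biomarker_names(c("CA 19–9", "CA 125", "ca 15-3"))
normalize_biomarker_names <- function(x) {
  key <- tolower(gsub("[–—-]", "-", x))
  key <- gsub("\\s+", " ", trimws(key))
  # collapse spacing/dash variants of the CA antigens to one key each
  collapsed <- gsub("[ -]", "", key)
  key[collapsed == "ca199"] <- "ca19-9"
  key[collapsed == "ca125"] <- "ca-125"
  key[collapsed == "ca153"] <- "ca 15-3"
  canon <- biomarker_panel()
  lookup <- stats::setNames(canon, tolower(canon))
  out <- unname(lookup[key])
  ifelse(is.na(out), x, out)
}

#' Per-assay cost and turnaround table
#'
#' Default clinical-lab cost model for the panel: the six biomarkers in
#' routine clinical use (AFP, CA 19-9, CA 125, CEA, Prolactin, CA 15-3)
#' cost $2 per assay; the remaining, more specialized markers cost $5.5.
#' Every assay takes 2.5 hours of processing time.
#'
#' @return A tibble with columns `biomarker`, `cost_usd`, `hours`.
#' @export
cost_table <- function() {
  routine <- c("AFP", "CA19-9", "CA-125", "CEA", "Prolactin", "CA 15-3")
  tibble::tibble(
    biomarker = biomarker_panel(),
    cost_usd = ifelse(biomarker_panel() %in% routine, 2, 5.5),
    hours = 2.5
  )
}

#' Total cost and turnaround of a biomarker panel
#'
#' Sums per-assay dollar cost and processing hours over a panel, under the
#' serial-processing convention (hours add, they do not overlap). The full
#' 39-marker panel under the default [cost_table()] comes to $193.5 and
#' 97.5 h.
#'
#' @param panel Character vector of biomarker names (any spelling dialect
#'   accepted, see [normalize_biomarker_names()]).
#' @param costs A cost table as returned by [cost_table()].
#' @return A tibble with one row: `n_assays`, `cost_usd`, `hours`.
#' @export
#' @examples
#' assay_cost(biomarker_panel())
assay_cost <- function(panel, costs = cost_table()) {
  stopifnot(is.data.frame(costs), all(c("biomarker", "cost_usd", "hours") %in% names(costs)))
  stopifnot(all(costs$cost_usd >= 0), all(costs$hours >= 0))
  panel <- normalize_biomarker_names(panel)
  unknown <- setdiff(panel, costs$biomarker)
  if (length(unknown) > 0) {
    stop("unknown biomarker(s) in panel: ", paste(unknown, collapse = ", "))
  }
  idx <- match(panel, costs$biomarker)
  tibble::tibble(
    n_assays = length(panel),
    cost_usd = sum(costs$cost_usd[idx]),
    hours = sum(costs$hours[idx])
  )
}
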