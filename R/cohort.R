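#' Published validation cohort: 56 colorectal cancer specimens
#'
#' Per-marker percentage allelic variabilities (integer percent, as printed)
#' for 56 FFPE colorectal cancer specimens with matched-normal tissue,
#' measured by capillary-electrophoresis fragment analysis on the Bethesda
#' panel, together with the IHC mismatch-repair status and BRAF subgroup for
#' each specimen. Columns prefixed `pub_` carry the originally reported
#' classification (unstable-marker count, NCI status, maximum variability,
#' MSI score and score-tier status) for cross-checking; a handful of reported
#' scores differ by one from the sum of the printed integer variabilities,
#' reflecting unrounded internal arithmetic in the source.
#'
#' @return tibble with one row per specimen
#' @seealso [cohort_ihc_labels()], [classify_variability()]
#' @export
specimen_cohort <- function() {
  path <- system.file("extdata", "specimen_variability.tsv", package = "msical",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' Cell-line dilution series: per-marker variabilities by MSI-H fraction
#'
#' Reported allelic variabilities for mixtures of an MSI-H cell line into an
#' MSS background at 5-100% MSI-H genomic material, used to establish the
#' assay's limit of detection (instability detectable down to 5%).
#'
#' @return tibble with one row per mixing fraction
#' @export
dilution_cohort <- function() {
  path <- system.file("extdata", "dilution_variability.tsv", package = "msical",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' IHC labels for the packaged validation cohort
#'
#' @param cohort a cohort tibble, by default [specimen_cohort()]
#' @return tibble `sample_id`, `ihc_status`, `subgroup` suitable for
#'   [concordance()]
#' @export
cohort_ihc_labels <- function(cohort = specimen_cohort()) {
  tibble::tibble(sample_id = cohort$sample_id,
                 ihc_status = cohort$ihc_status,
                 subgroup = cohort$subgroup)
}
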