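#' NCI marker-count classification
#'
#' Traditional Bethesda/NCI rule: a sample is MSS if no marker is unstable,
#' MSI-L if exactly one is, MSI-H if two or more are. A marker is unstable
#' when its allelic variability strictly exceeds the per-marker threshold.
#' Missing markers are skipped; if all five are missing the status is NA.
#'
#' @param variability numeric vector of per-marker allelic variabilities (%),
#'   NA for missing markers
#' @param threshold_pct instability threshold (default 2, strict `>`)
#' @return list with `n_unstable` (integer) and `status`
#'   (`"MSS"`/`"MSI-L"`/`"MSI-H"`, or NA when every marker is missing)
#' @examples
#' nci_status(c(4, 14, 0, 10, 3)) # 4 unstable markers -> MSI-H
#' @export
nci_status <- function(variability, threshold_pct = 2) {
  if (all(is.na(variability))) {
    return(list(n_unstable = NA_integer_, status = NA_character_))
  }
  n <- sum(variability > threshold_pct, na.rm = TRUE)
  status <- if (n == 0) "MSS" else if (n == 1) "MSI-L" else "MSI-H"
  list(n_unstable = as.integer(n), status = status)
}

#' MSI score: total allelic variability
#'
#' Sum of the per-marker allelic variabilities, theoretical range 0-500 for a
#' five-marker panel. Computed on unrounded values. Missing markers are
#' skipped (the score is not rescaled); all-missing gives NA.
#'
#' @inheritParams nci_status
#' @return the score (numeric)
#' @examples
#' msi_score(c(7, 0, 36, 0, 13)) # 56
#' @export
msi_score <- function(variability) {
  if (all(is.na(variability))) return(NA_real_)
  sum(variability, na.rm = TRUE)
}

#' Tier a sample by its MSI score
#'
#' MSS below the lower tier boundary, MSI-L on the closed interval between the
#' boundaries, MSI-H strictly above the upper boundary (defaults: MSS < 3,
#' MSI-L 3-5, MSI-H > 5). A score of exactly 5 is therefore MSI-L and 6 is
#' MSI-H.
#'
#' @param score MSI score (numeric, >= 0), NA allowed
#' @param panel an [msi_panel()] supplying the tier boundaries
#' @return `"MSS"`, `"MSI-L"` or `"MSI-H"` (NA for NA input)
#' @export
score_status <- function(score, panel = msi_panel()) {
  ifelse(is.na(score), NA_character_,
         ifelse(score < panel$score_msil_low, "MSS",
                ifelse(score <= panel$score_msil_high, "MSI-L", "MSI-H")))
}

#' Assemble a sample-level result from per-marker variabilities
#'
#' Computes the unstable-marker count and NCI status, the MSI score and its
#' tier, the maximum allelic variability, and the Toh score (total high-level
#' MSI, i.e. the MSI score reported only for score-tier MSI-H samples as a
#' measure of the degree of instability).
#'
#' @param variability named numeric vector of per-marker variabilities (%),
#'   names matching the panel's markers; NA marks a missing marker
#' @param panel an [msi_panel()]
#' @param sample_id identifier carried into the result
#' @return a one-row tibble: `sample_id`, one column per marker, `n_unstable`,
#'   `nci_status`, `max_variability_pct`, `msi_score`, `score_status`,
#'   `toh_score` (NA unless score-tier MSI-H), `qc`
#' @export
summarize_sample <- function(variability, panel = msi_panel(),
                             sample_id = NA_character_) {
  markers <- panel$markers$marker
  v <- stats::setNames(rep(NA_real_, length(markers)), markers)
  if (is.null(names(variability))) {
    stopifnot(length(variability) == length(markers))
    v[] <- variability
  } else {
    v[intersect(names(variability), markers)] <-
      variability[intersect(names(variability), markers)]
  }
  qc <- character()
  if (anyNA(v)) qc <- c(qc, paste0("missing_marker:", paste(markers[is.na(v)], collapse = ",")))
  nci <- nci_status(v, panel$marker_instability_threshold_pct)
  score <- msi_score(v)
  tier <- score_status(score, panel)
  if (all(is.na(v))) qc <- c(qc, "all_markers_missing")
  out <- tibble::tibble(sample_id = sample_id)
  for (m in markers) out[[m]] <- unname(v[m])
  out$n_unstable <- nci$n_unstable
  out$nci_status <- nci$status
  out$max_variability_pct <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  out$msi_score <- score
  out$score_status <- tier
  out$toh_score <- if (identical(tier, "MSI-H")) score else NA_real_
  out$qc <- join_flags(qc)
  out
}

#' Call MSI status for every sample in a paired peak table
#'
#' End-to-end caller: per-marker allelic variability via novel-peak detection,
#' then sample-level classification by both the NCI marker-count rule and the
#' MSI score.
#'
#' @param pairs an `msi_pairs` object from [read_peak_table()]
#' @param panel an [msi_panel()]
#' @return a sample-result tibble, one row per sample (see
#'   [summarize_sample()]); the per-marker long table is attached as attribute
#'   `marker_results`
#' @export
call_samples <- function(pairs, panel = attr(pairs, "panel") %||% msi_panel()) {
  mk <- marker_results(pairs, panel)
  samples <- unique(pairs$sample_id)
  rows <- lapply(samples, function(s) {
    sub <- mk[mk$sample_id == s, ]
    v <- stats::setNames(sub$variability_pct, sub$marker)
    res <- summarize_sample(v, panel, sample_id = s)
    extra <- join_flags(sub$qc)
    res$qc <- join_flags(c(res$qc, extra))
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "marker_results") <- mk
  out
}

#' Classify samples from a table of per-marker variabilities
#'
#' Convenience entry point when per-marker allelic variabilities are already
#' available (e.g. a published validation table) rather than raw peak data.
#'
#' @param tbl data frame with a `sample_id` column and one numeric column per
#'   panel marker (percent allelic variability; NA = missing marker)
#' @param panel an [msi_panel()]
#' @return a sample-result tibble, one row per input row
#' @examples
#' classify_variability(
#'   data.frame(sample_id = "ID 14", `BAT-25` = 4, `BAT-26` = 14,
#'              D5S346 = 0, D2S123 = 10, D17S250 = 3, check.names = FALSE)
#' )
#' @export
classify_variability <- function(tbl, panel = msi_panel()) {
  markers <- panel$markers$marker
  miss <- setdiff(markers, names(tbl))
  if (length(miss)) {
    stop("variability table is missing marker column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    v <- stats::setNames(as.numeric(unlist(tbl[i, markers])), markers)
    summarize_sample(v, panel, sample_id = as.character(tbl$sample_id[i]))
  })
  dplyr::bind_rows(rows)
}
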