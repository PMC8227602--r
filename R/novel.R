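#' Filter low-signal peaks as potential noise
#'
#' Removes peaks carrying less than `noise_fraction` of the trace's total
#' signal. The threshold is computed against the *pre-filter* total, and peaks
#' at exactly the threshold are retained (the filter boundary is `>=`). A
#' trace with zero total signal returns empty with QC flag `"zero_signal"`.
#'
#' @param peaks a trace tibble (`size_bp`, `rfu`), already gated to the marker
#'   window
#' @param noise_fraction fraction of total signal below which peaks are
#'   dropped; 0 returns the input unchanged
#' @return the filtered trace; attribute `qc` carries flags
#' @examples
#' tr <- peak_trace(c(100, 101, 102), c(98, 1, 1))
#' filter_noise(tr, 0.02) # only the 98-RFU peak survives
#' @export
filter_noise <- function(peaks, noise_fraction = 0.02) {
  total <- sum(peaks$rfu)
  if (total == 0) {
    out <- peaks[0, , drop = FALSE]
    attr(out, "qc") <- "zero_signal"
    return(out)
  }
  out <- peaks[peaks$rfu >= noise_fraction * total, , drop = FALSE]
  attr(out, "qc") <- character()
  out
}

#' Label tumour peaks as novel relative to the matched normal
#'
#' A tumour peak is *novel* — evidence of an instability-derived allele — iff
#' it survives the noise filter and
#' (a) lies at least `min_novel_distance_bp` from every peak of the
#'     (optionally noise-filtered) matched-normal trace, and
#' (b) lies no more than `max_outside_range_bp` outside the full range of
#'     normal peak sizes.
#' Both bounds are inclusive, and distances are computed on raw (possibly
#' fractional) sizes. Peaks beyond the extended range are treated as
#' artifacts: they are never novel but still count in the proportion
#' denominator (in `"pre"` mode), so they dilute rather than inflate the
#' variability.
#'
#' @param tumour,normal trace tibbles gated to the same marker window
#' @param panel an [msi_panel()]
#' @return a tibble of novel calls with one row per noise-surviving tumour
#'   peak: `size_bp`, `rfu`, `distance_to_nearest_normal_bp`,
#'   `within_extended_range`, `signal_proportion`, `is_novel`. If the normal
#'   trace is empty after preprocessing the attribute `missing` is TRUE (QC
#'   failure, not an error).
#' @export
label_novel <- function(tumour, normal, panel = msi_panel()) {
  norm <- if (panel$filter_normal) filter_noise(normal, panel$noise_fraction) else normal
  if (nrow(norm) == 0L) {
    out <- tibble::tibble(size_bp = numeric(), rfu = numeric(),
                          distance_to_nearest_normal_bp = numeric(),
                          within_extended_range = logical(),
                          signal_proportion = numeric(),
                          is_novel = logical())
    attr(out, "missing") <- TRUE
    return(out)
  }
  tum <- filter_noise(tumour, panel$noise_fraction)
  denom <- switch(panel$denominator_mode,
                  pre = sum(tumour$rfu),
                  post = sum(tum$rfu))
  lo <- min(norm$size_bp) - panel$max_outside_range_bp
  hi <- max(norm$size_bp) + panel$max_outside_range_bp
  if (nrow(tum) == 0L) {
    dist <- numeric()
    in_range <- logical()
    prop <- numeric()
  } else {
    dist <- vapply(tum$size_bp, function(s) min(abs(s - norm$size_bp)), numeric(1))
    in_range <- tum$size_bp >= lo & tum$size_bp <= hi
    prop <- if (denom > 0) tum$rfu / denom else rep(0, nrow(tum))
  }
  out <- tibble::tibble(
    size_bp = tum$size_bp,
    rfu = tum$rfu,
    distance_to_nearest_normal_bp = dist,
    within_extended_range = in_range,
    signal_proportion = prop,
    is_novel = dist >= panel$min_novel_distance_bp & in_range
  )
  attr(out, "missing") <- FALSE
  out
}

#' Per-marker percentage allelic variability
#'
#' The marker-level statistic of the caller: 100 x the summed signal
#' proportion of novel tumour peaks. A marker is called unstable when its
#' variability strictly exceeds `marker_instability_threshold_pct`.
#'
#' @param tumour,normal trace tibbles gated to the marker window; pass `NULL`
#'   for an absent trace to get a missing-marker result
#' @param panel an [msi_panel()]
#' @param marker marker name carried into the result
#' @return a one-row tibble: `marker`, `variability_pct`, `n_novel`,
#'   `unstable`, `missing`, `qc`, with the novel-call table attached as
#'   attribute `novel_calls`
#' @export
allelic_variability <- function(tumour, normal, panel = msi_panel(),
                                marker = NA_character_) {
  if (is.null(tumour) || is.null(normal)) {
    return(marker_result(marker, missing = TRUE, qc = "missing_trace"))
  }
  calls <- label_novel(tumour, normal, panel)
  if (isTRUE(attr(calls, "missing"))) {
    return(marker_result(marker, missing = TRUE, qc = "empty_normal"))
  }
  qc <- character()
  if (sum(tumour$rfu) == 0) qc <- c(qc, "zero_tumour_signal")
  v <- 100 * sum(calls$signal_proportion[calls$is_novel])
  res <- marker_result(
    marker,
    variability_pct = v,
    n_novel = sum(calls$is_novel),
    unstable = v > panel$marker_instability_threshold_pct,
    missing = FALSE,
    qc = join_flags(qc)
  )
  attr(res, "novel_calls") <- calls
  res
}

marker_result <- function(marker, variability_pct = NA_real_,
                          n_novel = NA_integer_, unstable = NA,
                          missing = FALSE, qc = "") {
  tibble::tibble(
    marker = marker,
    variability_pct = variability_pct,
    n_novel = as.integer(n_novel),
    unstable = unstable,
    missing = missing,
    qc = qc
  )
}

#' Per-marker results for every sample x marker pair
#'
#' @param pairs an `msi_pairs` object from [read_peak_table()]
#' @param panel an [msi_panel()]; defaults to the panel the pairs were read
#'   with
#' @return tibble with one row per sample x marker: `sample_id` plus the
#'   columns of [allelic_variability()]
#' @export
marker_results <- function(pairs, panel = attr(pairs, "panel") %||% msi_panel()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- allelic_variability(pairs$tumour[[i]], pairs$normal[[i]],
                               panel, marker = pairs$marker[i])
    res$sample_id <- pairs$sample_id[i]
    res
  })
  dplyr::relocate(dplyr::bind_rows(rows), "sample_id")
}
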