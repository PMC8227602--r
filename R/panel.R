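#' Panel configuration for MSI calling
#'
#' Holds the five-marker Bethesda/NCI panel definition and every threshold the
#' caller uses. All thresholds are exposed because instrument noise levels
#' differ between laboratories and the noise cut-off in particular is expected
#' to be re-calibrated locally.
#'
#' @param markers data frame with columns `marker`, `min_bp`, `max_bp` giving
#'   the per-marker fragment-size gating window in base pairs. Exactly five
#'   markers are required (the MSI score is reported out of 500, i.e. five
#'   markers x 100%). Defaults to the Bethesda panel with windows spanning the
#'   expected amplicon ranges.
#' @param noise_fraction fraction of total trace signal below which a peak is
#'   filtered as potential noise (default 0.02). Peaks at exactly the
#'   threshold are retained.
#' @param min_novel_distance_bp minimum distance (bp) from the nearest
#'   matched-normal peak for a tumour peak to count as novel (default 2,
#'   inclusive).
#' @param max_outside_range_bp maximum distance (bp) a novel peak may lie
#'   outside the full matched-normal peak-size range (default 10, inclusive).
#' @param marker_instability_threshold_pct per-marker allelic variability (%)
#'   above which the marker is called unstable; strictly greater-than
#'   (default 2).
#' @param score_msil_low,score_msil_high MSI-score tier boundaries: scores
#'   below `score_msil_low` are MSS, scores in
#'   `[score_msil_low, score_msil_high]` are MSI-L, scores strictly above
#'   `score_msil_high` are MSI-H (defaults 3 and 5).
#' @param filter_normal logical; apply the noise filter to the matched-normal
#'   trace before the novelty distance/range computation (default TRUE).
#' @param denominator_mode `"pre"` (default) computes novel-peak signal
#'   proportions over the total tumour-trace signal before noise filtering;
#'   `"post"` uses the post-filter total.
#'
#' @return an object of class `msi_panel`
#' @examples
#' panel <- msi_panel()
#' panel$markers
#' @export
msi_panel <- function(markers = default_markers(),
                      noise_fraction = 0.02,
                      min_novel_distance_bp = 2,
                      max_outside_range_bp = 10,
                      marker_instability_threshold_pct = 2,
                      score_msil_low = 3,
                      score_msil_high = 5,
                      filter_normal = TRUE,
                      denominator_mode = c("pre", "post")) {
  denominator_mode <- match.arg(denominator_mode)
  markers <- as.data.frame(markers)
  stopifnot(all(c("marker", "min_bp", "max_bp") %in% names(markers)))
  if (nrow(markers) != 5L) {
    stop("the panel must contain exactly five markers (MSI score is /500), got ",
         nrow(markers), call. = FALSE)
  }
  if (anyDuplicated(markers$marker)) stop("duplicate marker names in panel", call. = FALSE)
  if (any(markers$min_bp <= 0) || any(markers$max_bp <= markers$min_bp)) {
    stop("marker windows must satisfy 0 < min_bp < max_bp", call. = FALSE)
  }
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction >= 1) {
    stop("noise_fraction must be in [0, 1)", call. = FALSE)
  }
  for (nm in c("min_novel_distance_bp", "max_outside_range_bp",
               "marker_instability_threshold_pct", "score_msil_low",
               "score_msil_high")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop(nm, " must be a positive number", call. = FALSE)
    }
  }
  if (score_msil_high < score_msil_low) {
    stop("score_msil_high must be >= score_msil_low", call. = FALSE)
  }
  structure(
    list(
      markers = markers,
      noise_fraction = noise_fraction,
      min_novel_distance_bp = min_novel_distance_bp,
      max_outside_range_bp = max_outside_range_bp,
      marker_instability_threshold_pct = marker_instability_threshold_pct,
      score_msil_low = score_msil_low,
      score_msil_high = score_msil_high,
      filter_normal = isTRUE(filter_normal),
      denominator_mode = denominator_mode
    ),
    class = "msi_panel"
  )
}

#' Default Bethesda/NCI marker panel with size-gating windows
#'
#' Two quasi-monomorphic mononucleotide repeats (BAT-25, BAT-26) and three
#' dinucleotide repeats (D5S346, D2S123, D17S250). Windows bracket the
#' expected amplicon sizes generously; peaks outside the window are treated as
#' primer/ladder artifacts and dropped before any computation.
#'
#' @return data frame with columns `marker`, `min_bp`, `max_bp`
#' @export
default_markers <- function() {
  data.frame(
    marker = c("BAT-25", "BAT-26", "D5S346", "D2S123", "D17S250"),
    min_bp = c(100, 90, 90, 170, 130),
    max_bp = c(150, 140, 140, 240, 190),
    stringsAsFactors = FALSE
  )
}

#' @export
print.msi_panel <- function(x, ...) {
  cat("MSI panel configuration\n")
  cat("  markers:", paste(x$markers$marker, collapse = ", "), "\n")
  cat(sprintf("  noise filter: peaks < %.1f%% of trace signal removed\n",
              100 * x$noise_fraction))
  cat(sprintf("  novel peak: >= %g bp from nearest normal peak, <= %g bp outside normal range\n",
              x$min_novel_distance_bp, x$max_outside_range_bp))
  cat(sprintf("  marker unstable if variability > %g%%\n",
              x$marker_instability_threshold_pct))
  cat(sprintf("  score tiers: MSS < %g, MSI-L %g-%g, MSI-H > %g\n",
              x$score_msil_low, x$score_msil_low, x$score_msil_high,
              x$score_msil_high))
  cat(sprintf("  normal trace noise-filtered: %s; proportion denominator: %s-filter\n",
              x$filter_normal, x$denominator_mode))
  invisible(x)
}

marker_window <- function(panel, marker) {
  i <- match(marker, panel$markers$marker)
  if (is.na(i)) {
    stop("unknown marker '", marker, "'; accepted markers: ",
         paste(panel$markers$marker, collapse = ", "), call. = FALSE)
  }
  c(panel$markers$min_bp[i], panel$markers$max_bp[i])
}
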