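#' Concordance between MSI calls and IHC labels
#'
#' IHC classifies samples only as MSS or MSI-H, so samples the selected
#' calling method labels MSI-L are excluded before comparison. Concordance is
#' the fraction of remaining samples whose call equals the IHC status,
#' reported as a percentage rounded to the nearest integer.
#'
#' @param results sample-result tibble ([call_samples()] /
#'   [classify_variability()])
#' @param labels IHC label tibble ([read_ihc_labels()])
#' @param method `"nci"` (marker-count status) or `"score"` (MSI-score tier)
#' @param group optional subgroup label; restricts to samples whose label
#'   `subgroup` matches. `NULL` (default) pools all samples.
#' @return a one-row tibble: `method`, `group`, `n_total`, `n_excluded_msil`,
#'   `n_evaluated`, `n_concordant`, `pct_concordant` (NA when nothing remains
#'   after MSI-L exclusion)
#' @export
concordance <- function(results, labels, method = c("nci", "score"),
                        group = NULL) {
  method <- match.arg(method)
  missing_ids <- setdiff(results$sample_id, labels$sample_id)
  if (length(missing_ids)) {
    stop("no IHC label for sample(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::inner_join(results, labels, by = "sample_id")
  if (!is.null(group)) df <- df[!is.na(df$subgroup) & df$subgroup == group, ]
  call <- if (method == "nci") df$nci_status else df$score_status
  n_total <- nrow(df)
  excl <- !is.na(call) & call == "MSI-L"
  keep <- !excl & !is.na(call)
  n_conc <- sum(call[keep] == df$ihc_status[keep])
  n_eval <- n_total - sum(excl)
  tibble::tibble(
    method = method,
    group = group %||% "all",
    n_total = n_total,
    n_excluded_msil = sum(excl),
    n_evaluated = n_eval,
    n_concordant = n_conc,
    pct_concordant = if (n_eval > 0) round_half_up(100 * n_conc / n_eval) else NA_real_
  )
}

#' Full concordance table: both methods, every subgroup plus overall
#'
#' @inheritParams concordance
#' @return tibble of [concordance()] rows
#' @export
concordance_table <- function(results, labels) {
  groups <- unique(labels$subgroup)
  groups <- groups[!is.na(groups)]
  rows <- list()
  for (m in c("nci", "score")) {
    for (g in groups) rows[[length(rows) + 1L]] <- concordance(results, labels, m, g)
    rows[[length(rows) + 1L]] <- concordance(results, labels, m, NULL)
  }
  dplyr::bind_rows(rows)
}

#' Count samples per status tier, for each classification method
#'
#' @param results sample-result tibble
#' @return tibble `method`, `status`, `n` with all three tiers present per
#'   method (zero-filled)
#' @export
tier_counts <- function(results) {
  rows <- list()
  for (m in c("nci", "score")) {
    call <- if (m == "nci") results$nci_status else results$score_status
    tab <- table(factor(call, levels = STATUS_LEVELS))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      method = m, status = STATUS_LEVELS, n = as.integer(tab)
    )
  }
  dplyr::bind_rows(rows)
}

#' Compare MSI scores across subgroups (Kruskal-Wallis)
#'
#' Rank-based comparison of the MSI score distribution between subgroups
#' (e.g. MSI-H:BRAF-mutant vs MSI-H:BRAF-wild-type vs MSS), with average
#' ranks for ties and the chi-square approximation for the p-value.
#'
#' @param results sample-result tibble
#' @param labels IHC label tibble with a non-NA `subgroup` column
#' @return list with `statistic` (H), `df`, `p.value`, and `groups`, a tibble
#'   of per-group n, mean and median score
#' @export
group_score_test <- function(results, labels) {
  df <- dplyr::inner_join(results, labels, by = "sample_id")
  df <- df[!is.na(df$subgroup) & !is.na(df$msi_score), ]
  counts <- table(df$subgroup)
  if (length(counts) < 2L || any(counts == 0L)) {
    stop("need >= 2 subgroups with >= 1 sample each", call. = FALSE)
  }
  kt <- stats::kruskal.test(df$msi_score, factor(df$subgroup))
  groups <- dplyr::summarise(
    dplyr::group_by(df, .data$subgroup),
    n = dplyr::n(),
    mean_score = mean(.data$msi_score),
    median_score = stats::median(.data$msi_score),
    .groups = "drop"
  )
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value, groups = groups)
}

#' Two-group comparison of mean MSI score (Welch t-test)
#'
#' Utility for comparing mean scores between two subgroups.
#'
#' @inheritParams group_score_test
#' @param group1,group2 the two subgroup labels to compare
#' @return the `htest` object from [stats::t.test()]
#' @export
group_mean_test <- function(results, labels, group1, group2) {
  df <- dplyr::inner_join(results, labels, by = "sample_id")
  x <- df$msi_score[!is.na(df$subgroup) & df$subgroup == group1]
  y <- df$msi_score[!is.na(df$subgroup) & df$subgroup == group2]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 samples for a t-test", call. = FALSE)
  }
  stats::t.test(x, y)
}
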