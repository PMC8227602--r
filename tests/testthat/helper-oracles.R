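# Independent oracles and small fixture builders used across the suite.

# Exhaustive loop-based re-implementation of the novelty criteria, kept
# deliberately independent of label_novel(): explicit peak-by-peak loops,
# no vectorisation shared with the implementation.
oracle_novel <- function(tumour, normal, panel) {
  norm <- normal
  if (panel$filter_normal) {
    tot <- 0
    for (j in seq_len(nrow(normal))) tot <- tot + normal$rfu[j]
    keep <- logical(nrow(normal))
    for (j in seq_len(nrow(normal))) keep[j] <- normal$rfu[j] >= panel$noise_fraction * tot
    norm <- normal[keep, , drop = FALSE]
  }
  if (nrow(norm) == 0L) return(NULL)
  tot_t <- 0
  for (i in seq_len(nrow(tumour))) tot_t <- tot_t + tumour$rfu[i]
  lo <- min(norm$size_bp) - panel$max_outside_range_bp
  hi <- max(norm$size_bp) + panel$max_outside_range_bp
  out <- NULL
  for (i in seq_len(nrow(tumour))) {
    if (tumour$rfu[i] < panel$noise_fraction * tot_t) next
    d <- Inf
    for (j in seq_len(nrow(norm))) {
      d <- min(d, abs(tumour$size_bp[i] - norm$size_bp[j]))
    }
    novel <- d >= panel$min_novel_distance_bp &&
      tumour$size_bp[i] >= lo && tumour$size_bp[i] <= hi
    out <- rbind(out, data.frame(size_bp = tumour$size_bp[i], is_novel = novel))
  }
  out
}

# Random gated trace with <= max_peaks peaks at distinct sizes.
random_trace <- function(max_peaks = 8, window = c(100, 150)) {
  n <- sample.int(max_peaks, 1)
  sizes <- sort(sample(seq(window[1], window[2], by = 0.5), n))
  peak_trace(sizes, stats::runif(n, 0.5, 100))
}

# Tie-corrected Kruskal-Wallis H computed from first principles.
oracle_kruskal_h <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  h <- 0
  for (lev in unique(g)) {
    rj <- sum(r[g == lev])
    nj <- sum(g == lev)
    h <- h + rj^2 / nj
  }
  h <- 12 / (N * (N + 1)) * h - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Peak table whose per-marker allelic variability equals `v` percent by
# construction: the normal is a single 100-RFU peak at `base`; the tumour
# splits 100 RFU between `base` and a novel peak 5 bp below. Values below the
# default 2% filter are only reachable with a lowered noise_fraction.
degenerate_pair_rows <- function(sample_id, marker, v, base = 120) {
  norm <- data.frame(sample_id = sample_id, marker = marker, role = "normal",
                     size_bp = base, rfu = 100)
  if (v > 0) {
    tum <- data.frame(sample_id = sample_id, marker = marker, role = "tumour",
                      size_bp = c(base, base - 5), rfu = c(100 - v, v))
  } else {
    tum <- data.frame(sample_id = sample_id, marker = marker, role = "tumour",
                      size_bp = base, rfu = 100)
  }
  rbind(norm, tum)
}

# Peak table for a whole variability table (sample_id + marker columns).
degenerate_peak_table <- function(tbl, panel = msi_panel()) {
  rows <- list()
  for (i in seq_len(nrow(tbl))) {
    for (m in panel$markers$marker) {
      base <- marker_window(panel, m)[1] + 20
      rows[[length(rows) + 1L]] <-
        degenerate_pair_rows(tbl$sample_id[i], m, tbl[[m]][i], base)
    }
  }
  do.call(rbind, rows)
}

write_peaks_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
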