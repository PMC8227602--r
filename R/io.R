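#' Read a fragment-analysis peak table and pair tumour/normal traces
#'
#' Reads a delimited peak table (one row per detected peak) exported from a
#' fragment-analysis instrument, validates it, gates peaks to each marker's
#' configured size window, merges duplicate sizes, and pairs tumour with
#' matched-normal traces per sample x marker. The delimiter (comma or tab) is
#' autodetected from the header line.
#'
#' Samples missing the tumour or the normal trace for a marker get that marker
#' flagged missing rather than raising an error: marker dropout is common with
#' FFPE-derived DNA and is carried as an explicit NA through classification.
#'
#' @param path path to a delimited text file with a header row
#' @param panel an [msi_panel()] configuration
#' @param col_map named character vector mapping the required logical columns
#'   (`sample_id`, `marker`, `role`, `size_bp`, `rfu`) to the file's column
#'   names. The default expects those exact names; remap e.g.
#'   `c(rfu = "Peak Area")` to bind signal to area instead of height.
#' @return an object of class `msi_pairs`: a tibble with one row per
#'   sample x panel marker and columns `sample_id`, `marker`, `tumour`,
#'   `normal` (list columns of peak tibbles), `missing`. The attribute
#'   `n_gated_out` counts peaks dropped by size-window gating.
#' @export
read_peak_table <- function(path, panel = msi_panel(),
                            col_map = c(sample_id = "sample_id",
                                        marker = "marker",
                                        role = "role",
                                        size_bp = "size_bp",
                                        rfu = "rfu")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- c("sample_id", "marker", "role", "size_bp", "rfu")
  col_map <- c(col_map, stats::setNames(setdiff(required, names(col_map)),
                                        setdiff(required, names(col_map))))
  sep <- detect_delim(path)
  raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(col_map[required]), names(raw))
  if (length(missing_cols)) {
    stop("peak table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    sample_id = raw[[col_map[["sample_id"]]]],
    marker = raw[[col_map[["marker"]]]],
    role = tolower(trimws(raw[[col_map[["role"]]]])),
    size_raw = raw[[col_map[["size_bp"]]]],
    rfu_raw = raw[[col_map[["rfu"]]]],
    stringsAsFactors = FALSE
  )
  # line numbers in error messages count the header as line 1
  line_no <- seq_len(nrow(df)) + 1L

  df$size_bp <- suppressWarnings(as.numeric(df$size_raw))
  df$rfu <- suppressWarnings(as.numeric(df$rfu_raw))
  bad <- which(is.na(df$size_bp) | is.na(df$rfu))
  if (length(bad)) {
    stop("non-numeric size_bp/rfu at line ", line_no[bad[1]], ": '",
         df$size_raw[bad[1]], "' / '", df$rfu_raw[bad[1]], "'", call. = FALSE)
  }
  df$role[df$role == "tumor"] <- "tumour"
  bad_role <- which(!df$role %in% c("tumour", "normal"))
  if (length(bad_role)) {
    stop("invalid role '", df$role[bad_role[1]], "' at line ",
         line_no[bad_role[1]], "; expected tumour or normal", call. = FALSE)
  }
  unknown <- setdiff(unique(df$marker), panel$markers$marker)
  if (length(unknown)) {
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(panel$markers$marker, collapse = ", "),
         call. = FALSE)
  }

  samples <- unique(df$sample_id)
  n_gated_out <- 0L
  rows <- list()
  for (s in samples) {
    for (m in panel$markers$marker) {
      win <- marker_window(panel, m)
      tr <- list()
      for (r in c("tumour", "normal")) {
        sub <- df[df$sample_id == s & df$marker == m & df$role == r, , drop = FALSE]
        if (nrow(sub) == 0L) {
          tr[[r]] <- NULL
        } else {
          g <- gate_trace(peak_trace(sub$size_bp, sub$rfu), win)
          n_gated_out <- n_gated_out + attr(g, "n_dropped")
          tr[[r]] <- g
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = s, marker = m,
        tumour = list(tr$tumour), normal = list(tr$normal),
        missing = is.null(tr$tumour) || is.null(tr$normal)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "panel") <- panel
  attr(out, "n_gated_out") <- n_gated_out
  class(out) <- c("msi_pairs", class(out))
  out
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read immunohistochemistry (IHC) status labels
#'
#' IHC infers mismatch-repair deficiency from loss of MMR protein staining and
#' can only classify samples as MSS or MSI-H; an MSI-L label in the input is a
#' validation error.
#'
#' @param path delimited text file with columns `sample_id`, `ihc_status` and
#'   optionally `subgroup`
#' @return tibble with columns `sample_id`, `ihc_status`, `subgroup`
#'   (NA when absent)
#' @export
read_ihc_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "ihc_status") %in% names(raw))) {
    stop("IHC label table must have columns sample_id, ihc_status", call. = FALSE)
  }
  status <- trimws(raw$ihc_status)
  bad <- which(!status %in% c("MSS", "MSI-H"))
  if (length(bad)) {
    stop("invalid IHC status '", status[bad[1]], "' for sample ",
         raw$sample_id[bad[1]],
         "; IHC can only be MSS or MSI-H (it cannot detect MSI-L)",
         call. = FALSE)
  }
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup)) {
    stop("duplicated sample_id in IHC labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = raw$sample_id,
    ihc_status = status,
    subgroup = if ("subgroup" %in% names(raw)) trimws(raw$subgroup) else NA_character_
  )
}

#' Write a per-sample MSI report
#'
#' TSV output mirrors the conventional report layout: per-marker allelic
#' variabilities as integer percent (rounded half up), the unstable-marker
#' count, NCI status, maximum allelic variability, MSI score, score-tier
#' status, and the Toh score (total high-level MSI, reported only for MSI-H
#' samples). JSON output additionally carries the unrounded variabilities and
#' score so the report round-trips exactly. Output is byte-stable across runs
#' on identical input.
#'
#' @param results a sample-result tibble from [call_samples()] or
#'   [classify_variability()]
#' @param path output file path
#' @param format `"tsv"` or `"json"`
#' @return `path`, invisibly
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (nrow(results) == 0L) stop("no samples to report", call. = FALSE)
  markers <- report_marker_cols(results)
  if (format == "tsv") {
    disp <- data.frame(sample_id = results$sample_id, check.names = FALSE,
                       stringsAsFactors = FALSE)
    for (m in markers) disp[[m]] <- round_half_up(results[[m]])
    disp$n_unstable <- results$n_unstable
    disp$nci_status <- results$nci_status
    disp$max_variability_pct <- round_half_up(results$max_variability_pct)
    disp$msi_score <- round_half_up(results$msi_score)
    disp$score_status <- results$score_status
    disp$toh_score <- ifelse(is.na(results$toh_score), "",
                             as.character(round_half_up(results$toh_score)))
    disp$qc <- results$qc
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(disp, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", eol = "\n")
  } else {
    objs <- lapply(seq_len(nrow(results)), function(i) {
      r <- as.list(results[i, ])
      vari <- stats::setNames(as.list(as.numeric(unlist(results[i, markers]))), markers)
      o <- list(
        sample_id = r$sample_id,
        allelic_variability_pct = vari,
        n_unstable = r$n_unstable,
        nci_status = r$nci_status,
        max_variability_pct = r$max_variability_pct,
        msi_score = r$msi_score,
        score_status = r$score_status,
        qc = if (nzchar(r$qc)) strsplit(r$qc, ";", fixed = TRUE)[[1]] else character()
      )
      if (!is.na(r$toh_score)) o$toh_score <- r$toh_score
      o
    })
    # 17 significant digits: doubles survive the round-trip bit-exactly
    json <- jsonlite::toJSON(objs, auto_unbox = TRUE, digits = I(17),
                             na = "null", null = "null", pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con, sep = "\n")
  }
  invisible(path)
}

report_marker_cols <- function(results) {
  fixed <- c("sample_id", "n_unstable", "nci_status", "max_variability_pct",
             "msi_score", "score_status", "toh_score", "qc")
  setdiff(names(results), fixed)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path path to a JSON report
#' @return a sample-result tibble with the same columns as [call_samples()]
#' @export
read_report <- function(path) {
  objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(objs, function(o) {
    v <- o$allelic_variability_pct
    row <- tibble::tibble(sample_id = o$sample_id)
    for (m in names(v)) row[[m]] <- if (is.null(v[[m]])) NA_real_ else as.numeric(v[[m]])
    row$n_unstable <- o$n_unstable %||% NA_integer_
    row$nci_status <- o$nci_status %||% NA_character_
    row$max_variability_pct <- as.numeric(o$max_variability_pct %||% NA_real_)
    row$msi_score <- as.numeric(o$msi_score %||% NA_real_)
    row$score_status <- o$score_status %||% NA_character_
    row$toh_score <- as.numeric(o$toh_score %||% NA_real_)
    row$qc <- join_flags(unlist(o$qc) %||% character())
    row
  })
  dplyr::bind_rows(rows)
}
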