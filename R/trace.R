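#' Construct an electropherogram trace (peak list)
#'
#' A trace is the set of detected fragment peaks for one sample x marker x
#' role, abstracted from the raw fluorescence signal. Peaks at identical size
#' are merged by summing their signal (one position cannot carry two peaks),
#' and peaks are kept strictly ordered by size.
#'
#' @param size_bp numeric vector of fragment sizes in base pairs (> 0); may be
#'   fractional, as instrument size-calling interpolates against a ladder
#' @param rfu numeric vector of peak signals in relative fluorescence units
#'   (>= 0)
#' @return a tibble with columns `size_bp`, `rfu`, sorted ascending by size
#' @examples
#' peak_trace(c(120, 119, 120), c(100, 20, 50)) # duplicate 120s merged to 150 RFU
#' @export
peak_trace <- function(size_bp = numeric(), rfu = numeric()) {
  stopifnot(length(size_bp) == length(rfu))
  if (length(size_bp) && (!is.numeric(size_bp) || !is.numeric(rfu))) {
    stop("size_bp and rfu must be numeric", call. = FALSE)
  }
  if (any(size_bp <= 0) || any(!is.finite(size_bp))) {
    stop("peak sizes must be positive and finite", call. = FALSE)
  }
  if (any(rfu < 0) || any(!is.finite(rfu))) {
    stop("peak signals must be non-negative and finite", call. = FALSE)
  }
  if (anyDuplicated(size_bp)) {
    rfu <- as.numeric(tapply(rfu, size_bp, sum))
    size_bp <- sort(unique(size_bp))
  } else {
    o <- order(size_bp)
    size_bp <- size_bp[o]
    rfu <- rfu[o]
  }
  tibble::tibble(size_bp = as.numeric(size_bp), rfu = as.numeric(rfu))
}

#' Gate a trace to a marker's size window
#'
#' Drops peaks outside `[min_bp, max_bp]` (inclusive). Gating is idempotent.
#'
#' @param peaks a trace tibble (`size_bp`, `rfu`)
#' @param window numeric length-2 `(min_bp, max_bp)`
#' @return the gated trace; attribute `n_dropped` carries the number of peaks
#'   removed
#' @export
gate_trace <- function(peaks, window) {
  keep <- peaks$size_bp >= window[1] & peaks$size_bp <= window[2]
  out <- peaks[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
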