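#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used for all
#' displayed integer percentages. `base::round()` rounds half to even, which
#' does not match how fragment-analysis reports are conventionally printed.
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return numeric vector rounded half away from zero
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical status levels, from stable to unstable.
STATUS_LEVELS <- c("MSS", "MSI-L", "MSI-H")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and string labels
#'
#' All simulator randomness flows from one integer seed; per-trace seeds are
#' derived by hashing the sample/marker/role labels so any single trace can be
#' regenerated in isolation. The result always fits in a 32-bit integer.
#'
#' @param seed integer base seed
#' @param ... character labels (e.g. sample id, marker, role)
#' @return a single integer seed
#' @export
split_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "\x1f")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 + h) %% 2147483563 + 1)
}

# Collapse QC flags into a single ";"-separated string ("" if none).
join_flags <- function(flags) paste(unique(flags[nzchar(flags)]), collapse = ";")
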