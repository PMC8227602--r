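#' Marker model for the synthetic electropherogram simulator
#'
#' Describes how one microsatellite marker amplifies: germline allele sizes,
#' a geometric stutter ladder below each allele (PCR slippage artifacts one
#' repeat unit apart), multiplicative signal jitter, and spurious low-signal
#' noise peaks.
#'
#' @param marker marker name
#' @param repeat_unit_bp repeat unit length: 1 (mononucleotide) or 2
#'   (dinucleotide)
#' @param allele_sizes_bp one or two germline allele lengths (bp), inside
#'   `window_bp`
#' @param window_bp length-2 marker size window `(min_bp, max_bp)`
#' @param stutter_decay per-step geometric signal ratio of the stutter ladder,
#'   in (0, 1) (default 0.15)
#' @param n_stutter number of stutter positions below each allele (default 1)
#' @param main_signal_rfu signal scale of an allele peak (default 1000 RFU)
#' @param noise_peak_rate expected (Poisson) count of spurious peaks per trace
#'   (default 2)
#' @param noise_signal_frac upper bound of a spurious peak's signal as a
#'   fraction of `main_signal_rfu` (default 0.015, which keeps noise below the
#'   2% trace-signal filter)
#' @param signal_cv multiplicative log-normal jitter (sdlog) applied to allele
#'   and stutter signals (default 0.05)
#' @return an object of class `marker_model`
#' @export
marker_model <- function(marker, repeat_unit_bp, allele_sizes_bp, window_bp,
                         stutter_decay = 0.15, n_stutter = 1,
                         main_signal_rfu = 1000, noise_peak_rate = 2,
                         noise_signal_frac = 0.015, signal_cv = 0.05) {
  stopifnot(repeat_unit_bp %in% c(1, 2),
            length(allele_sizes_bp) %in% 1:2,
            length(window_bp) == 2, window_bp[1] < window_bp[2],
            stutter_decay > 0, stutter_decay < 1, n_stutter >= 0,
            main_signal_rfu > 0, noise_peak_rate >= 0,
            noise_signal_frac >= 0, signal_cv >= 0)
  if (any(allele_sizes_bp < window_bp[1] | allele_sizes_bp > window_bp[2])) {
    stop("allele sizes must lie inside the marker window", call. = FALSE)
  }
  structure(list(marker = marker, repeat_unit_bp = repeat_unit_bp,
                 allele_sizes_bp = sort(allele_sizes_bp), window_bp = window_bp,
                 stutter_decay = stutter_decay, n_stutter = n_stutter,
                 main_signal_rfu = main_signal_rfu,
                 noise_peak_rate = noise_peak_rate,
                 noise_signal_frac = noise_signal_frac,
                 signal_cv = signal_cv),
            class = "marker_model")
}

#' Default five-marker simulator models
#'
#' Quasi-monomorphic mononucleotide markers (BAT-25, BAT-26, one allele each)
#' and heterozygous dinucleotide markers (D5S346, D2S123, D17S250, two
#' alleles), with windows matching the panel configuration.
#'
#' @param panel an [msi_panel()] supplying the size windows
#' @param ... arguments forwarded to every [marker_model()] (e.g.
#'   `n_stutter = 0` for stutter-free traces)
#' @return named list of `marker_model` objects
#' @export
default_marker_models <- function(panel = msi_panel(), ...) {
  win <- function(m) marker_window(panel, m)
  list(
    "BAT-25" = marker_model("BAT-25", 1, 124, win("BAT-25"), ...),
    "BAT-26" = marker_model("BAT-26", 1, 116, win("BAT-26"), ...),
    "D5S346" = marker_model("D5S346", 2, c(110, 120), win("D5S346"), ...),
    "D2S123" = marker_model("D2S123", 2, c(200, 212), win("D2S123"), ...),
    "D17S250" = marker_model("D17S250", 2, c(150, 160), win("D17S250"), ...)
  )
}

#' Tumour model: which markers shift, by how much, at what clonal fraction
#'
#' @param shift_bp signed size shift of the unstable allele in the tumour
#'   clone (default -3, i.e. a 3-bp deletion)
#' @param tumour_fraction fraction of DNA from the unstable clone, in `[0, 1]`
#' @param unstable_markers markers carrying the shift (default the two
#'   mononucleotide markers plus D2S123)
#' @return an object of class `tumour_model`
#' @export
tumour_model <- function(shift_bp = -3, tumour_fraction = 0.5,
                         unstable_markers = c("BAT-25", "BAT-26", "D2S123")) {
  if (!is.numeric(tumour_fraction) || tumour_fraction < 0 || tumour_fraction > 1) {
    stop("tumour_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(shift_bp = shift_bp, tumour_fraction = tumour_fraction,
                 unstable_markers = unstable_markers),
            class = "tumour_model")
}

# Deterministic allele + stutter profile (no noise, no jitter).
# Only the lowest allele shifts in the tumour clone; with shift = 0 this is
# the germline profile.
profile_peaks <- function(model, shift = 0) {
  sizes <- numeric()
  rfu <- numeric()
  alleles <- model$allele_sizes_bp
  if (shift != 0) {
    shifted <- alleles[1] + shift
    if (shifted < model$window_bp[1] || shifted > model$window_bp[2]) {
      stop("shifted allele (", shifted, " bp) falls outside the ",
           model$marker, " window", call. = FALSE)
    }
    alleles[1] <- shifted
  }
  for (a in alleles) {
    k <- 0:model$n_stutter
    sizes <- c(sizes, a - k * model$repeat_unit_bp)
    rfu <- c(rfu, model$main_signal_rfu * model$stutter_decay^k)
  }
  peak_trace(sizes, rfu)
}

# Apply seeded signal jitter and Poisson noise peaks to a deterministic
# profile. Peak-wise draws happen in size order so the same profile and seed
# always yield the same trace.
render_trace <- function(prof, model, seed) {
  withr::with_seed(seed, {
    jit <- exp(stats::rnorm(nrow(prof), 0, model$signal_cv))
    prof$rfu <- prof$rfu * jit
    n_noise <- stats::rpois(1, model$noise_peak_rate)
    if (n_noise > 0) {
      pos <- stats::runif(n_noise, model$window_bp[1], model$window_bp[2])
      sig <- stats::runif(n_noise, 0, model$noise_signal_frac * model$main_signal_rfu)
      prof <- peak_trace(c(prof$size_bp, pos), c(prof$rfu, sig))
    }
    prof
  })
}

#' Simulate a matched-normal trace
#'
#' Deterministic for a fixed seed: germline allele peaks with their stutter
#' ladders, log-normal signal jitter, and Poisson-count noise peaks at uniform
#' positions in the marker window.
#'
#' @param model a [marker_model()]
#' @param seed integer seed
#' @return a trace tibble (`size_bp`, `rfu`)
#' @export
make_normal_trace <- function(model, seed) {
  render_trace(profile_peaks(model), model, seed)
}

#' Simulate a tumour trace as a normal/shifted mixture
#'
#' For markers in the tumour model's unstable set, the deterministic profile
#' is `(1 - f) x germline + f x shifted` (the shifted allele brings its own
#' stutter ladder), where `f` is the tumour fraction; stable markers keep the
#' pure germline profile. Jitter and noise are then applied exactly as in
#' [make_normal_trace()], so `tumour_fraction = 0` reproduces the normal
#' trace for the same seed.
#'
#' @param model a [marker_model()]
#' @param tmodel a [tumour_model()]
#' @param seed integer seed
#' @return a trace tibble
#' @export
make_tumour_trace <- function(model, tmodel, seed) {
  if (!model$marker %in% tmodel$unstable_markers) {
    return(make_normal_trace(model, seed))
  }
  prof <- mix_profiles(profile_peaks(model), profile_peaks(model, tmodel$shift_bp),
                       tmodel$tumour_fraction)
  render_trace(prof, model, seed)
}

# Weighted mixture of two deterministic profiles; zero-weight peaks are
# dropped so the pure cases reduce exactly to their component profile.
mix_profiles <- function(normal_prof, shifted_prof, fraction) {
  mixed <- peak_trace(c(normal_prof$size_bp, shifted_prof$size_bp),
                 c((1 - fraction) * normal_prof$rfu, fraction * shifted_prof$rfu))
  mixed[mixed$rfu > 0, , drop = FALSE]
}

#' Simulate one paired tumour/normal sample as a peak table
#'
#' Per-trace seeds are split from the base seed by sample, marker and role
#' ([split_seed()]), so any single trace can be regenerated in isolation.
#'
#' @param models list of [marker_model()]s (one per panel marker)
#' @param tmodel a [tumour_model()]
#' @param seed integer base seed
#' @param sample_id sample identifier
#' @return tibble in the peak-table format [read_peak_table()] reads:
#'   `sample_id`, `marker`, `role`, `size_bp`, `rfu`
#' @export
simulate_sample <- function(models, tmodel, seed, sample_id = "sim") {
  rows <- list()
  for (model in models) {
    for (role in c("normal", "tumour")) {
      s <- split_seed(seed, sample_id, model$marker, role)
      tr <- if (role == "normal") make_normal_trace(model, s)
            else make_tumour_trace(model, tmodel, s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sample_id, marker = model$marker, role = role,
        size_bp = tr$size_bp, rfu = tr$rfu
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a tumour-fraction dilution series
#'
#' Emulates proportional mixing of an unstable (MSI-H) cell line into a
#' stable (MSS) background: one synthetic sample per mixing fraction, five
#' markers each, paired with an unmixed normal, plus a ground-truth sidecar
#' table.
#'
#' @param msih_models list of [marker_model()]s for the unstable line; by
#'   default derived from `mss_models` by shifting the lowest allele of each
#'   marker in `unstable_markers` by `shift_bp`
#' @param mss_models list of [marker_model()]s for the stable background
#'   (also the matched normal)
#' @param fractions mixing fractions in `[0, 1]`
#' @param seed integer base seed
#' @param shift_bp,unstable_markers used to derive `msih_models` when it is
#'   `NULL`
#' @return list with `peaks` (long peak table for all samples) and `truth`
#'   (tibble `sample_id`, `tumour_fraction`, `marker`, `shifted`, `shift_bp`)
#' @export
mixing_series <- function(msih_models = NULL,
                          mss_models = default_marker_models(),
                          fractions = c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1),
                          seed = 1,
                          shift_bp = -3,
                          unstable_markers = c("BAT-25", "BAT-26", "D2S123")) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("mixing fractions must be in [0, 1]", call. = FALSE)
  }
  if (is.null(msih_models)) {
    msih_models <- lapply(mss_models, function(m) {
      if (m$marker %in% unstable_markers) m$allele_sizes_bp[1] <- m$allele_sizes_bp[1] + shift_bp
      do.call(marker_model, unclass(m))
    })
    names(msih_models) <- vapply(msih_models, `[[`, "", "marker")
  }
  peaks <- list()
  truth <- list()
  for (f in fractions) {
    sid <- sprintf("mix_%03d", round(100 * f))
    for (nm in names(mss_models)) {
      mss <- mss_models[[nm]]
      msih <- msih_models[[nm]]
      shifted <- !identical(mss$allele_sizes_bp, msih$allele_sizes_bp)
      prof <- mix_profiles(profile_peaks(mss), profile_peaks(msih), f)
      for (role in c("normal", "tumour")) {
        s <- split_seed(seed, sid, nm, role)
        tr <- if (role == "normal") make_normal_trace(mss, s)
              else render_trace(prof, mss, s)
        peaks[[length(peaks) + 1L]] <- tibble::tibble(
          sample_id = sid, marker = nm, role = role,
          size_bp = tr$size_bp, rfu = tr$rfu
        )
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        sample_id = sid, tumour_fraction = f, marker = nm,
        shifted = shifted,
        shift_bp = if (shifted) msih$allele_sizes_bp[1] - mss$allele_sizes_bp[1] else 0
      )
    }
  }
  list(peaks = dplyr::bind_rows(peaks), truth = dplyr::bind_rows(truth))
}
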