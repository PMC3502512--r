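# Segment-averaged power spectra.
#
# Estimation follows the disjoint-section convention: rectangular window, no
# overlap, per-segment mean removal, periodograms averaged over segments. The
# zero-frequency bin is dropped everywhere (rectified EMG carries a large DC
# offset that band totals cannot sensibly include); bins run from fs/nfft up
# to the Nyquist bin in steps of fs/nfft.

#' Full-wave rectification
#'
#' Elementwise absolute value, applied to raw EMG before segmentation and
#' spectral analysis. Idempotent on non-negative input. Note that
#' [generate_session()] emits EMG surrogates that already represent the
#' rectified signal, so synthetic sessions are analysed without a second
#' rectification pass.
#'
#' @param series Numeric vector or matrix.
#' @return Object of the same shape with `abs()` applied.
#' @export
rectify <- function(series) {
  if (!is.numeric(series)) abort("`series` must be numeric.")
  abs(series)
}

#' Cut a series into sequential non-overlapping segments
#'
#' @param series Numeric vector.
#' @param segment_length Samples per segment.
#' @return A `segment_length x floor(length/segment_length)` matrix; the
#'   trailing remainder is discarded.
#' @export
segment_sequential <- function(series, segment_length) {
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  n_seg <- length(series) %/% segment_length
  if (n_seg < 1) {
    abort(sprintf("series of %d samples is shorter than one %d-sample segment.",
                  length(series), as.integer(segment_length)))
  }
  matrix(series[seq_len(n_seg * segment_length)], segment_length, n_seg)
}

#' Extract contiguous hold-phase sections from annotated trials
#'
#' Takes `sections_per_trial` contiguous segments per trial, starting at the
#' annotated onset of the steady-hold phase. Trials whose hold window is
#' shorter than `sections_per_trial * segment_length` samples are skipped with
#' a warning rather than zero-padded (padding would bias coherence).
#'
#' @param trials A data frame with one row per trial: a list-column `samples`
#'   (the trial's numeric series) and integer columns `hold_start` and
#'   `hold_end` (first and last sample index of the hold phase, inclusive).
#' @param sections_per_trial Segments taken per trial.
#' @param segment_length Samples per segment.
#' @return A `segment_length x (n_kept_trials * sections_per_trial)` matrix of
#'   pooled segments.
#' @export
segment_hold_phase <- function(trials, sections_per_trial, segment_length) {
  if (!is.data.frame(trials) ||
      !all(c("samples", "hold_start", "hold_end") %in% names(trials))) {
    abort("`trials` needs columns samples (list), hold_start, hold_end.")
  }
  stopifnot_scalar(sections_per_trial, "sections_per_trial", positive = TRUE)
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  need <- sections_per_trial * segment_length
  segs <- vector("list", nrow(trials))
  skipped <- 0L
  for (i in seq_len(nrow(trials))) {
    x <- trials$samples[[i]]
    lo <- trials$hold_start[i]
    hi <- min(trials$hold_end[i], length(x))
    if (hi - lo + 1 < need) {
      skipped <- skipped + 1L
      next
    }
    segs[[i]] <- matrix(x[lo:(lo + need - 1)], segment_length,
                        sections_per_trial)
  }
  if (skipped > 0) {
    warn(sprintf("%d of %d trials skipped: hold window shorter than %d samples.",
                 skipped, nrow(trials), as.integer(need)))
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) abort("no trial had a usable hold window.")
  do.call(cbind, segs)
}

#' Spectral resolution of a segment-averaged analysis
#'
#' @param sampling_rate Hz.
#' @param segment_length Samples per segment.
#' @return Bin width `sampling_rate / segment_length` in Hz (1.13 Hz for the
#'   study's 4096-point segments at 4630 Hz).
#' @export
frequency_resolution <- function(sampling_rate, segment_length) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  sampling_rate / segment_length
}

#' Duration of one analysis segment
#'
#' @param segment_length Samples per segment.
#' @param sampling_rate Hz.
#' @return Segment duration `segment_length / sampling_rate` in seconds
#'   (0.88 s for the study's 4096-point segments at 4630 Hz).
#' @export
segment_duration <- function(segment_length, sampling_rate) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  segment_length / sampling_rate
}

new_power_spectrum <- function(frequency, power, n_segments, sampling_rate,
                               normalization = "raw", reference_total = NULL) {
  out <- tibble(frequency = frequency, power = power)
  attr(out, "n_segments") <- n_segments
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "normalization") <- normalization
  attr(out, "reference_total") <- reference_total
  class(out) <- c("power_spectrum", class(out))
  out
}

# one-sided averaged periodogram over segment columns; DC dropped, interior
# bins doubled, Nyquist bin not doubled. Sum over bins equals the mean
# per-segment (biased) variance.
periodogram_avg <- function(segments) {
  N <- nrow(segments)
  segments <- sweep(segments, 2, colMeans(segments))
  F <- mvfft(segments)
  half <- N %/% 2
  p <- rowMeans(Mod(F[2:(half + 1), , drop = FALSE])^2) / N^2
  mult <- c(rep(2, half - 1), if (N %% 2 == 0) 1 else 2)
  p * mult
}

#' Segment-averaged power spectrum
#'
#' Per-segment periodograms (rectangular window, per-segment mean removed)
#' averaged over disjoint segments. Scaling is Parseval-consistent: the sum of
#' raw power over all retained bins equals the mean per-segment variance
#' (mean square about the segment mean).
#'
#' @param segments Numeric matrix, one column per segment, or a numeric
#'   vector (a single segment).
#' @param sampling_rate Hz.
#' @return A `power_spectrum` tibble with columns `frequency`, `power`
#'   (attributes: `n_segments`, `sampling_rate`, `normalization = "raw"`).
#' @export
power_spectrum <- function(segments, sampling_rate) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    segments <- matrix(segments, ncol = 1)
  }
  if (!is.matrix(segments) || ncol(segments) < 1 || nrow(segments) < 2) {
    abort("`segments` must be a matrix with >= 1 column and >= 2 rows.")
  }
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  new_power_spectrum(
    frequency = bin_frequencies(sampling_rate, nrow(segments)),
    power = periodogram_avg(segments),
    n_segments = ncol(segments), sampling_rate = sampling_rate)
}

#' Normalise a power spectrum to a total power
#'
#' `own_total` divides by the spectrum's own total so bins sum to one
#' (used for EEG and EMG, exposing peak size relative to the total);
#' `reference_total` divides by a supplied total -- for acceleration, the
#' total power of the day's first recording, so that overall tremor-power
#' changes remain measurable across the before/after pair.
#'
#' @param spectrum A raw `power_spectrum`.
#' @param mode `"own_total"` or `"reference_total"`.
#' @param reference_total Total power of the reference recording (required
#'   for `mode = "reference_total"`).
#' @return A normalised `power_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, mode = c("own_total", "reference_total"),
                               reference_total = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  mode <- match.arg(mode)
  total <- sum(spectrum$power)
  if (mode == "own_total") {
    if (total <= 0) abort("spectrum has zero total power; cannot normalise.")
    ref <- total
  } else {
    if (is.null(reference_total)) {
      abort("`reference_total` must be supplied for reference normalisation.")
    }
    stopifnot_scalar(reference_total, "reference_total", positive = TRUE)
    ref <- reference_total
  }
  new_power_spectrum(spectrum$frequency, spectrum$power / ref,
                     attr(spectrum, "n_segments"),
                     attr(spectrum, "sampling_rate"),
                     normalization = mode, reference_total = ref)
}

#' Analysis band definition
#'
#' @param label Band name.
#' @param f_lo,f_hi Closed frequency interval in Hz, `0 < f_lo < f_hi`.
#'   A bin belongs to the band when its centre frequency lies in
#'   `[f_lo, f_hi]`.
#' @return A `band_definition` object.
#' @export
band_definition <- function(label, f_lo, f_hi) {
  stopifnot_scalar(f_lo, "f_lo", positive = TRUE)
  stopifnot_scalar(f_hi, "f_hi", positive = TRUE)
  if (f_lo >= f_hi) abort("need f_lo < f_hi.")
  structure(list(label = as.character(label), f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' The study's two analysis bands
#'
#' Tremor: 6.2--11.9 Hz; beta: 15.3--32.2 Hz.
#' @return Named list of [band_definition()] objects.
#' @export
default_bands <- function() {
  list(tremor = band_definition("tremor", 6.2, 11.9),
       beta = band_definition("beta", 15.3, 32.2))
}

#' Band power of a spectrum
#'
#' Sum of power over the bins whose centre frequency lies in the closed band
#' interval.
#'
#' @param spectrum A `power_spectrum` (or any data frame with `frequency` and
#'   `power` columns).
#' @param band A [band_definition()].
#' @return Scalar band power.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(band, "band_definition"))
  idx <- band_bin_indices(spectrum$frequency, band$f_lo, band$f_hi)
  if (length(idx) == 0) {
    abort(sprintf(
      "band '%s' [%.3g, %.3g] Hz contains no bin centres at resolution %.4g Hz.",
      band$label, band$f_lo, band$f_hi, diff(spectrum$frequency[1:2])))
  }
  sum(spectrum$power[idx])
}

#' Average spectra across subjects (and muscles)
#'
#' Arithmetic per-bin mean of spectra on identical bin grids and in the same
#' normalisation state.
#'
#' @param spectra A list of `power_spectrum` objects.
#' @return A `power_spectrum` whose `n_segments` attribute records the
#'   contributors' segment counts.
#' @export
average_spectra <- function(spectra) {
  if (length(spectra) < 1) abort("need at least one spectrum.")
  f0 <- spectra[[1]]$frequency
  norm0 <- attr(spectra[[1]], "normalization")
  for (s in spectra) {
    if (!isTRUE(all.equal(s$frequency, f0))) {
      abort("spectra are on different frequency grids.")
    }
    if (!identical(attr(s, "normalization"), norm0)) {
      abort("spectra are in different normalisation states.")
    }
  }
  p <- rowMeans(vapply(spectra, function(s) s$power, numeric(length(f0))))
  out <- new_power_spectrum(
    f0, p, n_segments = vapply(spectra, function(s) attr(s, "n_segments"),
                               numeric(1)),
    sampling_rate = attr(spectra[[1]], "sampling_rate"),
    normalization = norm0)
  attr(out, "contributors") <- length(spectra)
  out
}

#' Tidy per-recording power spectra for a synthetic session
#'
#' Computes the segment-averaged power spectrum of every grip channel
#' (EEG/EMG segment matrices) and of the accelerometer series (cut into
#' sequential segments of `segment_length`). EEG and EMG spectra are
#' normalised to their own total power; acceleration spectra to the total
#' power of the same subject/arm "before" recording, following the day-first
#' reference convention.
#'
#' @param session A `tremor_session` from [generate_session()].
#' @param normalize Apply the study normalisations (default `TRUE`; `FALSE`
#'   returns raw spectra).
#' @return A tibble with columns subject, arm, condition, channel, role,
#'   frequency, power, n_segments, normalization.
#' @export
session_spectra <- function(session, normalize = TRUE) {
  plan <- attr(session, "plan")
  fs <- plan$sampling_rate
  seg_len <- plan$segment_length

  spec_one <- function(data, role) {
    segs <- if (role == "ACC") segment_sequential(data, seg_len) else data
    power_spectrum(segs, fs)
  }

  rows <- purrr::pmap(
    list(session$subject, session$arm, session$condition,
         session$channel, session$role, session$data),
    function(subject, arm, condition, channel, role, data) {
      sp <- spec_one(data, role)
      tibble(subject = subject, arm = arm, condition = condition,
             channel = channel, role = role,
             frequency = sp$frequency, power = sp$power,
             n_segments = attr(sp, "n_segments"),
             total_power = sum(sp$power))
    })
  out <- bind_rows(rows)
  if (!normalize) {
    return(out |> mutate(normalization = "raw") |> select(-"total_power"))
  }
  ref <- out |>
    filter(.data$condition == "before") |>
    dplyr::distinct(.data$subject, .data$arm, .data$channel,
                    ref_total = .data$total_power)
  out |>
    left_join(ref, by = c("subject", "arm", "channel")) |>
    mutate(
      power = dplyr::if_else(.data$role == "ACC",
                             .data$power / .data$ref_total,
                             .data$power / .data$total_power),
      normalization = dplyr::if_else(.data$role == "ACC",
                                     "reference_total", "own_total")) |>
    select(-"total_power", -"ref_total")
}

#' Band power per recording from tidy session spectra
#'
#' @param spectra Output of [session_spectra()].
#' @param band A [band_definition()].
#' @return One row per (subject, arm, condition, channel) with the summed
#'   band power.
#' @export
session_band_power <- function(spectra, band) {
  stopifnot(inherits(band, "band_definition"))
  spectra |>
    group_by(.data$subject, .data$arm, .data$condition, .data$channel,
             .data$role) |>
    summarise(
      band_power = sum(.data$power[.data$frequency >= !!band$f_lo &
                                     .data$frequency <= !!band$f_hi]),
      .groups = "drop") |>
    mutate(band = !!band$label, .before = "band_power")
}
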