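# Disjoint-segment coherence estimation and its significance limits.
#
# Estimator: magnitude-squared coherence from cross- and auto-spectra summed
# over L non-overlapping, untapered segments,
#   C(f) = |sum_i X_i conj(Y_i)|^2 / (sum_i |X_i|^2 sum_i |Y_i|^2).
# With independent Gaussian inputs the per-bin null distribution is exactly
# Beta(1, L-1), giving the closed-form single-spectrum significance limit
# 1 - alpha^(1/(L-1)); limits for coherence averaged over K spectra are the
# corresponding quantile of the mean of K independent Beta(1, L-1) variables,
# evaluated by Monte Carlo on the exact null.

# fast core on FFT coefficient matrices (bins x segments)
coh_core <- function(Fx, Fy) {
  cross <- rowSums(Fx * Conj(Fy))
  px <- rowSums(Mod(Fx)^2)
  py <- rowSums(Mod(Fy)^2)
  den <- px * py
  coh <- ifelse(den > 0, Mod(cross)^2 / den, 0)
  coh <- pmin(pmax(coh, 0), 1)
  phase <- ifelse(Mod(cross) > 0, Arg(cross), NA_real_)
  list(coherence = coh, phase = phase)
}

# positive-frequency FFT coefficients of mean-removed segment columns
segment_ffts <- function(segments) {
  N <- nrow(segments)
  segments <- sweep(segments, 2, colMeans(segments))
  F <- mvfft(segments)
  F[2:(N %/% 2 + 1), , drop = FALSE]
}

#' Coherence spectrum between two sets of aligned segments
#'
#' Magnitude-squared coherence and cross-spectral phase per frequency bin,
#' from cross- and auto-spectra summed over the L disjoint segments. Phase is
#' the argument of `sum X conj(Y)`: positive phase means the first channel
#' (EEG) leads. Bins whose cross-spectrum is exactly zero get `NA` phase.
#'
#' @param segments_x,segments_y Numeric matrices of identical dimension, one
#'   column per segment (x is conventionally the EEG channel).
#' @param sampling_rate Hz.
#' @param pair Optional character vector of length 2 naming the channels.
#' @return A `coherence_spectrum` tibble with columns `frequency`,
#'   `coherence`, `phase` and attributes `n_segments`, `pair`.
#' @export
coherence_spectrum <- function(segments_x, segments_y, sampling_rate,
                               pair = c("EEG", "EMG")) {
  if (!is.matrix(segments_x) || !is.matrix(segments_y)) {
    abort("segments must be matrices (samples x segments).")
  }
  if (!all(dim(segments_x) == dim(segments_y))) {
    abort("segment sets must have identical dimensions.")
  }
  L <- ncol(segments_x)
  if (L < 2) abort("coherence needs L >= 2 disjoint segments.")
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  est <- coh_core(segment_ffts(segments_x), segment_ffts(segments_y))
  out <- tibble(
    frequency = bin_frequencies(sampling_rate, nrow(segments_x)),
    coherence = est$coherence, phase = est$phase)
  attr(out, "n_segments") <- L
  attr(out, "pair") <- pair
  class(out) <- c("coherence_spectrum", class(out))
  out
}

#' Significance limit for a single coherence spectrum
#'
#' The (1 - alpha) quantile of the Beta(1, L-1) null distribution of the
#' disjoint-segment estimator: `1 - alpha^(1/(L-1))`.
#'
#' @param L Number of disjoint segments (>= 2).
#' @param alpha Significance level in (0, 1).
#' @return Threshold in \[0, 1\]; coherence above it is significant at
#'   level alpha.
#' @export
single_coherence_significance <- function(L, alpha = 0.05) {
  stopifnot_scalar(L, "L")
  if (L < 2) abort("L must be >= 2.")
  stopifnot_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  1 - alpha^(1 / (L - 1))
}

#' Significance limit for coherence averaged over K spectra
#'
#' Null distribution of the arithmetic mean of K independent per-spectrum
#' coherence estimates, each Beta(1, L-1) under independence; the (1 - alpha)
#' quantile is evaluated by Monte Carlo (`n_draws` means of K Beta draws,
#' fixed internal seed, so the limit is deterministic). K = 1 returns the
#' closed-form single-spectrum limit.
#'
#' @param K Number of averaged spectra (subjects x muscles).
#' @param L Disjoint segments per spectrum (>= 2).
#' @param alpha Significance level in (0, 1).
#' @param n_draws Monte Carlo sample size (default 1e5).
#' @return Threshold in \[0, 1\] for the averaged coherence.
#' @export
averaged_coherence_significance <- function(K, L, alpha = 0.05,
                                            n_draws = 1e5) {
  stopifnot_scalar(K, "K", positive = TRUE)
  stopifnot_scalar(L, "L")
  if (L < 2) abort("L must be >= 2.")
  stopifnot_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  if (K == 1) return(single_coherence_significance(L, alpha))
  with_local_seed(104729L, {
    draws <- matrix(rbeta(n_draws * K, 1, L - 1), n_draws, K)
    unname(quantile(rowMeans(draws), probs = 1 - alpha, type = 8))
  })
}

#' Average coherence spectra across subjects and muscles
#'
#' Arithmetic per-bin mean of coherence magnitudes (phases are not averaged
#' here; paired phase analysis uses [select_phase_pairs()]).
#'
#' @param spectra List of `coherence_spectrum` objects on identical grids.
#' @return An `averaged_coherence` tibble with columns `frequency`,
#'   `mean_coherence`; attributes `contributors` (K) and `n_segments`
#'   (per-spectrum L values).
#' @export
average_coherence <- function(spectra) {
  if (length(spectra) < 1) abort("need at least one coherence spectrum.")
  f0 <- spectra[[1]]$frequency
  for (s in spectra) {
    if (!isTRUE(all.equal(s$frequency, f0))) {
      abort("coherence spectra are on different frequency grids.")
    }
  }
  m <- rowMeans(vapply(spectra, function(s) s$coherence, numeric(length(f0))))
  out <- tibble(frequency = f0, mean_coherence = m)
  attr(out, "contributors") <- length(spectra)
  attr(out, "n_segments") <- vapply(spectra, function(s) attr(s, "n_segments"),
                                    numeric(1))
  class(out) <- c("averaged_coherence", class(out))
  out
}

#' Tidy corticomuscular coherence for every recording of a session
#'
#' Computes the EEG-EMG coherence spectrum for each subject, arm, condition
#' and muscle of a synthetic session.
#'
#' @param session A `tremor_session` from [generate_session()].
#' @return A tibble with columns subject, arm, condition, muscle, frequency,
#'   coherence, phase, n_segments.
#' @export
session_coherence <- function(session) {
  plan <- attr(session, "plan")
  fs <- plan$sampling_rate
  keys <- session |>
    filter(.data$role == "EEG") |>
    select("subject", "arm", "condition")
  rows <- purrr::pmap(keys, function(subject, arm, condition) {
    sub <- session[session$subject == subject & session$arm == arm &
                     session$condition == condition, ]
    eeg <- sub$data[[which(sub$role == "EEG")]]
    Fx <- segment_ffts(eeg)
    freqs <- bin_frequencies(fs, nrow(eeg))
    musc <- which(sub$role == "EMG")
    bind_rows(lapply(musc, function(i) {
      est <- coh_core(Fx, segment_ffts(sub$data[[i]]))
      tibble(subject = subject, arm = arm, condition = condition,
             muscle = sub$channel[i], frequency = freqs,
             coherence = est$coherence, phase = est$phase,
             n_segments = ncol(eeg))
    }))
  })
  bind_rows(rows)
}

#' Pair before/after coherence within an analysis band
#'
#' Reshapes tidy session coherence into the paired substrate of the
#' difference-of-coherence statistics: one row per (subject, muscle,
#' frequency bin) inside the band, with before and after coherence, phase and
#' segment counts side by side.
#'
#' @param coherence Output of [session_coherence()], restricted to one arm
#'   (or pass `arm` to select it here).
#' @param band A [band_definition()] (the beta band by default).
#' @param arm Optional arm label to filter on.
#' @return A `paired_coherence` tibble with columns subject, muscle,
#'   frequency, coh_before, coh_after, phase_before, phase_after, L_before,
#'   L_after; the band is recorded as an attribute.
#' @export
pair_conditions <- function(coherence, band = default_bands()$beta,
                            arm = NULL) {
  stopifnot(inherits(band, "band_definition"))
  if (!is.null(arm)) coherence <- filter(coherence, .data$arm == !!arm)
  if (length(unique(coherence$arm)) > 1) {
    abort("`coherence` spans several arms; pass `arm` to select one.")
  }
  inband <- filter(coherence, .data$frequency >= band$f_lo,
                   .data$frequency <= band$f_hi)
  if (nrow(inband) == 0) abort("band contains no frequency bins.")
  wide <- inband |>
    tidyr::pivot_wider(
      id_cols = c("subject", "muscle", "frequency"),
      names_from = "condition",
      values_from = c("coherence", "phase", "n_segments"))
  need <- c("coherence_before", "coherence_after")
  if (!all(need %in% names(wide)) || anyNA(wide[need])) {
    abort("both 'before' and 'after' conditions are required for every row.")
  }
  out <- wide |>
    dplyr::rename(coh_before = "coherence_before", coh_after = "coherence_after",
                  L_before = "n_segments_before", L_after = "n_segments_after")
  attr(out, "band") <- band
  class(out) <- c("paired_coherence", class(out))
  out
}
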