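# Paired-study simulator used for calibration and power experiments.

#' Simulate a paired before/after coherence study
#'
#' Generates, through [generate_coupled_pair()] and the disjoint-segment
#' estimator, one crossover recording pair per subject: `L_before` segments
#' under `coupling_before` and an independent set of `L_after` segments under
#' `coupling_after`, each with one EEG channel and `n_muscles` EMG channels.
#' Returns the band-restricted paired coherence set that
#' [coherence_diff_z()] consumes. With `coupling_after = coupling_before`
#' this is an exact simulation of the null hypothesis of unchanged coherence,
#' the construction used to verify that the pooled Z statistic is standard
#' normal.
#'
#' @param coupling_before A [coupling_model()].
#' @param coupling_after A [coupling_model()]; defaults to `coupling_before`
#'   (the null).
#' @param n_subjects Number of subjects.
#' @param n_muscles EMG channels per subject.
#' @param L_before,L_after Disjoint segments per recording.
#' @param segment_length Samples per segment.
#' @param sampling_rate Hz.
#' @param band A [band_definition()] restricting the pooled bins.
#' @param seed Integer seed.
#' @param share_drive If `TRUE` (the physiological layout), one drive and one
#'   EEG channel are shared by all of a subject's muscles, which correlates
#'   the per-muscle coherence estimates. `FALSE` draws every
#'   (subject, muscle) recording pair independently -- the construction under
#'   which the pooled Z statistic's terms are exactly independent, used for
#'   its null calibration.
#' @return A `paired_coherence` tibble (subject, muscle, frequency,
#'   coh/phase before and after, L_before, L_after).
#' @export
simulate_paired_coherence <- function(coupling_before,
                                      coupling_after = coupling_before,
                                      n_subjects = 8, n_muscles = 5,
                                      L_before = 60, L_after = L_before,
                                      segment_length = 64,
                                      sampling_rate = 64,
                                      band = band_definition("beta", 15, 30),
                                      seed, share_drive = FALSE) {
  stopifnot(inherits(coupling_before, "coupling_model"),
            inherits(coupling_after, "coupling_model"),
            inherits(band, "band_definition"))
  if (missing(seed)) abort("`seed` is required.")
  muscles <- paste0("m", seq_len(n_muscles))
  freqs <- bin_frequencies(sampling_rate, segment_length)
  bidx <- band_bin_indices(freqs, band$f_lo, band$f_hi)
  if (length(bidx) == 0) abort("band contains no bins at this resolution.")
  nf <- length(bidx)

  per_subject <- function(s) {
    one_cond <- function(model, L, tag) {
      if (share_drive) {
        rec <- generate_coupled_pair(model, L, segment_length, sampling_rate,
                                     seed = derive_seed(seed, s, tag),
                                     muscles = muscles)
        Fx <- segment_ffts(rec$eeg)
        lapply(rec$emg, function(y) {
          est <- coh_core(Fx, segment_ffts(y))
          list(coh = est$coherence[bidx], phase = est$phase[bidx])
        })
      } else {
        lapply(stats::setNames(muscles, muscles), function(m) {
          rec <- generate_coupled_pair(model, L, segment_length, sampling_rate,
                                       seed = derive_seed(seed, s, tag, m),
                                       muscles = m)
          est <- coh_core(segment_ffts(rec$eeg), segment_ffts(rec$emg[[1]]))
          list(coh = est$coherence[bidx], phase = est$phase[bidx])
        })
      }
    }
    bef <- one_cond(coupling_before, L_before, "before")
    aft <- one_cond(coupling_after, L_after, "after")
    tibble(
      subject = s,
      muscle = rep(muscles, each = nf),
      frequency = rep(freqs[bidx], n_muscles),
      coh_before = unlist(lapply(bef, `[[`, "coh")),
      coh_after = unlist(lapply(aft, `[[`, "coh")),
      phase_before = unlist(lapply(bef, `[[`, "phase")),
      phase_after = unlist(lapply(aft, `[[`, "phase")),
      L_before = L_before, L_after = L_after)
  }
  out <- bind_rows(lapply(seq_len(n_subjects), per_subject))
  attr(out, "band") <- band
  class(out) <- c("paired_coherence", class(out))
  out
}

#' Default coupling model for calibration studies
#'
#' A coupling model on the 1 Hz calibration grid (64-sample segments at
#' 64 Hz) whose drive spans the 16-bin 15--30 Hz band with expected in-band
#' coherence about 0.4 -- inside the range where the Fisher-transform
#' variance approximation 1/(2L) is accurate.
#'
#' @param coupling_gain Gain from drive to muscle (default 1).
#' @return A [coupling_model()].
#' @export
calibration_coupling <- function(coupling_gain = 1) {
  coupling_model(drive_centre = 22.5, drive_bandwidth = 16,
                 drive_power = 0.86, coupling_gain = coupling_gain,
                 coupling_delay = 0.01, eeg_noise_power = 1,
                 emg_noise_power = 1)
}
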