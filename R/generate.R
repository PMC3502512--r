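# Synthetic session generator.
#
# The common drive is band-limited Gaussian noise built by frequency-domain
# shaping: independent complex-Gaussian Fourier coefficients at the bins whose
# centres fall inside the drive band, zero elsewhere, inverse-transformed to a
# real segment. This gives an exactly flat in-band spectrum and therefore a
# closed-form population coherence (expected_coherence), at the cost of
# physiological realism. Segments are drawn independently of one another so
# the disjoint-segment estimator's Beta(1, L-1) null is exact; a continuous
# mode (one long shaped series, cut into segments) is available for
# integration tests.

# per-bin complex-Gaussian drive coefficients for one segment grid
drive_bins <- function(centre, bandwidth, sampling_rate, nfft) {
  freqs <- bin_frequencies(sampling_rate, nfft)
  idx <- which(abs(freqs - centre) <= bandwidth / 2 & seq_along(freqs) < nfft / 2)
  if (length(idx) == 0L) {
    abort("drive band contains no frequency bins at this resolution.")
  }
  idx
}

# real N x L matrix of band-limited segments with total variance `power`;
# `extra_phase(f)` (radians, per positive-frequency bin) rotates the
# coefficients, which is how coupling delay and phase shift are applied.
shaped_segments <- function(coefs, idx, nfft, amp, phase = NULL) {
  L <- ncol(coefs)
  D <- matrix(0 + 0i, nfft, L)
  rot <- if (is.null(phase)) amp else amp * exp(-1i * phase)
  D[idx + 1L, ] <- coefs * rot
  D[nfft - idx + 1L, ] <- Conj(coefs * rot)
  Re(mvfft(D, inverse = TRUE)) / nfft
}

#' Closed-form population coherence of the coupled-oscillator model
#'
#' For EEG = drive + noise and EMG = g x (delayed drive) + noise, the
#' magnitude-squared coherence at frequency f is
#' \deqn{C(f) = \frac{g^2 S_d(f)^2}{(S_d(f) + S_{ex}(f))\,(g^2 S_d(f) + S_{ey}(f))}}
#' where \eqn{S_d} is the drive power spectral density (flat at
#' `drive_power / drive_bandwidth` inside the band, zero outside) and
#' \eqn{S_{ex}, S_{ey}} are the white-noise densities
#' (`noise_power / (sampling_rate/2)`). This is the ground truth that
#' estimator-recovery tests converge to.
#'
#' @param model A [coupling_model()].
#' @param frequency Frequency or vector of frequencies in Hz, inside
#'   (0, Nyquist).
#' @param sampling_rate Sampling rate in Hz (fixes the white-noise density).
#' @return Coherence values in \[0, 1\].
#' @export
expected_coherence <- function(model, frequency, sampling_rate = 4630) {
  stopifnot(inherits(model, "coupling_model"))
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (any(frequency <= 0 | frequency >= sampling_rate / 2)) {
    abort("`frequency` must lie strictly inside (0, Nyquist).")
  }
  in_band <- abs(frequency - model$drive_centre) <= model$drive_bandwidth / 2
  s_d <- ifelse(in_band, model$drive_power / model$drive_bandwidth, 0)
  s_ex <- model$eeg_noise_power / (sampling_rate / 2)
  s_ey <- model$emg_noise_power / (sampling_rate / 2)
  g2 <- model$coupling_gain^2
  num <- g2 * s_d^2
  den <- (s_d + s_ex) * (g2 * s_d + s_ey)
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, 0), 1)
}

check_drive_band <- function(model, sampling_rate) {
  nyq <- sampling_rate / 2
  lo <- model$drive_centre - model$drive_bandwidth / 2
  hi <- model$drive_centre + model$drive_bandwidth / 2
  if (lo <= 0 || hi >= nyq) {
    abort(sprintf(
      "drive band [%.3g, %.3g] Hz must lie strictly inside (0, Nyquist = %.3g) Hz.",
      lo, hi, nyq))
  }
}

#' Generate coupled EEG/EMG analysis segments with known coherence
#'
#' Draws `n_segments` mutually independent segment pairs from the
#' coupled-oscillator model: the EEG channel is drive + white noise; each EMG
#' channel is `coupling_gain` x (drive delayed by `coupling_delay` and rotated
#' by `coupling_phase_shift`) + independent white noise. The population
#' coherence at in-band frequencies is [expected_coherence()]; the coherence
#' phase at frequency f is `2*pi*f*coupling_delay + coupling_phase_shift`
#' (positive phase = EEG leads).
#'
#' @param model A [coupling_model()].
#' @param n_segments Number of disjoint segments L (>= 2).
#' @param segment_length Samples per segment.
#' @param sampling_rate Hz.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param muscles Character vector of EMG channel labels (one coupled channel
#'   generated per label, each with independent noise).
#' @param continuous If `TRUE`, one long shaped series of
#'   `n_segments * segment_length` samples is generated and cut into
#'   consecutive segments instead of drawing segments independently
#'   (introduces the spectral leakage of a real continuous recording).
#' @return A list with elements `eeg` (`segment_length x n_segments` matrix),
#'   `emg` (named list of matrices), `sampling_rate` and `model`.
#' @export
generate_coupled_pair <- function(model, n_segments, segment_length,
                                  sampling_rate, seed,
                                  muscles = "EMG", continuous = FALSE) {
  stopifnot(inherits(model, "coupling_model"))
  stopifnot_scalar(n_segments, "n_segments", positive = TRUE)
  if (n_segments < 2) abort("`n_segments` must be >= 2 (coherence needs L >= 2).")
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_drive_band(model, sampling_rate)
  L <- as.integer(n_segments)
  N <- as.integer(segment_length)
  nfft_gen <- if (continuous) N * L else N

  with_local_seed(seed, {
    idx <- drive_bins(model$drive_centre, model$drive_bandwidth,
                      sampling_rate, nfft_gen)
    nb <- length(idx)
    amp <- (nfft_gen / 2) * sqrt(model$drive_power / nb)
    ncol_gen <- if (continuous) 1L else L
    coefs <- matrix(complex(real = rnorm(nb * ncol_gen),
                            imaginary = rnorm(nb * ncol_gen)), nb, ncol_gen)
    f_idx <- idx * sampling_rate / nfft_gen
    theta <- 2 * pi * f_idx * model$coupling_delay + model$coupling_phase_shift

    as_segments <- function(x) if (continuous) matrix(x, N, L) else x
    drive_eeg <- as_segments(shaped_segments(coefs, idx, nfft_gen, amp))
    drive_emg <- as_segments(
      shaped_segments(coefs, idx, nfft_gen, amp * model$coupling_gain, theta))

    eeg <- drive_eeg + matrix(rnorm(N * L, sd = sqrt(model$eeg_noise_power)),
                              N, L)
    emg <- lapply(muscles, function(m) {
      drive_emg + matrix(rnorm(N * L, sd = sqrt(model$emg_noise_power)), N, L)
    })
    names(emg) <- muscles
    list(eeg = eeg, emg = emg, sampling_rate = sampling_rate, model = model)
  })
}

#' Generate a synthetic finger-acceleration recording
#'
#' Narrowband Gaussian tremor (frequency-domain shaped, flat inside
#' `tremor_freq +/- tremor_bandwidth/2`) plus white broadband noise. The power
#' in any band containing the tremor component scales linearly with
#' `tremor_power`.
#'
#' @param model A [tremor_model()].
#' @param duration Recording length in seconds (study recordings were 90 s).
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return Numeric acceleration series of `round(duration * sampling_rate)`
#'   samples.
#' @export
generate_tremor_accel <- function(model, duration, sampling_rate, seed) {
  stopifnot(inherits(model, "tremor_model"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  nyq <- sampling_rate / 2
  if (model$tremor_freq + model$tremor_bandwidth / 2 >= nyq ||
      model$tremor_freq - model$tremor_bandwidth / 2 <= 0) {
    abort("tremor band must lie strictly inside (0, Nyquist).")
  }
  n <- as.integer(round(duration * sampling_rate))
  if (n < 2) abort("recording too short.")

  with_local_seed(seed, {
    x <- rnorm(n, sd = sqrt(model$broadband_power))
    if (model$tremor_power > 0) {
      idx <- drive_bins(model$tremor_freq, model$tremor_bandwidth,
                        sampling_rate, n)
      nb <- length(idx)
      amp <- (n / 2) * sqrt(model$tremor_power / nb)
      coefs <- matrix(complex(real = rnorm(nb), imaginary = rnorm(nb)), nb, 1)
      x <- x + drop(shaped_segments(coefs, idx, n, amp))
    }
    x
  })
}

apply_effect <- function(coupling, tremor, effect) {
  coupling$coupling_gain <- coupling$coupling_gain *
    effect$coupling_gain_multiplier
  coupling$coupling_phase_shift <- coupling$coupling_phase_shift +
    effect$coupling_phase_shift
  tremor$tremor_power <- tremor$tremor_power * effect$tremor_power_multiplier
  list(coupling = coupling, tremor = tremor)
}

#' Generate a full synthetic crossover session
#'
#' For every subject and study arm, a "before" and an "after" recording set
#' is produced: precision-grip analysis segments for the EEG channel and each
#' muscle (via [generate_coupled_pair()]) and one accelerometer series (via
#' [generate_tremor_accel()]). The "after" recordings apply the arm's
#' [drug_effect()]. Per-subject baselines of coupling gain and tremor power
#' vary log-normally (sd `plan$subject_spread` on the log scale) around the
#' plan values, emulating day-to-day baseline variability. Everything is a
#' pure function of the plan seed.
#'
#' @param plan A [session_plan()].
#' @param coupling A [coupling_model()] giving the population baseline.
#' @param tremor A [tremor_model()] giving the population baseline.
#' @return A tibble of class `tremor_session` with one row per
#'   (subject, arm, condition, channel); `data` is a list-column holding a
#'   `segment_length x L` segment matrix for EEG/EMG rows and a numeric
#'   series for ACC rows.
#' @export
generate_session <- function(plan,
                             coupling = coupling_model(),
                             tremor = tremor_model()) {
  stopifnot(inherits(plan, "session_plan"))
  stopifnot(inherits(coupling, "coupling_model"))
  stopifnot(inherits(tremor, "tremor_model"))
  check_drive_band(coupling, plan$sampling_rate)
  L <- plan$n_trials * plan$sections_per_trial

  rows <- list()
  for (s in seq_len(plan$n_subjects)) {
    fac <- with_local_seed(derive_seed(plan$seed, "subject", s), {
      exp(rnorm(2, 0, plan$subject_spread))
    })
    cpl_s <- coupling
    cpl_s$coupling_gain <- cpl_s$coupling_gain * fac[1]
    trm_s <- tremor
    trm_s$tremor_power <- trm_s$tremor_power * fac[2]

    for (arm in names(plan$arms)) {
      eff <- plan$arms[[arm]]
      for (cond in c("before", "after")) {
        mods <- if (cond == "after") {
          apply_effect(cpl_s, trm_s, eff)
        } else {
          list(coupling = cpl_s, tremor = trm_s)
        }
        grip <- generate_coupled_pair(
          mods$coupling, L, plan$segment_length, plan$sampling_rate,
          seed = derive_seed(plan$seed, s, arm, cond, "grip"),
          muscles = plan$muscles)
        acc <- generate_tremor_accel(
          mods$tremor, plan$accel_duration, plan$sampling_rate,
          seed = derive_seed(plan$seed, s, arm, cond, "accel"))
        chans <- c("EEG", plan$muscles, "ACC")
        roles <- c("EEG", rep("EMG", length(plan$muscles)), "ACC")
        dat <- c(list(grip$eeg), grip$emg, list(acc))
        rows[[length(rows) + 1L]] <- tibble(
          subject = s, arm = arm, condition = cond,
          channel = chans, role = roles, data = dat)
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "plan") <- plan
  attr(out, "coupling") <- coupling
  attr(out, "tremor") <- tremor
  class(out) <- c("tremor_session", class(out))
  out
}
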