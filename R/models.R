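#' Coupled-oscillator model of corticomuscular drive
#'
#' Describes the generative model behind the synthetic precision-grip
#' recordings: a band-limited Gaussian common drive (flat spectral density
#' inside `drive_band`, zero outside) appears directly in the EEG channel and,
#' scaled by `coupling_gain` and delayed by `coupling_delay`, in every
#' rectified-EMG channel; independent broadband Gaussian noise is added to
#' each channel. Under this model the population coherence between EEG and an
#' EMG channel has the closed form evaluated by [expected_coherence()], which
#' is what makes the generator usable as ground truth for estimator
#' calibration.
#'
#' @param drive_centre Centre frequency of the shared oscillatory drive (Hz).
#'   Default 22.5 Hz, the middle of the 15.3--32.2 Hz beta analysis band.
#' @param drive_bandwidth Full width of the drive band (Hz).
#' @param drive_power Variance of the band-limited drive signal.
#' @param coupling_gain Dimensionless gain from drive to each EMG channel
#'   (>= 0; 0 disconnects cortex from muscle).
#' @param coupling_delay Corticomuscular propagation lag in seconds; sets the
#'   slope of the coherence phase across frequency. Default 0.015 s, a typical
#'   cortex-to-hand-muscle conduction delay.
#' @param coupling_phase_shift Additional frequency-independent phase offset
#'   (radians) applied to the drive as seen by the muscles.
#' @param eeg_noise_power,emg_noise_power Variances of the independent white
#'   noise added to the EEG channel and to each EMG channel.
#'
#' @return An object of class `coupling_model`.
#' @seealso [expected_coherence()], [generate_coupled_pair()]
#' @export
coupling_model <- function(drive_centre = 22.5,
                           drive_bandwidth = 10,
                           drive_power = 0.003,
                           coupling_gain = 1,
                           coupling_delay = 0.015,
                           coupling_phase_shift = 0,
                           eeg_noise_power = 1,
                           emg_noise_power = 1) {
  stopifnot_scalar(drive_centre, "drive_centre", positive = TRUE)
  stopifnot_scalar(drive_bandwidth, "drive_bandwidth", positive = TRUE)
  for (nm in c("drive_power", "coupling_gain", "eeg_noise_power",
               "emg_noise_power")) {
    v <- get(nm)
    stopifnot_scalar(v, nm)
    if (v < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  stopifnot_scalar(coupling_delay, "coupling_delay")
  stopifnot_scalar(coupling_phase_shift, "coupling_phase_shift")
  if (drive_centre - drive_bandwidth / 2 <= 0) {
    abort("drive band must lie strictly above 0 Hz.")
  }
  structure(
    list(drive_centre = drive_centre, drive_bandwidth = drive_bandwidth,
         drive_power = drive_power, coupling_gain = coupling_gain,
         coupling_delay = coupling_delay,
         coupling_phase_shift = coupling_phase_shift,
         eeg_noise_power = eeg_noise_power, emg_noise_power = emg_noise_power),
    class = "coupling_model"
  )
}

#' Narrowband physiological tremor model for finger acceleration
#'
#' The acceleration channel is modelled as band-limited Gaussian noise centred
#' on `tremor_freq` (the ~10 Hz tremor peak seen during index-finger
#' extension) plus independent white noise. Band power in any band containing
#' the tremor component scales linearly in `tremor_power`, which is the
#' property drug-effect recovery tests rely on.
#'
#' @param tremor_freq Tremor peak frequency (Hz); default 9 Hz, inside the
#'   6.2--11.9 Hz physiological-tremor analysis band.
#' @param tremor_bandwidth Full width of the tremor component (Hz).
#' @param tremor_power Variance of the narrowband tremor component.
#' @param broadband_power Variance of the additive white noise floor.
#'
#' @return An object of class `tremor_model`.
#' @seealso [generate_tremor_accel()]
#' @export
tremor_model <- function(tremor_freq = 9,
                         tremor_bandwidth = 3,
                         tremor_power = 1,
                         broadband_power = 1) {
  stopifnot_scalar(tremor_freq, "tremor_freq", positive = TRUE)
  stopifnot_scalar(tremor_bandwidth, "tremor_bandwidth", positive = TRUE)
  stopifnot_scalar(tremor_power, "tremor_power")
  stopifnot_scalar(broadband_power, "broadband_power")
  if (tremor_power < 0 || broadband_power < 0) {
    abort("tremor_power and broadband_power must be >= 0.")
  }
  if (tremor_freq - tremor_bandwidth / 2 <= 0) {
    abort("tremor band must lie strictly above 0 Hz.")
  }
  structure(
    list(tremor_freq = tremor_freq, tremor_bandwidth = tremor_bandwidth,
         tremor_power = tremor_power, broadband_power = broadband_power),
    class = "tremor_model"
  )
}

#' Multiplicative drug effect applied to the "after" recordings of an arm
#'
#' Parameterises the phenomenology a crossover pharmacology study must detect:
#' a multiplicative change in tremor power, a multiplicative change in
#' corticomuscular coupling gain, and an additive shift of the coupling phase.
#' The identity effect (`1, 1, 0`) models a placebo arm.
#'
#' @param tremor_power_multiplier Factor applied to tremor power (>= 0).
#' @param coupling_gain_multiplier Factor applied to coupling gain (>= 0).
#' @param coupling_phase_shift Additive coupling phase change in radians,
#'   in (-pi, pi].
#'
#' @return An object of class `drug_effect`.
#' @export
drug_effect <- function(tremor_power_multiplier = 1,
                        coupling_gain_multiplier = 1,
                        coupling_phase_shift = 0) {
  stopifnot_scalar(tremor_power_multiplier, "tremor_power_multiplier")
  stopifnot_scalar(coupling_gain_multiplier, "coupling_gain_multiplier")
  stopifnot_scalar(coupling_phase_shift, "coupling_phase_shift")
  if (tremor_power_multiplier < 0 || coupling_gain_multiplier < 0) {
    abort("drug-effect multipliers must be >= 0.")
  }
  if (coupling_phase_shift <= -pi || coupling_phase_shift > pi) {
    abort("coupling_phase_shift must lie in (-pi, pi].")
  }
  structure(
    list(tremor_power_multiplier = tremor_power_multiplier,
         coupling_gain_multiplier = coupling_gain_multiplier,
         coupling_phase_shift = coupling_phase_shift),
    class = "drug_effect"
  )
}

#' Study design for a synthetic crossover session
#'
#' Defaults mirror the study protocol the package emulates: 8 subjects, five
#' hand/forearm muscles (1DI, AbPB, AbDM, FDS, EDC), 80 precision-grip trials
#' with three 4096-sample hold-phase sections each (so L = 240 disjoint
#' segments per recording), 4630 Hz sampling, and three arms -- placebo
#' (identity effect), propranolol-like (coherence up, tremor down) and
#' salbutamol-like (tremor up, coherence unchanged, phase reduced).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param muscles Character vector of EMG channel labels.
#' @param n_trials Precision-grip trials per recording.
#' @param sections_per_trial Contiguous hold-phase sections taken per trial;
#'   the coherence segment count is `n_trials * sections_per_trial`.
#' @param sampling_rate Sampling rate in Hz.
#' @param segment_length Samples per analysis segment (a power of two).
#' @param accel_duration Length of the accelerometer recording in seconds.
#' @param arms Named list of [drug_effect()] objects, one per study arm.
#' @param subject_spread Log-scale standard deviation of the per-subject
#'   log-normal variation of baseline coupling gain and tremor power
#'   (default 0.3), emulating the high day-to-day variability of baseline
#'   tremor and coherence.
#' @param seed Integer seed from which all randomness in the session derives.
#'
#' @return An object of class `session_plan`.
#' @seealso [generate_session()]
#' @export
session_plan <- function(n_subjects = 8,
                         muscles = c("1DI", "AbPB", "AbDM", "FDS", "EDC"),
                         n_trials = 80,
                         sections_per_trial = 3,
                         sampling_rate = 4630,
                         segment_length = 4096,
                         accel_duration = 90,
                         arms = list(
                           placebo = drug_effect(1, 1, 0),
                           propranolol = drug_effect(0.6, 1.5, 0),
                           salbutamol = drug_effect(3, 1, -0.12)
                         ),
                         subject_spread = 0.3,
                         seed = 1L) {
  stopifnot_scalar(n_subjects, "n_subjects", positive = TRUE)
  stopifnot_scalar(n_trials, "n_trials", positive = TRUE)
  stopifnot_scalar(sections_per_trial, "sections_per_trial", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(segment_length, "segment_length", positive = TRUE)
  stopifnot_scalar(accel_duration, "accel_duration", positive = TRUE)
  stopifnot_scalar(subject_spread, "subject_spread")
  stopifnot_scalar(seed, "seed")
  if (length(muscles) < 1 || anyDuplicated(muscles)) {
    abort("`muscles` must be a non-empty set of unique labels.")
  }
  if (n_trials * sections_per_trial < 2) {
    abort("n_trials * sections_per_trial must be >= 2 (coherence needs L >= 2).")
  }
  if (bitwAnd(as.integer(segment_length), as.integer(segment_length) - 1L) != 0L) {
    abort("`segment_length` must be a power of two.")
  }
  if (length(arms) < 1) abort("`arms` must contain at least one arm.")
  if (is.null(names(arms)) || any(names(arms) == "") ||
      anyDuplicated(names(arms))) {
    abort("`arms` must be a named list with unique, non-empty labels.")
  }
  for (a in arms) {
    if (!inherits(a, "drug_effect")) abort("each arm must be a drug_effect().")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), muscles = muscles,
         n_trials = as.integer(n_trials),
         sections_per_trial = as.integer(sections_per_trial),
         sampling_rate = sampling_rate,
         segment_length = as.integer(segment_length),
         accel_duration = accel_duration, arms = arms,
         subject_spread = subject_spread, seed = as.integer(seed)),
    class = "session_plan"
  )
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf(
    "<coupling_model> drive %.1f +/- %.1f Hz (power %.4g), gain %.3g, delay %.3g s, noise EEG %.3g / EMG %.3g\n",
    x$drive_centre, x$drive_bandwidth / 2, x$drive_power, x$coupling_gain,
    x$coupling_delay, x$eeg_noise_power, x$emg_noise_power))
  invisible(x)
}

#' @export
print.tremor_model <- function(x, ...) {
  cat(sprintf(
    "<tremor_model> %.1f +/- %.1f Hz, tremor power %.3g, broadband %.3g\n",
    x$tremor_freq, x$tremor_bandwidth / 2, x$tremor_power, x$broadband_power))
  invisible(x)
}

#' @export
print.drug_effect <- function(x, ...) {
  cat(sprintf(
    "<drug_effect> tremor x%.3g, coupling x%.3g, phase %+.3g rad\n",
    x$tremor_power_multiplier, x$coupling_gain_multiplier,
    x$coupling_phase_shift))
  invisible(x)
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf(
    "<session_plan> %d subjects x %d muscles, %d trials x %d sections (L = %d), fs %.4g Hz, nfft %d, arms: %s, seed %d\n",
    x$n_subjects, length(x$muscles), x$n_trials, x$sections_per_trial,
    x$n_trials * x$sections_per_trial, x$sampling_rate, x$segment_length,
    paste(names(x$arms), collapse = ", "), x$seed))
  invisible(x)
}
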