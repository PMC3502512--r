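# Small fixture builders shared across test files. All simulations here run
# on a 1 Hz-resolution grid (64-sample segments at 64 Hz) where the beta-like
# drive band 15-30 Hz holds 16 bins; statistics are invariant to the absolute
# grid, so this keeps the suite fast.

fix_fs <- 64
fix_nfft <- 64

# coupling with expected in-band coherence ~0.4 on the fixture grid
fix_coupling <- function(gain = 1) calibration_coupling(coupling_gain = gain)

fix_band <- function() band_definition("beta", 15, 30)

# band set scaled to the fixture grid's 32 Hz Nyquist
fix_bands <- function() {
  list(tremor = band_definition("tremor", 6.2, 11.9), beta = fix_band())
}

# a small but complete crossover plan on the fixture grid
fix_plan <- function(n_subjects = 4, muscles = c("m1", "m2"),
                     n_trials = 20, seed = 42,
                     arms = list(placebo = drug_effect(),
                                 propranolol = drug_effect(0.6, 1.5, 0)),
                     accel_duration = 32, subject_spread = 0.3) {
  session_plan(n_subjects = n_subjects, muscles = muscles,
               n_trials = n_trials, sections_per_trial = 3,
               sampling_rate = fix_fs, segment_length = fix_nfft,
               accel_duration = accel_duration, arms = arms,
               subject_spread = subject_spread, seed = seed)
}

fix_tremor <- function(power = 1, broadband = 0.2) {
  tremor_model(tremor_freq = 9, tremor_bandwidth = 3,
               tremor_power = power, broadband_power = broadband)
}

# white-noise segment matrix
noise_segments <- function(n, L, sd = 1) matrix(rnorm(n * L, sd = sd), n, L)
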