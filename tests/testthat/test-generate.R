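# The generator's closed-form coherence is the ground truth everything else
# is calibrated against, so its own tests use independent oracles: direct
# evaluation of the spectral-density formula, and brute-force Monte Carlo
# over replicate generations.

test_that("expected_coherence evaluates the closed spectral-density form", {
  # no coupling -> zero everywhere
  m0 <- coupling_model(coupling_gain = 0)
  expect_equal(expected_coherence(m0, c(5, 22.5, 40), 4630), c(0, 0, 0))

  # noiseless coupled channels -> coherence 1 in band, 0 outside
  m1 <- coupling_model(drive_centre = 20, drive_bandwidth = 8,
                       drive_power = 1, coupling_gain = 2,
                       eeg_noise_power = 0, emg_noise_power = 0)
  expect_equal(expected_coherence(m1, 20, 200), 1)
  expect_equal(expected_coherence(m1, 50, 200), 0)

  # equal unit densities: S_d = S_ex = S_ey = 1, g = 1 -> 1/4
  # (fs = 200 so Nyquist = 100: noise power 100 gives density 1;
  #  drive power 10 over 10 Hz bandwidth gives density 1)
  m2 <- coupling_model(drive_centre = 20, drive_bandwidth = 10,
                       drive_power = 10, coupling_gain = 1,
                       eeg_noise_power = 100, emg_noise_power = 100)
  expect_equal(expected_coherence(m2, 20, 200), 1 / 4)

  expect_error(expected_coherence(m2, 150, 200), "Nyquist")
})

test_that("generated pairs reproduce the null, perfect and noisy coherence regimes", {
  # zero gain: mean estimated coherence ~ 1/L (Beta(1, L-1) null mean)
  L <- 50
  m0 <- coupling_model(drive_power = 0.86, drive_bandwidth = 16,
                       coupling_gain = 0)
  p0 <- generate_coupled_pair(m0, L, fix_nfft, fix_fs, seed = 5)
  c0 <- coherence_spectrum(p0$eeg, p0$emg[[1]], fix_fs)
  bins <- c0$coherence[seq_len(31)]        # below-Nyquist bins
  se <- sqrt(var(bins) / length(bins))
  expect_lt(abs(mean(bins) - 1 / L), 3 * se + 0.003)

  # no noise: coherence 1 at drive bins
  m1 <- coupling_model(drive_centre = 22.5, drive_bandwidth = 16,
                       drive_power = 1, coupling_gain = 1,
                       eeg_noise_power = 0, emg_noise_power = 0)
  p1 <- generate_coupled_pair(m1, 20, fix_nfft, fix_fs, seed = 6)
  c1 <- coherence_spectrum(p1$eeg, p1$emg[[1]], fix_fs)
  expect_true(all(c1$coherence[c1$frequency >= 15 & c1$frequency <= 30] >
                    1 - 1e-9))

  # Monte Carlo mean at the drive centre matches the closed form (L = 500,
  # 200 replicate generations, 3 MC standard errors)
  cm <- fix_coupling()
  target <- expected_coherence(cm, 22, fix_fs)
  est <- vapply(1:200, function(r) {
    p <- generate_coupled_pair(cm, 500, fix_nfft, fix_fs, seed = 1000 + r)
    cs <- coherence_spectrum(p$eeg, p$emg[[1]], fix_fs)
    cs$coherence[cs$frequency == 22]
  }, numeric(1))
  expect_lt(abs(mean(est) - target), 3 * sd(est) / sqrt(200) + 2 / 500)

  expect_error(generate_coupled_pair(cm, 1, fix_nfft, fix_fs, seed = 1),
               "L >= 2")
  bad <- coupling_model(drive_centre = 40, drive_bandwidth = 4)
  expect_error(generate_coupled_pair(bad, 10, fix_nfft, fix_fs, seed = 1),
               "Nyquist")
})

test_that("coherence phase tracks the coupling delay and phase shift", {
  cm <- coupling_model(drive_centre = 22.5, drive_bandwidth = 16,
                       drive_power = 0.86, coupling_gain = 1,
                       coupling_delay = 0.01, coupling_phase_shift = 0.3)
  ph <- vapply(1:300, function(r) {
    p <- generate_coupled_pair(cm, 60, fix_nfft, fix_fs, seed = 2000 + r)
    cs <- coherence_spectrum(p$eeg, p$emg[[1]], fix_fs)
    cs$phase[cs$frequency == 22]
  }, numeric(1))
  target <- 2 * pi * 22 * 0.01 + 0.3
  expect_lt(abs(mean(ph) - target), 4 * sd(ph) / sqrt(300))
})

test_that("continuous-recording mode preserves the coherence structure", {
  cm <- fix_coupling()
  p <- generate_coupled_pair(cm, 400, fix_nfft, fix_fs, seed = 9,
                             continuous = TRUE)
  expect_equal(dim(p$eeg), c(fix_nfft, 400))
  cs <- coherence_spectrum(p$eeg, p$emg[[1]], fix_fs)
  inband <- mean(cs$coherence[cs$frequency >= 17 & cs$frequency <= 28])
  expect_gt(inband, 0.25)
  outband <- mean(cs$coherence[cs$frequency <= 10])
  expect_lt(outband, 0.05)
})

test_that("tremor generator is flat without tremor and linear in tremor power", {
  fs <- 128
  # no tremor: band power ~ bandwidth fraction of total
  m0 <- tremor_model(tremor_freq = 9, tremor_bandwidth = 3,
                     tremor_power = 0, broadband_power = 1)
  a0 <- generate_tremor_accel(m0, 120, fs, seed = 3)
  sp0 <- power_spectrum(segment_sequential(a0, 128), fs)
  band <- band_definition("t", 6.2, 11.9)
  frac <- band_power(sp0, band) / sum(sp0$power)
  n_band_bins <- sum(sp0$frequency >= 6.2 & sp0$frequency <= 11.9)
  expect_lt(abs(frac - n_band_bins / nrow(sp0)), 0.02)

  # doubling tremor_power doubles tremor-band power (100 replicates)
  ratios <- vapply(1:100, function(r) {
    m1 <- tremor_model(9, 3, tremor_power = 1, broadband_power = 0)
    m2 <- tremor_model(9, 3, tremor_power = 2, broadband_power = 0)
    a1 <- generate_tremor_accel(m1, 16, fs, seed = 100 + r)
    a2 <- generate_tremor_accel(m2, 16, fs, seed = 900 + r)
    band_power(power_spectrum(segment_sequential(a2, 128), fs), band) /
      band_power(power_spectrum(segment_sequential(a1, 128), fs), band)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 3 * sd(ratios) / sqrt(100))

  # 8 Hz tremor peaks within one bin of 8 Hz at the study's 1.13 Hz resolution
  fs_hi <- 4630 / 8                       # 1.1304 Hz bins with 512-sample segments
  m8 <- tremor_model(8, 2, tremor_power = 4, broadband_power = 0.5)
  a8 <- generate_tremor_accel(m8, 400, fs_hi, seed = 12)
  sp8 <- power_spectrum(segment_sequential(a8, 512), fs_hi)
  peak <- sp8$frequency[which.max(sp8$power)]
  expect_lt(abs(peak - 8), 4630 / 4096 + 1e-9)

  expect_error(generate_tremor_accel(tremor_model(50, 30), 10, fs, seed = 1),
               "Nyquist")
})

test_that("sessions are reproducible and carry the arm effects", {
  plan <- fix_plan(n_subjects = 3, muscles = "m1", n_trials = 8,
                   arms = list(salbutamol = drug_effect(3, 1, 0)),
                   accel_duration = 64, subject_spread = 0.3, seed = 7)
  s1 <- generate_session(plan, fix_coupling(), fix_tremor(broadband = 0.05))
  s2 <- generate_session(plan, fix_coupling(), fix_tremor(broadband = 0.05))
  expect_identical(s1$data, s2$data)      # same seed -> bit-identical

  plan3 <- fix_plan(n_subjects = 3, muscles = "m1", n_trials = 8,
                    arms = list(salbutamol = drug_effect(3, 1, 0)),
                    accel_duration = 64, subject_spread = 0.3, seed = 8)
  s3 <- generate_session(plan3, fix_coupling(), fix_tremor(broadband = 0.05))
  expect_false(identical(s1$data, s3$data))

  # tremor x3 arm: after/before tremor band-power ratio ~ 3 across subjects
  band <- band_definition("t", 6.2, 11.9)
  ratios <- vapply(1:3, function(s) {
    rows <- s1[s1$subject == s & s1$role == "ACC", ]
    bp <- vapply(c("before", "after"), function(cond) {
      a <- rows$data[[which(rows$condition == cond)]]
      band_power(power_spectrum(segment_sequential(a, fix_nfft), fix_fs), band)
    }, numeric(1))
    bp[["after"]] / bp[["before"]]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.45)
})

test_that("an identity drug effect is a true null for the pooled Z", {
  plan <- fix_plan(n_subjects = 2, muscles = "m1", n_trials = 8,
                   arms = list(placebo = drug_effect()),
                   accel_duration = 4, subject_spread = 0.2)
  zs <- vapply(1:30, function(r) {
    p <- fix_plan(n_subjects = 2, muscles = "m1", n_trials = 8,
                  arms = list(placebo = drug_effect()),
                  accel_duration = 4, subject_spread = 0.2, seed = 5000 + r)
    sess <- generate_session(p, fix_coupling(), fix_tremor())
    coh <- session_coherence(sess)
    coherence_diff_z(pair_conditions(coh, fix_band()))$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(30))
})
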