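# helper: hand-built paired set with explicit columns
paired_set <- function(cb, ca, Lb = 60, La = Lb, band = fix_band()) {
  out <- tibble::tibble(
    subject = seq_along(cb), muscle = "m1", frequency = 20,
    coh_before = cb, coh_after = ca,
    phase_before = 0, phase_after = 0, L_before = Lb, L_after = La)
  attr(out, "band") <- band
  class(out) <- c("paired_coherence", class(out))
  out
}

test_that("pooled Z is zero on identity, antisymmetric, and guards its domain", {
  set.seed(41)
  c0 <- runif(20, 0.1, 0.6)
  z0 <- coherence_diff_z(paired_set(c0, c0))
  expect_equal(z0$z, 0)
  expect_equal(z0$p_two_sided, 1)

  c1 <- pmin(c0 + runif(20, 0, 0.3), 0.95)
  expect_equal(coherence_diff_z(paired_set(c0, c1))$z,
               -coherence_diff_z(paired_set(c1, c0))$z)

  expect_warning(zc <- coherence_diff_z(paired_set(c(0.2, 1), c(0.3, 0.4))),
                 "clamped")
  expect_true(is.finite(zc$z))
  expect_error(coherence_diff_z(paired_set(numeric(0), numeric(0))), "empty")
  expect_error(coherence_diff_z(paired_set(0.2, 0.3, Lb = 1)), ">= 2")
})

test_that("pooled Z is approximately standard normal under a simulated null", {
  zs <- vapply(1:150, function(r) {
    s <- simulate_paired_coherence(fix_coupling(), n_subjects = 4,
                                   n_muscles = 2, L_before = 60,
                                   band = fix_band(), seed = 7000 + r)
    coherence_diff_z(s)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(150))
  expect_lt(abs(var(zs) - 1), 3 * sqrt(2 / 150) + 0.05)
})

test_that("pooled Z power grows monotonically with the coupling-gain effect", {
  mean_z <- vapply(c(1, 1.2, 1.5), function(mult) {
    zs <- vapply(1:25, function(r) {
      s <- simulate_paired_coherence(
        fix_coupling(), fix_coupling(gain = mult), n_subjects = 2,
        n_muscles = 2, L_before = 40, band = fix_band(),
        seed = round(8000 + 100 * mult) + r)
      coherence_diff_z(s)$z
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_z) > 0))
  expect_gt(mean_z[3], 3)                  # strong effect -> near-certain rejection
})

test_that("the placebo contrast is the 1/sqrt(2)-scaled Z difference", {
  z1 <- coherence_diff_z(paired_set(c(0.2, 0.3), c(0.5, 0.6)))
  expect_equal(delta_z(z1, z1)$delta_z, 0)

  fake_z <- function(z) structure(list(z = z, band = fix_band()), class = "coh_z")
  dz <- delta_z(fake_z(3.0), fake_z(0.2))
  expect_equal(dz$delta_z, 2.8 / sqrt(2))
  expect_equal(round(dz$delta_z, 3), 1.980)

  other_band <- paired_set(c(0.2, 0.3), c(0.5, 0.6),
                           band = band_definition("x", 5, 10))
  expect_error(delta_z(z1, coherence_diff_z(other_band)), "different bands")
})

test_that("paired band tests reject degenerate differences and hold their size", {
  expect_error(paired_band_test(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_band_test(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_band_test(1:3, 1:4), "length")

  set.seed(42)
  rej <- mean(vapply(1:4000, function(r) {
    b <- rnorm(8)
    paired_band_test(b, b + rnorm(8))$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("the exact sign test reproduces the binomial tail probabilities", {
  t78 <- sign_binomial_test(7, 8)
  expect_equal(t78$p_two_sided, 2 * (choose(8, 7) + choose(8, 8)) / 2^8)
  expect_equal(t78$p_one_sided, (choose(8, 7) + choose(8, 8)) / 2^8)
  expect_lt(t78$p_one_sided, 0.05)        # significant only one-sided
  expect_gt(t78$p_two_sided, 0.05)
  expect_equal(sign_binomial_test(4, 8)$p_two_sided, 1)
  expect_equal(sign_binomial_test(8, 8)$p_two_sided, 2 / 256)
  expect_error(sign_binomial_test(3, 0), "n_total")
  expect_error(sign_binomial_test(9, 8), "n_success")
})

test_that("phase pairs are selected where coherence is significant in both conditions", {
  # nothing significant -> empty, and that is a valid result
  low <- paired_set(rep(0.001, 10), rep(0.001, 10))
  expect_identical(nrow(select_phase_pairs(low, 0.05)), 0L)

  # everything near 1 -> all band bins selected
  high <- paired_set(rep(0.98, 10), rep(0.97, 10))
  expect_identical(nrow(select_phase_pairs(high, 0.05)), 10L)

  # with coupling confined to 18-25 Hz, selections cluster inside the drive band
  cm <- coupling_model(drive_centre = 21.5, drive_bandwidth = 7,
                       drive_power = 2, coupling_gain = 1,
                       coupling_delay = 0.01)
  s <- simulate_paired_coherence(cm, n_subjects = 4, n_muscles = 2,
                                 L_before = 60, band = fix_band(), seed = 91)
  sel <- select_phase_pairs(s, 0.05)
  expect_gt(nrow(sel), 10)
  expect_true(all(sel$frequency >= 15 & sel$frequency <= 30))
  expect_gt(mean(sel$frequency >= 18 & sel$frequency <= 25), 0.9)
})

test_that("circular mean handles wraparound and degenerate resultants", {
  expect_equal(circular_mean(c(0, 0)), 0)
  expect_equal(circular_mean(c(pi / 2, pi / 2)), pi / 2)
  delta <- 0.05
  m <- circular_mean(c(-3 * pi / 4 + delta, 3 * pi / 4 + delta))
  expect_equal(m, delta - pi)             # pi + delta wrapped into (-pi, pi]
  expect_error(circular_mean(numeric(0)), "non-empty")
  expect_error(circular_mean(c(0, pi)), "undefined")
})

test_that("the phase shuffle test is exact on identity, sensitive to shifts, and seeded", {
  ph <- runif(30, -1, 1)
  same <- tibble::tibble(phase_before = ph, phase_after = ph)
  r0 <- phase_shuffle_test(same, n_shuffles = 500, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)

  # +0.5 rad shift with 0.2 rad noise on 50 pairs: far outside the null
  set.seed(43)
  before <- runif(50, -0.5, 0.5)
  shifted <- tibble::tibble(phase_before = before,
                            phase_after = before + 0.5 + rnorm(50, 0, 0.2))
  rs <- phase_shuffle_test(shifted, n_shuffles = 1e4, seed = 2)
  expect_lt(rs$p, 0.01)
  expect_equal(rs$circ_mean_difference, 0.5, tolerance = 0.15)

  # reproducible from seed, and p never exactly zero
  rs2 <- phase_shuffle_test(shifted, n_shuffles = 1e4, seed = 2)
  expect_identical(tidy(rs), tidy(rs2))
  expect_gt(rs$p, 0)

  expect_error(phase_shuffle_test(shifted[1, ], 500, seed = 1), "2 phase pairs")
  expect_error(phase_shuffle_test(shifted, 50, seed = 1), ">= 100")
  expect_error(phase_shuffle_test(shifted, 500), "required")
})

test_that("tidiers expose the fitted statistics as one-row tibbles", {
  z <- coherence_diff_z(paired_set(c(0.2, 0.3), c(0.4, 0.5)))
  td <- tidy(z)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("z", "p_value", "n_terms", "n_subjects", "n_muscles",
                     "band"))
  expect_identical(glance(z), td)

  dz <- delta_z(z, z)
  expect_named(tidy(dz), c("delta_z", "z_drug", "z_placebo", "p_value", "band"))

  ph <- tibble::tibble(phase_before = runif(10), phase_after = runif(10))
  expect_named(tidy(phase_shuffle_test(ph, 200, seed = 5)),
               c("circ_mean_before", "circ_mean_after", "circ_mean_difference",
                 "statistic", "n_pairs", "n_shuffles", "n_exceeding",
                 "p_value", "p_raw"))
})
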