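---
title: "Corticomuscular coherence and tremor: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corticomuscular coherence and tremor: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorcoh)
```

tremorcoh analyses crossover pharmacology studies in which each subject
provides a "before" and an "after" recording in each arm (e.g. placebo,
a beta-blocker, a beta-agonist), and the outcomes of interest are
beta-band (15.3–32.2 Hz) corticomuscular coherence during a precision
grip and ~10 Hz physiological tremor (6.2–11.9 Hz) from finger
accelerometry. This vignette describes the underlying models, the
estimators and their null laws, the statistics used to compare arms, the
synthetic-data generator that makes the whole chain testable, and the
design decisions taken where more than one reasonable choice existed.

## Spectral estimation

All spectra are segment averaged: a recording is cut into L disjoint,
consecutive segments (no overlap, rectangular window), each segment has
its mean removed, and periodograms are averaged. Defaults follow the
protocol the package emulates — 4096-sample segments at 4630 Hz, i.e.
0.88 s segments and 1.13 Hz bins; for the grip task, three contiguous
hold-phase sections per trial over 80 trials give L = 240. The
zero-frequency bin is dropped everywhere: full-wave rectified EMG
carries a large DC offset that no band total should include. Scaling is
Parseval-consistent (raw bin powers sum to the mean per-segment
variance), EEG/EMG spectra are normalised to their own total power, and
acceleration spectra to the total of the day's first recording so that
overall tremor-power changes remain visible. Band membership is decided
by bin *centre* within the closed interval — at 1.13 Hz resolution the
tremor band 6.2–11.9 Hz therefore holds exactly bins 6–10 — which makes
bin counts deterministic under reimplementation.

Two tunable choices deserve a note. Rectangular windows and disjoint
segments are not what a general-purpose spectral library would pick
(Welch overlap with tapering usually has lower variance), but they are
what makes the coherence null law below *exact*, and the downstream
statistics lean on that exactness. And per-segment mean removal is the
only detrending applied: anything stronger would alter band powers.

## Coherence and its null laws

Coherence between the EEG channel and a rectified EMG channel is
estimated from the summed cross- and auto-spectra of the L segments.
With independent Gaussian inputs the per-bin estimate is exactly
Beta(1, L−1), so the single-spectrum significance limit at level
$\alpha$ is the closed form $1-\alpha^{1/(L-1)}$. For coherence averaged
over K subject × muscle spectra the package evaluates the null of the
*mean* of K independent Beta(1, L−1) variables by Monte Carlo (10⁵
draws under a fixed internal seed, so the limit is deterministic); the
K = 1 case returns the closed form, and the K → ∞ behaviour agrees with
the central-limit approximation $1/L + z_{1-\alpha}\sigma/\sqrt{K}$ to
within 2%, both of which are enforced by tests. Averaging is the
arithmetic mean of coherence *magnitudes*, not of pooled cross-spectra:
an averaged spectrum is plotted against its own averaged-null limit.

Phase is the argument of the summed cross-spectrum
$\sum_i X_i \overline{Y_i}$ with X = EEG, so positive phase means the
EEG leads the muscle. The convention matters because the drug-phase test
below is signed.

## The pooled difference-of-coherence statistics

The variance-stabilising transform of coherence is
$z = \tanh^{-1}\sqrt{C}$, with variance approximately $1/(2L)$. For
each (subject, muscle, band-bin) triple the package forms the
before/after difference and pools:

$$Z = \frac{\sum_{n,m,f} \left(\tanh^{-1}\sqrt{C^{A}_{n,m}(f)} -
\tanh^{-1}\sqrt{C^{B}_{n,m}(f)}\right)}
{\sqrt{\sum_{n,m,f} \left(\tfrac{1}{2L_A}+\tfrac{1}{2L_B}\right)}}$$

Under the null that coherence is unchanged, Z is standard normal; the
drug-versus-placebo contrast $\Delta Z = (Z_d - Z_p)/\sqrt 2$ is again
standard normal when both substances change coherence equally. These
distributional claims are the statistics' defining contract, and the
package verifies them by simulation rather than taking them on faith:
2000 replicate null crossover studies (8 subjects × 5 muscles × 16 band
bins, L = 60) must give Z with mean 0 and variance 1 within three
standard errors and pass a Kolmogorov–Smirnov test against N(0, 1).

Two caveats that the calibration experiments exposed, and that a user
should know:

- **The unit-variance claim needs non-trivial coherence.** As the true
  coherence approaches zero, the variance of $\tanh^{-1}\sqrt{\hat C}$
  falls from $1/(2L)$ towards $(1-\pi/4)/L$, so Z becomes conservative.
  Calibration studies therefore use an in-band coherence of about 0.4,
  squarely in the regime where the approximation is accurate; beta-band
  coherence in real grip data is lower, which errs on the conservative
  side.
- **Pooling across muscles assumes independent terms.** Frequency bins
  from disjoint rectangular-window segments are exactly independent, but
  five muscles recorded against one shared EEG channel are not: their
  coherence estimates co-fluctuate through the shared cortical signal,
  which inflates the variance of the pooled sum above 1. The null
  calibration accordingly simulates independent recordings per
  (subject, muscle) — `simulate_paired_coherence(share_drive = FALSE)` —
  while `share_drive = TRUE` reproduces the physiological layout for
  power studies. On real shared-EEG data the pooled Z should be read as
  anticonservative to a degree that grows with inter-muscle coupling.

Unequal segment counts before/after are supported through the summed
per-term variances. Estimates exactly equal to 1 (possible only in
degenerate noiseless data) are clamped to $1-1/(2L)$ with a warning
rather than propagating an infinite transform.

## Band-power, sign and phase tests

Per-subject band powers are compared with classical paired t-tests, and
the per-subject *changes* of a drug arm against the placebo arm with a
second paired t-test plus an exact binomial sign test on the direction
of change. Both one- and two-sided sign-test p-values are reported: a
7-of-8 split gives 0.0352 one-sided but 0.0703 two-sided, so claims of
significance at 0.05 for such a split are inherently one-sided.

The phase analysis selects band bins whose coherence exceeds the
single-spectrum limit both before and after administration, pools the
paired phases over subjects and muscles, and tests the absolute circular
mean of the paired differences against a label-shuffling null: each pair
independently swaps its before/after labels with probability ½ (which
negates that pair's difference), 10⁵ times by default. The reported
p-value uses the add-one permutation bound
$(n_{\text{exceeding}}+1)/(n_{\text{shuffles}}+1)$, which cannot be
zero and is never anticonservative; the uncorrected ratio is reported
alongside. Phase differences are unweighted in the circular mean —
coherence magnitude already gated the selection, and weighting would
entangle the phase test with the magnitude test.

## The synthetic-data generator

No recordings are deposited with studies of this design, so the
generator is a first-class module rather than a test fixture. It
emulates exactly the statistical structure the analysis assumes:

- **Common drive.** Band-limited Gaussian noise, built by
  frequency-domain shaping (independent complex-Gaussian coefficients at
  the bins inside the drive band, zero outside). The EEG channel is
  drive + white noise; each EMG channel is gain × (drive delayed by the
  corticomuscular lag and rotated by any drug phase shift) + independent
  white noise. The flat in-band spectrum gives the closed-form
  population coherence

  $$C(f) = \frac{g^2 S_d(f)^2}{(S_d(f)+S_{ex}(f))\,(g^2 S_d(f)+S_{ey}(f))},$$

  evaluated by `expected_coherence()` — the ground truth that recovery
  tests converge to (within 2% at L = 2000). A flat drive is chosen for
  testability over physiological realism: a realistic beta peak has no
  closed-form coherence.
- **Independent segments.** Grip segments are drawn independently rather
  than cut from one long series, which removes leakage and serial
  correlation so the Beta(1, L−1) null is exact. A continuous mode
  (`continuous = TRUE`) generates one long shaped series and cuts it,
  for integration tests of the segmentation path.
- **Rectified-EMG surrogate.** The generator emits the
  post-rectification equivalent signal directly; synthesising raw EMG
  and rectifying it is out of scope. Synthetic sessions are therefore
  analysed without a second rectification pass (`rectify()` exists for
  real raw EMG, where it is applied before segmentation).
- **Tremor.** The acceleration channel is narrowband shaped noise at the
  tremor frequency (default 9 Hz, bandwidth 3 Hz) plus a white floor;
  band power is exactly linear in the tremor-power parameter, which is
  what drug-effect recovery tests exploit.
- **Subjects and arms.** Per-subject baseline coupling gain and tremor
  power vary log-normally with σ = 0.3 on the log scale — a documented
  stand-in for the high day-to-day baseline variability seen in such
  experiments, which keeps the power of the paired tests realistic. The
  "after" recording of an arm applies that arm's multiplicative
  `drug_effect()` (tremor power ×, coupling gain ×, coupling phase +).
  Default arm effects are placebo (identity), a propranolol-like arm
  (tremor ×0.6, coupling ×1.5) and a salbutamol-like arm (tremor ×3,
  coupling unchanged, phase −0.12 rad), matching the phenomenology the
  pipeline is designed to detect.
- **Reproducibility.** Every recording's seed is derived by hashing
  (plan seed, subject, arm, condition, channel), so a session is a pure
  function of its plan and identical plans are bit-identical.

What the generator deliberately does *not* emulate: mechanical resonance
and stretch-reflex contributions to tremor, motor-unit-level EMG
structure, non-stationarity within a recording, artifacts, and 1/f
backgrounds. Passing tests therefore demonstrate correctness of the
estimators and statistics under the model's assumptions — not robustness
to the full messiness of human recordings.

## Numerical and design details

- Sampling-rate convention: analyses quote 4630 Hz with 4096-point
  segments (1.13 Hz bins, 0.88 s segments) and the package defaults
  follow that; recording hardware in this field often digitises at
  slightly different rates (e.g. 4273.5 Hz, which would give 1.04 Hz
  bins), and the resolution helper makes the dependence explicit.
- Totals and normalisations run over all bins above DC up to Nyquist.
- The averaged-coherence limit's internal Monte Carlo uses a fixed seed
  (so thresholds are reproducible across calls and machines) and
  quantile type 8.
- Degenerate inputs fail loudly: coherence needs L ≥ 2; paired t-tests
  reject zero-variance differences; the circular mean is undefined below
  resultant length 10⁻¹²; hold-phase windows shorter than the requested
  sections skip the trial with a warning rather than zero-pad, because
  padding biases coherence.
- The split-half reproducibility check (`reproducibility_split()`)
  references both halves' tremor power to the *first* half's total — the
  same day-first convention as the main analysis — so that genuine
  overall power changes between halves remain detectable.

## Problem sizes used in the test-suite experiments

Statistical properties are invariant to the absolute frequency grid, so
simulation experiments run on a reduced grid chosen once: 64-sample
segments at 64 Hz (1 Hz bins) with a 16-bin drive band at 15–30 Hz and
in-band coherence ≈ 0.4 (`calibration_coupling()`). The calibration
experiments use 2000 replicate null studies of 8 subjects × 5 muscles ×
16 bins at L = 60; recovery runs at L = 2000; effect-detection uses 40
replicate 4-subject, 2-muscle studies; phase-test calibration uses 1000
replicate tests of 50 pairs at 1000 shuffles. These sizes give standard
errors comfortably inside the asserted tolerances while keeping the
whole suite runnable on a laptop.

## Known limitations

The pooled Z treats subject × muscle terms as independent (see above);
the generator's Gaussian, stationary world understates real-data
variability; the phase test conditions on a selection step (bins
significant in both conditions) whose selection noise it does not model;
and no correction is applied across the two pre-specified analysis
bands, which mirrors the analysis convention the package implements.
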