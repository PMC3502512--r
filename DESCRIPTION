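Package: tremorcoh
Title: Corticomuscular Coherence and Physiological Tremor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segment-averaged spectral and coherence analysis of simultaneous
    EEG, rectified EMG and finger-acceleration recordings, as used to study
    beta-band (15.3-32.2 Hz) corticomuscular coupling and ~10 Hz physiological
    tremor in placebo-controlled crossover drug studies. Implements the
    disjoint-segment coherence estimator with its Beta(1, L-1) null law,
    significance limits for single and subject/muscle-averaged coherence, the
    pooled Fisher-transform difference-of-coherence Z statistic and its
    drug-versus-placebo contrast, paired band-power and exact sign tests, and a
    Monte Carlo shuffle test for paired coherence-phase changes. A synthetic
    session generator with closed-form expected coherence provides ground truth
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
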