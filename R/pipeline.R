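# Orchestration: simulate -> spectra -> coherence -> compare -> phase ->
# report, as a pure function of (config, seed).

#' Pipeline configuration
#'
#' Bundles and validates everything the end-to-end analysis needs. All
#' validation happens here, before any stage runs; the config (and its hash)
#' is echoed into the report for provenance.
#'
#' @param plan A [session_plan()] (also carries the master seed).
#' @param coupling A [coupling_model()] population baseline.
#' @param tremor A [tremor_model()] population baseline.
#' @param bands Named list of [band_definition()]s; must contain `tremor` and
#'   `beta` (defaults 6.2--11.9 Hz and 15.3--32.2 Hz).
#' @param alpha Significance level used throughout (default 0.05).
#' @param n_shuffles Shuffles for the phase test (default 1e5).
#' @param placebo_arm Name of the reference arm for the delta-Z contrast
#'   (`NULL` for sessions without one).
#' @param out_dir Optional directory; when set, [run_pipeline()] writes tidy
#'   tables and a JSON report there.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(plan = session_plan(),
                            coupling = coupling_model(),
                            tremor = tremor_model(),
                            bands = default_bands(),
                            alpha = 0.05,
                            n_shuffles = 1e5,
                            placebo_arm = "placebo",
                            out_dir = NULL) {
  stopifnot(inherits(plan, "session_plan"),
            inherits(coupling, "coupling_model"),
            inherits(tremor, "tremor_model"))
  if (!all(c("tremor", "beta") %in% names(bands))) {
    abort("`bands` must contain 'tremor' and 'beta' definitions.")
  }
  nyq <- plan$sampling_rate / 2
  for (b in bands) {
    stopifnot(inherits(b, "band_definition"))
    if (b$f_hi >= nyq) {
      abort(sprintf("band '%s' extends to %.3g Hz, beyond Nyquist (%.3g Hz).",
                    b$label, b$f_hi, nyq))
    }
  }
  stopifnot_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  stopifnot_scalar(n_shuffles, "n_shuffles", positive = TRUE)
  check_drive_band(coupling, plan$sampling_rate)
  if (!is.null(placebo_arm) && !placebo_arm %in% names(plan$arms)) {
    abort(sprintf("placebo arm '%s' is not among the plan's arms.", placebo_arm))
  }
  cfg <- structure(
    list(plan = plan, coupling = coupling, tremor = tremor, bands = bands,
         alpha = alpha, n_shuffles = n_shuffles, placebo_arm = placebo_arm,
         out_dir = out_dir),
    class = "pipeline_config")
  attr(cfg, "hash") <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  cfg
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes, in order: session simulation, normalised power spectra, band
#' powers, per-recording coherence, the pooled difference-of-coherence Z per
#' arm, the drug-versus-placebo delta-Z contrasts, paired band-power t-tests,
#' binomial sign tests on the per-subject drug-versus-placebo changes, and
#' the Monte Carlo phase test per arm. Re-running with an identical config
#' reproduces every output exactly.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle (list) with the tidy stage outputs, the summary
#'   statistics, the config hash and seed. Written to `config$out_dir` as
#'   CSV/JSON when that is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  plan <- config$plan
  seed <- plan$seed
  session <- generate_session(plan, config$coupling, config$tremor)
  spectra <- session_spectra(session)
  bp_tremor <- session_band_power(filter(spectra, .data$role == "ACC"),
                                  config$bands$tremor)
  bp_beta <- session_band_power(filter(spectra, .data$role != "ACC"),
                                config$bands$beta)
  band_power_tbl <- bind_rows(bp_tremor, bp_beta)
  coh <- session_coherence(session)

  arms <- names(plan$arms)
  z_list <- list()
  paired_list <- list()
  for (a in arms) {
    paired_list[[a]] <- pair_conditions(coh, config$bands$beta, arm = a)
    z_list[[a]] <- coherence_diff_z(paired_list[[a]])
  }
  z_tbl <- bind_rows(lapply(z_list, tidy), .id = "arm")

  # paired before/after band-power tests per arm and signal
  change_tbl <- band_power_tbl |>
    tidyr::pivot_wider(names_from = "condition", values_from = "band_power") |>
    mutate(change = .data$after - .data$before)
  test_one <- function(df) {
    agg <- df |>
      group_by(.data$subject) |>
      summarise(before = mean(.data$before), after = mean(.data$after),
                .groups = "drop")
    paired_band_test(agg$before, agg$after)
  }
  band_tests <- change_tbl |>
    group_by(.data$arm, .data$role, .data$band) |>
    dplyr::group_modify(~test_one(.x)) |>
    ungroup()

  delta_tbl <- NULL
  sign_tbl <- NULL
  if (!is.null(config$placebo_arm) && length(arms) > 1) {
    pl <- config$placebo_arm
    per_subject_change <- change_tbl |>
      group_by(.data$arm, .data$role, .data$band, .data$subject) |>
      summarise(change = mean(.data$change), .groups = "drop")
    drugs <- setdiff(arms, pl)
    delta_tbl <- bind_rows(lapply(drugs, function(a) {
      tidy(delta_z(z_list[[a]], z_list[[pl]]))
    }) |> stats::setNames(drugs), .id = "arm")
    sign_tbl <- bind_rows(lapply(drugs, function(a) {
      ch <- per_subject_change |>
        filter(.data$role == "ACC") |>
        tidyr::pivot_wider(names_from = "arm", values_from = "change")
      # direction of interest: tremor change under drug below placebo change
      n_down <- sum(ch[[a]] < ch[[pl]])
      cbind(tibble(measure = "tremor_change_below_placebo"),
            sign_binomial_test(n_down, nrow(ch)))
    }) |> stats::setNames(drugs), .id = "arm")
  }

  phase_tbl <- bind_rows(lapply(stats::setNames(arms, arms), function(a) {
    pairs <- select_phase_pairs(paired_list[[a]], config$alpha)
    if (nrow(pairs) < 2) {
      return(tibble(n_pairs = nrow(pairs), p_value = NA_real_))
    }
    res <- phase_shuffle_test(pairs, config$n_shuffles,
                              seed = derive_seed(seed, a, "phase"))
    tidy(res)
  }), .id = "arm")

  report <- list(
    config_hash = attr(config, "hash"), seed = seed,
    alpha = config$alpha,
    bands = lapply(config$bands, unclass),
    band_power = band_power_tbl, band_tests = band_tests,
    z = z_tbl, delta_z = delta_tbl, sign_tests = sign_tbl,
    phase = phase_tbl, coherence = coh, spectra = spectra)

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(band_power_tbl, file.path(dir, "band_power.csv"))
    readr::write_csv(band_tests, file.path(dir, "band_tests.csv"))
    readr::write_csv(coh, file.path(dir, "coherence.csv"))
    summary <- report[c("config_hash", "seed", "alpha", "bands")]
    summary$z <- z_tbl
    summary$delta_z <- delta_tbl
    summary$sign_tests <- sign_tbl
    summary$phase <- phase_tbl
    summary$band_tests <- band_tests
    jsonlite::write_json(summary, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' Split-half reproducibility analysis
#'
#' Re-runs the tremor band-power and averaged-coherence analyses separately
#' on the first and last half of each subject's recording (the check used to
#' justify comparing successive recordings without a placebo arm): the
#' accelerometer series is halved in time, the grip segment set into its
#' first and last segments. Paired t-tests across subjects compare the two
#' halves.
#'
#' @param session A `tremor_session`.
#' @param arm Arm whose recordings to split (default: first arm).
#' @param condition Condition to split (default `"before"`).
#' @param bands Band definitions (`tremor` and `beta` entries used).
#' @return A list with `halves` (per-subject tibble of tremor band power and
#'   mean beta coherence per half) and `tests` (paired t-tests between
#'   halves).
#' @export
reproducibility_split <- function(session, arm = NULL, condition = "before",
                                  bands = default_bands()) {
  stopifnot(inherits(session, "tremor_session"))
  plan <- attr(session, "plan")
  fs <- plan$sampling_rate
  seg_len <- plan$segment_length
  if (is.null(arm)) arm <- session$arm[1]
  sub <- session[session$arm == arm & session$condition == condition, ]
  if (nrow(sub) == 0) abort("no recordings for that arm/condition.")

  halves_one <- function(s) {
    rows <- sub[sub$subject == s, ]
    acc <- rows$data[[which(rows$role == "ACC")]]
    n <- length(acc)
    if (n %/% 2 < 2 * seg_len) abort("recording too short to split.")
    acc_halves <- list(acc[1:(n %/% 2)], acc[(n %/% 2 + 1):n])
    eeg <- rows$data[[which(rows$role == "EEG")]]
    L <- ncol(eeg)
    Lh <- L %/% 2
    if (Lh < 2) abort("too few segments to split.")
    seg_idx <- list(seq_len(Lh), seq.int(L - Lh + 1, L))
    emg_rows <- which(rows$role == "EMG")
    # tremor power referenced to the first half's total, the day-first
    # convention, so overall power changes between halves stay measurable
    ref_total <- sum(power_spectrum(segment_sequential(acc_halves[[1]],
                                                       seg_len), fs)$power)
    purrr::map2(acc_halves, seg_idx, function(a, idx) {
      sp <- power_spectrum(segment_sequential(a, seg_len), fs)
      trem <- band_power(sp, bands$tremor) / ref_total
      cohs <- vapply(emg_rows, function(i) {
        cs <- coherence_spectrum(eeg[, idx, drop = FALSE],
                                 rows$data[[i]][, idx, drop = FALSE], fs)
        mean(cs$coherence[cs$frequency >= bands$beta$f_lo &
                            cs$frequency <= bands$beta$f_hi])
      }, numeric(1))
      c(tremor_power = trem, beta_coherence = mean(cohs))
    })
  }

  subjects <- sort(unique(sub$subject))
  halves <- bind_rows(lapply(subjects, function(s) {
    h <- halves_one(s)
    tibble(subject = s, half = c("first", "last"),
           tremor_power = c(h[[1]]["tremor_power"], h[[2]]["tremor_power"]),
           beta_coherence = c(h[[1]]["beta_coherence"],
                              h[[2]]["beta_coherence"]))
  }))
  wide <- halves |>
    tidyr::pivot_wider(names_from = "half",
                       values_from = c("tremor_power", "beta_coherence"))
  # identical halves give zero-variance differences; report NA rather than fail
  safe_test <- function(b, a) {
    tryCatch(paired_band_test(b, a),
             error = function(e) tibble(estimate = mean(a - b),
                                        statistic = NA_real_,
                                        p_value = NA_real_, n = length(b)))
  }
  tests <- bind_rows(
    tremor_power = safe_test(wide$tremor_power_first, wide$tremor_power_last),
    beta_coherence = safe_test(wide$beta_coherence_first,
                               wide$beta_coherence_last),
    .id = "measure")
  list(halves = halves, tests = tests)
}
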