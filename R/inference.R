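# Difference-of-coherence statistics and the circular phase test.
#
# The pooled Z statistic variance-stabilises each coherence estimate with the
# Fisher transform of its square root: atanh(sqrt(C)) has variance ~1/(2L)
# for L disjoint segments (accurate away from C = 0). Per (subject, muscle,
# bin) the before/after difference d = atanh(sqrt(C_after)) -
# atanh(sqrt(C_before)) has variance 1/(2 L_after) + 1/(2 L_before); the
# pooled sum over all terms, divided by the square root of the summed
# variances, is N(0, 1) under the null of unchanged coherence. Two drug arms
# are contrasted as (Z_drug - Z_placebo) / sqrt(2), again N(0, 1) when both
# substances change coherence equally.

#' Pooled difference-of-coherence Z statistic
#'
#' Tests whether coherence changed between the before and after recordings,
#' pooling Fisher-transformed differences over every (subject, muscle,
#' frequency-bin) triple of the band. Under the null of unchanged coherence
#' Z is standard normal; a positive Z means coherence increased.
#'
#' @param set A `paired_coherence` tibble from [pair_conditions()] or
#'   [simulate_paired_coherence()] (columns coh_before, coh_after, L_before,
#'   L_after).
#' @return A `coh_z` object with elements `z`, `p_two_sided`, `n_terms` and
#'   the band; see [tidy.coh_z()].
#' @export
coherence_diff_z <- function(set) {
  need <- c("coh_before", "coh_after", "L_before", "L_after")
  if (!is.data.frame(set) || !all(need %in% names(set))) {
    abort("`set` must have columns coh_before, coh_after, L_before, L_after.")
  }
  if (nrow(set) == 0) abort("empty paired set: the band selected no bins.")
  if (any(set$L_before < 2) || any(set$L_after < 2)) {
    abort("all segment counts must be >= 2.")
  }
  clamp <- function(c, L) {
    hit <- c >= 1
    if (any(hit)) {
      warn(sprintf("%d coherence value(s) equal to 1 clamped to 1 - 1/(2L).",
                   sum(hit)))
      c[hit] <- 1 - 1 / (2 * L[hit])
    }
    c
  }
  ca <- clamp(set$coh_after, set$L_after)
  cb <- clamp(set$coh_before, set$L_before)
  d <- atanh(sqrt(ca)) - atanh(sqrt(cb))
  v <- 1 / (2 * set$L_after) + 1 / (2 * set$L_before)
  z <- sum(d) / sqrt(sum(v))
  structure(
    list(z = z, p_two_sided = 2 * pnorm(-abs(z)), n_terms = nrow(set),
         n_subjects = length(unique(set[["subject"]])),
         n_muscles = length(unique(set[["muscle"]])),
         band = attr(set, "band")),
    class = "coh_z")
}

#' @export
print.coh_z <- function(x, ...) {
  cat(sprintf("Pooled difference-of-coherence test\nZ = %.3f, two-sided p = %.4g (%d pooled terms)\n",
              x$z, x$p_two_sided, x$n_terms))
  invisible(x)
}

#' Drug-versus-placebo contrast of two pooled Z statistics
#'
#' `(Z_drug - Z_placebo) / sqrt(2)`: when the two substances change coherence
#' equally the contrast is standard normal, because each Z is unit-variance
#' and the arms are independent.
#'
#' @param z_drug,z_placebo `coh_z` objects computed on the same band and
#'   study structure.
#' @return A `coh_dz` object with elements `delta_z` and `p_two_sided`.
#' @export
delta_z <- function(z_drug, z_placebo) {
  stopifnot(inherits(z_drug, "coh_z"), inherits(z_placebo, "coh_z"))
  b1 <- z_drug$band
  b2 <- z_placebo$band
  if (!is.null(b1) && !is.null(b2) &&
      !(isTRUE(all.equal(b1$f_lo, b2$f_lo)) &&
        isTRUE(all.equal(b1$f_hi, b2$f_hi)))) {
    abort("the two Z statistics were computed on different bands.")
  }
  dz <- (z_drug$z - z_placebo$z) / sqrt(2)
  structure(
    list(delta_z = dz, p_two_sided = 2 * pnorm(-abs(dz)),
         z_drug = z_drug$z, z_placebo = z_placebo$z, band = b1),
    class = "coh_dz")
}

#' @export
print.coh_dz <- function(x, ...) {
  cat(sprintf("Drug vs placebo coherence contrast\ndeltaZ = %.3f (Z_drug = %.3f, Z_placebo = %.3f), two-sided p = %.4g\n",
              x$delta_z, x$z_drug, x$z_placebo, x$p_two_sided))
  invisible(x)
}

#' Paired t-test on band-power values
#'
#' Classical paired t on after - before differences, the test applied to
#' per-subject band powers. Zero-variance differences (e.g. after identical
#' to before plus a constant) are rejected as degenerate input.
#'
#' @param before,after Equal-length paired numeric vectors (n >= 2).
#' @return A one-row tibble with `estimate` (mean after - before),
#'   `statistic`, `p_value`, `n`.
#' @export
paired_band_test <- function(before, after) {
  if (length(before) != length(after)) abort("paired samples differ in length.")
  if (length(before) < 2) abort("need at least 2 pairs.")
  d <- after - before
  if (isTRUE(all.equal(var(d), 0)) || var(d) == 0) {
    abort("degenerate input: differences have zero variance.")
  }
  tt <- t.test(after, before, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         p_value = tt$p.value, n = length(before))
}

#' Exact binomial sign test against one half
#'
#' Used on per-subject direction-of-change counts (e.g. tremor reduced in
#' 7 of 8 subjects). Both sidings are reported: 7/8 is significant at 0.05
#' only one-sided.
#'
#' @param n_success Number of subjects changing in the hypothesised direction.
#' @param n_total Number of subjects.
#' @return A one-row tibble with `n_success`, `n_total`, `p_one_sided`
#'   (upper tail) and `p_two_sided` (exact, central).
#' @export
sign_binomial_test <- function(n_success, n_total) {
  stopifnot_scalar(n_success, "n_success")
  stopifnot_scalar(n_total, "n_total")
  if (n_total < 1) abort("n_total must be >= 1.")
  if (n_success < 0 || n_success > n_total) {
    abort("need 0 <= n_success <= n_total.")
  }
  tibble(
    n_success = as.integer(n_success), n_total = as.integer(n_total),
    p_one_sided = pbinom(n_success - 1, n_total, 0.5, lower.tail = FALSE),
    p_two_sided = binom.test(n_success, n_total, 0.5)$p.value)
}

#' Select paired phases at bins significant in both conditions
#'
#' Finds the band bins whose coherence exceeds the single-spectrum
#' significance limit both before and after substance administration, and
#' returns their paired phases pooled over subjects and muscles -- the
#' substrate of the circular phase-change test. An empty selection is a valid
#' (empty) result.
#'
#' @param set A `paired_coherence` tibble (band already applied).
#' @param alpha Significance level for the per-bin limit (default 0.05).
#' @return A `phase_pairs` tibble with columns subject, muscle, frequency,
#'   phase_before, phase_after.
#' @export
select_phase_pairs <- function(set, alpha = 0.05) {
  need <- c("coh_before", "coh_after", "L_before", "L_after",
            "phase_before", "phase_after")
  if (!is.data.frame(set) || !all(need %in% names(set))) {
    abort("`set` must be a paired_coherence tibble with phases.")
  }
  thr_b <- vapply(set$L_before, single_coherence_significance, numeric(1),
                  alpha = alpha)
  thr_a <- vapply(set$L_after, single_coherence_significance, numeric(1),
                  alpha = alpha)
  out <- set[set$coh_before > thr_b & set$coh_after > thr_a,
             intersect(c("subject", "muscle", "frequency",
                         "phase_before", "phase_after"), names(set))]
  out <- as_tibble(out)
  attr(out, "alpha") <- alpha
  class(out) <- c("phase_pairs", class(out))
  out
}

#' Circular mean of a set of angles
#'
#' Direction of the mean resultant vector `sum(exp(i * theta)) / n`, mapped
#' into (-pi, pi]. Undefined (error) when the resultant length is below
#' 1e-12, e.g. for exactly antipodal angles.
#'
#' @param angles Non-empty numeric vector of angles in radians.
#' @return The circular mean in (-pi, pi].
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0) abort("`angles` must be non-empty.")
  r <- mean(exp(1i * angles))
  if (Mod(r) < 1e-12) abort("mean resultant length ~ 0: direction undefined.")
  Arg(r)
}

#' Monte Carlo shuffle test for a paired circular phase change
#'
#' The observed statistic is the absolute circular mean of the paired phase
#' differences (after - before). Each shuffle independently swaps the
#' before/after labels of every pair with probability one half (equivalent to
#' negating that pair's difference) and recomputes the statistic; the
#' reported p uses the add-one permutation bound
#' `(n_exceeding + 1) / (n_shuffles + 1)` (the uncorrected ratio is reported
#' alongside as `p_raw`).
#'
#' @param pairs A `phase_pairs` tibble (or any data frame with
#'   `phase_before` and `phase_after` columns), >= 2 rows.
#' @param n_shuffles Number of label shuffles (>= 100; the study used 1e5).
#' @param seed Integer seed; required for reproducibility.
#' @return A `phase_shuffle` object with the circular means before/after, the
#'   circular mean difference, `n_exceeding` and the Monte Carlo `p`.
#' @export
phase_shuffle_test <- function(pairs, n_shuffles = 1e5, seed) {
  if (!is.data.frame(pairs) ||
      !all(c("phase_before", "phase_after") %in% names(pairs))) {
    abort("`pairs` must have columns phase_before and phase_after.")
  }
  n <- nrow(pairs)
  if (n < 2) abort("need at least 2 phase pairs.")
  stopifnot_scalar(n_shuffles, "n_shuffles", positive = TRUE)
  if (n_shuffles < 100) abort("n_shuffles must be >= 100.")
  if (missing(seed)) abort("`seed` is required.")

  d <- pairs$phase_after - pairs$phase_before
  observed <- abs(circular_mean(d))
  cs <- cos(d)
  sn <- sin(d)
  csum <- sum(cs)

  n_exceeding <- with_local_seed(seed, {
    total <- 0L
    done <- 0L
    chunk <- 20000L
    while (done < n_shuffles) {
      m <- min(chunk, n_shuffles - done)
      # label swap of pair j negates d_j; only the sine part changes sign
      signs <- matrix(2 * rbinom(m * n, 1, 0.5) - 1, m, n)
      stat <- abs(atan2(signs %*% sn, csum))
      total <- total + sum(stat >= observed)
      done <- done + m
    }
    total
  })

  structure(
    list(circ_mean_before = circular_mean(pairs$phase_before),
         circ_mean_after = circular_mean(pairs$phase_after),
         circ_mean_difference = circular_mean(d),
         observed = observed, n_pairs = n,
         n_shuffles = as.integer(n_shuffles),
         n_exceeding = as.integer(n_exceeding),
         p = (n_exceeding + 1) / (n_shuffles + 1),
         p_raw = n_exceeding / n_shuffles, seed = seed),
    class = "phase_shuffle")
}

#' @export
print.phase_shuffle <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo circular phase-change test (%d pairs, %d shuffles)\ncircular mean before %.3f rad, after %.3f rad, difference %.3f rad\np = %.4g (raw %d/%d)\n",
    x$n_pairs, x$n_shuffles, x$circ_mean_before, x$circ_mean_after,
    x$circ_mean_difference, x$p, x$n_exceeding, x$n_shuffles))
  invisible(x)
}
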