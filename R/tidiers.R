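# broom-style tidiers for the fitted statistic objects

#' Tidy a pooled difference-of-coherence test
#'
#' @param x A `coh_z` object.
#' @param ... Unused.
#' @return A one-row tibble with `z`, `p_value` and the pooled term count.
#' @export
tidy.coh_z <- function(x, ...) {
  tibble(z = x$z, p_value = x$p_two_sided, n_terms = x$n_terms,
         n_subjects = x$n_subjects, n_muscles = x$n_muscles,
         band = if (is.null(x$band)) NA_character_ else x$band$label)
}

#' @rdname tidy.coh_z
#' @export
glance.coh_z <- function(x, ...) tidy(x, ...)

#' Tidy a drug-versus-placebo coherence contrast
#'
#' @param x A `coh_dz` object.
#' @param ... Unused.
#' @return A one-row tibble with `delta_z`, its components and `p_value`.
#' @export
tidy.coh_dz <- function(x, ...) {
  tibble(delta_z = x$delta_z, z_drug = x$z_drug, z_placebo = x$z_placebo,
         p_value = x$p_two_sided,
         band = if (is.null(x$band)) NA_character_ else x$band$label)
}

#' @rdname tidy.coh_dz
#' @export
glance.coh_dz <- function(x, ...) tidy(x, ...)

#' Tidy a Monte Carlo circular phase-change test
#'
#' @param x A `phase_shuffle` object.
#' @param ... Unused.
#' @return A one-row tibble with the circular means, the observed statistic
#'   and both Monte Carlo p-values.
#' @export
tidy.phase_shuffle <- function(x, ...) {
  tibble(circ_mean_before = x$circ_mean_before,
         circ_mean_after = x$circ_mean_after,
         circ_mean_difference = x$circ_mean_difference,
         statistic = x$observed, n_pairs = x$n_pairs,
         n_shuffles = x$n_shuffles, n_exceeding = x$n_exceeding,
         p_value = x$p, p_raw = x$p_raw)
}

#' @rdname tidy.phase_shuffle
#' @export
glance.phase_shuffle <- function(x, ...) tidy(x, ...)
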