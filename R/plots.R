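# ggplot2 display of spectra and coherence

#' Plot a power spectrum
#'
#' @param object A `power_spectrum`.
#' @param band Optional [band_definition()] to shade.
#' @param f_max Upper frequency limit of the plot (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_spectrum <- function(object, band = NULL, f_max = 50, ...) {
  p <- ggplot2::ggplot(dplyr::filter(object, .data$frequency <= f_max),
                       ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = sprintf("Power (%s)", attr(object, "normalization"))) +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band$f_lo, xmax = band$f_hi,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "gold")
  }
  p
}

#' Plot a coherence spectrum with its significance limit
#'
#' @param object A `coherence_spectrum` or `averaged_coherence`.
#' @param alpha Significance level for the dashed limit line.
#' @param band Optional [band_definition()] to shade.
#' @param f_max Upper frequency limit of the plot (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coherence_spectrum <- function(object, alpha = 0.05, band = NULL,
                                        f_max = 50, ...) {
  L <- attr(object, "n_segments")
  ycol <- if ("coherence" %in% names(object)) "coherence" else "mean_coherence"
  thr <- if (inherits(object, "averaged_coherence")) {
    averaged_coherence_significance(attr(object, "contributors"),
                                    round(mean(L)), alpha)
  } else {
    single_coherence_significance(L, alpha)
  }
  p <- ggplot2::ggplot(dplyr::filter(object, .data$frequency <= f_max),
                       ggplot2::aes(x = .data$frequency, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Coherence") +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band$f_lo, xmax = band$f_hi,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "gold")
  }
  p
}

#' @export
autoplot.averaged_coherence <- autoplot.coherence_spectrum

#' Before/after spectra for one channel of a session, per arm
#'
#' @param spectra Output of [session_spectra()].
#' @param role Channel role to display ("ACC", "EEG" or "EMG").
#' @param f_max Upper frequency limit of the plot (Hz).
#' @return A ggplot object: subject-averaged before/after spectra, one facet
#'   per arm.
#' @export
plot_session_spectra <- function(spectra, role = "ACC", f_max = 50) {
  dat <- spectra |>
    filter(.data$role == !!role, .data$frequency <= f_max) |>
    group_by(.data$arm, .data$condition, .data$frequency) |>
    summarise(power = mean(.data$power), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$frequency, y = .data$power,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalised power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
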