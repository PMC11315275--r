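#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences against pair means, with the bias line (solid) and the
#' limits of agreement (dashed).
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two measurements (dB HL)",
                  y = paste0("Difference (", object$orientation, ", dB)"),
                  title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Per-frequency Bland-Altman panel plot
#'
#' One facet per frequency: per-ear differences against pair means, bias
#' and limits-of-agreement lines per facet.
#'
#' @param object An `agreement_by_freq` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot agreement_by_freq
#' @export
autoplot.agreement_by_freq <- function(object, ...) {
  pts <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(object), "frequency_hz",
                  "differences", "means"),
    cols = c("differences", "means"))
  lines <- dplyr::select(tibble::as_tibble(object), "frequency_hz",
                         "bias_db", "loa_low_db", "loa_high_db")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$means,
                                    y = .data$differences)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$bias_db)) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$loa_low_db),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$loa_high_db),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~frequency_hz, scales = "free_y") +
    ggplot2::labs(x = "Mean threshold (dB HL)",
                  y = paste0("Difference (",
                             attr(object, "orientation") %||% "a - b",
                             ", dB)")) +
    ggplot2::theme_minimal()
}

#' Plot an audiogram
#'
#' Threshold against frequency on the conventional audiogram axes
#' (log-frequency, inverted hearing-level axis); ceiling/floor points are
#' marked by shape.
#'
#' @param audiogram A tibble from [run_session()] (columns
#'   `frequency_hz`, `threshold_hl`, `status`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_audiogram <- function(audiogram, ...) {
  df <- dplyr::arrange(tibble::as_tibble(audiogram), .data$frequency_hz)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_hz,
                                   y = .data$threshold_hl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), size = 2) +
    ggplot2::scale_x_log10(breaks = df$frequency_hz,
                           labels = df$frequency_hz / 1000) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Frequency (kHz)", y = "Threshold (dB HL)",
                  shape = "Status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a rendered stimulus waveform
#'
#' @param waveform A `stimulus_waveform` from [render_stimulus()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_stimulus <- function(waveform, ...) {
  df <- tibble::tibble(
    t_ms = (seq_along(waveform$samples) - 1) / waveform$sample_rate_hz *
      1000,
    sample = waveform$samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$sample)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude") +
    ggplot2::theme_minimal()
}
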