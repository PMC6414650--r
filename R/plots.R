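#' Plot an amplitude spectrum
#'
#' Log-amplitude line plot of a single-sided spectrum; the fundamental is
#' marked when the spectrum came from [predict_spectrum()].
#'
#' @param object An `amplitude_spectrum` tibble.
#' @param fmax Upper frequency limit, Hz (default: full range).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amplitude_spectrum <- function(object, fmax = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(fmax)) df <- filter(df, .data$freq_hz <= fmax)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Frequency (Hz)",
      y = if (isTRUE(attr(object, "normalized"))) "Normalized amplitude"
          else "Displacement amplitude (m)")
  f0 <- attr(object, "f0_hz")
  if (!is.null(f0)) {
    p <- p + ggplot2::geom_vline(xintercept = f0, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Plot a peri-stimulus time histogram
#'
#' Bar plot of 1 ms bin counts, one facet per channel, with the stimulus
#' trigger at 0 ms.
#'
#' @param object A [build_psth()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psth <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_ms, .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~channel, ncol = 4) +
    ggplot2::labs(x = "Time after trigger (ms)", y = "Spike count")
}

#' Plot a frequency response map
#'
#' Normalised driven-rate heat map over the frequency-level grid, one facet
#' per channel.
#'
#' @param object A [build_frm()] result.
#' @param channels Channels to show. Default: all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frm <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- filter(df, .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(factor(round(.data$freq_hz)),
                                   factor(.data$level_db),
                                   fill = .data$ndsr)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(name = "Normalized\nDSR", limits = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Level (dB SPL)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 5))
}

#' Plot a pulse train
#'
#' Pulse energies over time with the modulation envelope overlaid.
#'
#' @param train A [make_pulse_train()] result.
#' @param t_max Plot only the first `t_max` seconds (default: two
#'   modulation periods).
#' @return A ggplot object.
#' @export
plot_pulse_train <- function(train, t_max = NULL) {
  stopifnot(inherits(train, "pulse_train"))
  p <- attr(train, "params")
  if (is.null(t_max)) t_max <- 2 / (p$lmr * 1000)
  df <- filter(as_tibble(train), .data$time_s <= t_max)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s * 1000, .data$energy_uj)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$time_s * 1000, yend = 0),
                          linewidth = 0.4) +
    ggplot2::labs(x = "Time (ms)", y = "Pulse energy (µJ)",
                  title = sprintf("LPR %g kHz / LMR %g kHz", p$lpr, p$lmr))
}
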