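# ggplot2 displays for the common result types.

#' Plot the training history of a fit
#'
#' Train/validation loss per epoch with the learning-rate schedule.
#'
#' @param object a `spikecoder_fit`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.spikecoder_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "loss per unit-bin", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Frequency-response-area heatmap
#'
#' @param tuning tibble from [tuning_summary()] on a tone battery
#' @param unit unit to display
#' @return a ggplot object
#' @export
plot_fra <- function(tuning, unit = 1) {
  d <- dplyr::filter(tuning, .data$unit == !!unit)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(round(.data$freq_hz)),
                                  y = factor(.data$level_db),
                                  fill = .data$mean_count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean count/bin") +
    ggplot2::labs(x = "frequency (Hz)", y = "level (dB SPL)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Rate-intensity curves
#'
#' @param tuning tibble from [tuning_summary()] (e.g. HPR or masking battery)
#' @param units units to display (default all)
#' @return a ggplot object
#' @export
plot_rate_intensity <- function(tuning, units = NULL) {
  d <- tuning
  if (!is.null(units)) d <- dplyr::filter(d, .data$unit %in% units)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level_db, y = .data$mean_count,
                                  colour = factor(.data$unit))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "level (dB SPL)", y = "mean count/bin", colour = "unit") +
    ggplot2::theme_minimal()
}

#' Modulation transfer functions (synchrony vs modulation frequency)
#'
#' @param mtf tibble from [synchrony_mtf()] rows over modulation frequencies
#' @param summarise average across units?
#' @return a ggplot object
#' @export
plot_mtf <- function(mtf, summarise = TRUE) {
  if (summarise) {
    d <- mtf |>
      dplyr::group_by(.data$mod_freq_hz) |>
      dplyr::summarise(synchrony = mean(.data$synchrony, na.rm = TRUE),
                       .groups = "drop")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$mod_freq_hz, y = .data$synchrony)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "modulation frequency (Hz)", y = "synchrony") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(mtf, ggplot2::aes(x = .data$mod_freq_hz, y = .data$synchrony,
                                      group = .data$unit)) +
      ggplot2::geom_line(alpha = 0.3) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "modulation frequency (Hz)", y = "synchrony") +
      ggplot2::theme_minimal()
  }
}
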