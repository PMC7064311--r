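#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: area functions
#' (area vs. distance from glottis), frequency responses, sensitivity
#' functions (raw and adjusted, per resonance), tract movies (area heat
#' map over time and distance), resonance tracks (per-variant tracks with
#' gaps), spectrograms, and audio waveforms.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name vtsynth-autoplot
NULL

#' @rdname vtsynth-autoplot
#' @export
autoplot.area_function <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$distance_cm, y = .data$area_cm2)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from glottis (cm)", y = expression(area ~ (cm^2)))
}

#' @rdname vtsynth-autoplot
#' @export
autoplot.frequency_response <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$frequency_hz, y = .data$magnitude_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "|U_lips / U_glottis| (dB)")
}

#' @rdname vtsynth-autoplot
#' @export
autoplot.sensitivity_functions <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, dplyr::any_of(c("S", "Z")),
                           names_to = "kind", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_cm, y = .data$value,
                                  linetype = factor(.data$resonance))) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "distance from glottis (cm)", y = NULL,
                  linetype = "resonance")
}

#' @rdname vtsynth-autoplot
#' @export
autoplot.tract_movie <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$distance_cm,
                               fill = .data$area_cm2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(area ~ (cm^2))) +
    ggplot2::labs(x = "time (s)", y = "distance from glottis (cm)")
}

#' @rdname vtsynth-autoplot
#' @export
autoplot.resonance_tracks <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("f_R1", "f_R2", "f_R3"),
                           names_to = "resonance", values_to = "frequency_hz")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$frequency_hz,
                                  colour = .data$variant,
                                  group = interaction(.data$variant,
                                                      .data$resonance))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "resonance frequency (Hz)")
}

#' @rdname vtsynth-autoplot
#' @export
autoplot.vt_spectrogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$frequency_hz,
                                       fill = .data$magnitude_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' @rdname vtsynth-autoplot
#' @export
autoplot.audio_result <- function(object, ...) {
  d <- tibble::tibble(time_s = seq_along(object$samples) / object$rate,
                      amplitude = object$samples)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}
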