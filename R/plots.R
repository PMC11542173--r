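#' Plot a spectral fit
#'
#' Log-log view of the data, the combined model, and the aperiodic
#' component alone (dashed), the standard diagnostic for a periodic/
#' aperiodic decomposition.
#'
#' @param object A `spectral_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_fit <- function(object, ...) {
  df <- tibble(
    freq = rep(object$freqs, 3),
    log_power = c(object$log_power, object$model,
                  aperiodic_model(object$freqs, object$offset,
                                  object$exponent)),
    component = rep(c("data", "model", "aperiodic"),
                    each = length(object$freqs))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$log_power,
                                   colour = .data$component,
                                   linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_linetype_manual(
      values = c(data = "solid", model = "solid", aperiodic = "dashed")) +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power",
                  title = sprintf("offset %.2f, exponent %.2f, R² %.4f",
                                  object$offset, object$exponent,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Scalp map of a cluster test
#'
#' Electrode positions coloured by the observed t value; members of
#' significant clusters are ringed.
#'
#' @param object A `cluster_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_test <- function(object, ...) {
  df <- dplyr::left_join(object$adjacency$coords, object$t_map,
                         by = "channel")
  sig_ch <- unlist(object$clusters$channels[
    which(object$clusters$significant)])
  df$in_cluster <- df$channel %in% sig_ch
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t), size = 4) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey90",
                                    high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s design, forming |t| > %.2f",
                                  object$kind, object$forming_threshold)) +
    ggplot2::theme_void()
  if (any(df$in_cluster)) {
    p <- p + ggplot2::geom_point(
      data = df[df$in_cluster, , drop = FALSE],
      shape = 21, size = 6, stroke = 1, fill = NA, colour = "black")
  }
  p
}

#' Spaghetti plot of cohort spectra
#'
#' @param spectra Tidy spectra tibble.
#' @param colour_by Column mapped to colour (default `group`).
#' @param alpha Line transparency.
#' @return A ggplot of log10 power against frequency, one line per
#'   spectrum.
#' @export
plot_spectra <- function(spectra, colour_by = "group", alpha = 0.2) {
  spectra$id <- paste(spectra$subject, spectra$session, spectra$condition,
                      spectra$channel)
  ggplot2::ggplot(spectra,
                  ggplot2::aes(x = .data$freq, y = log10(.data$power),
                               group = .data$id,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power") +
    ggplot2::theme_minimal()
}
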