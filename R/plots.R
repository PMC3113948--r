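# ggplot2 views of the main result types.

#' @method autoplot emg_session
#' @export
autoplot.emg_session <- function(object, channels = NULL, downsample = 8, ...) {
  channels <- channels %||% seq_len(nrow(object$signal))
  idx <- seq(1, ncol(object$signal), by = downsample)
  df <- dplyr::bind_rows(lapply(channels, function(ch) {
    tibble(time_s = (idx - 1) / object$fs, amplitude = object$signal[ch, idx],
           channel = factor(ch))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)",
                  title = sprintf("Subject %s session %s",
                                  format(object$subject_id),
                                  format(object$session)))
}

#' @method autoplot emg_decisions
#' @export
autoplot.emg_decisions <- function(object, fs = 1024, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("truth", "raw", "fused"),
                            names_to = "stream", values_to = "label")
  ggplot2::ggplot(df, ggplot2::aes(.data$start_sample / fs, .data$label,
                                   colour = .data$stream)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stream)) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "time (s)", y = "class")
}

#' @method autoplot emg_experiment
#' @export
autoplot.emg_experiment <- function(object, ...) {
  tab <- summarize_results(object)
  ggplot2::ggplot(tab, ggplot2::aes(.data$section, 100 * .data$mean_error,
                                    group = interaction(.data$classifier,
                                                        .data$feature_set),
                                    colour = paste(.data$classifier,
                                                   .data$feature_set,
                                                   sep = "/"))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$mean_error - .data$sd_error),
      ymax = 100 * (.data$mean_error + .data$sd_error)
    ), width = 0.15) +
    ggplot2::labs(x = "training section", y = "error (%)", colour = "cell")
}

#' Normalized-error plot
#'
#' Per-subject normalized errors by training section with the across-subject
#' mean overlaid.
#'
#' @param normalized A [normalized_errors()] result.
#' @return A ggplot object.
#' @export
plot_normalized_errors <- function(normalized) {
  df <- mutate(normalized,
               section = factor(.data$section, levels = training_sections()))
  ggplot2::ggplot(df, ggplot2::aes(.data$section, .data$normalized)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1,
                          ggplot2::aes(group = 1), colour = "black") +
    ggplot2::facet_wrap(~ .data$feature_set + .data$classifier) +
    ggplot2::labs(x = "training section", y = "normalized error")
}
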