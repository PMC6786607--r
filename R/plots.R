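# Diagnostic ggplot2 figures for the main result types.

#' Plot a staircase track
#'
#' Level against trial number, with reversals marked and the threshold
#' shown as a dashed line.
#'
#' @param object A `staircase_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.staircase_track <- function(object, ...) {
  log <- tidy(object)
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$trial,
                                         y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$response)) +
    ggplot2::geom_point(
      data = log[log$reversal, ], colour = "red", size = 2
    ) +
    ggplot2::labs(x = "Trial", y = "Signal level (dB SPL)",
                  shape = "Correct",
                  title = sprintf("Staircase track: %s", object$condition))
  if (object$converged) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = "dashed")
  }
  p
}

#' Plot an averaged AEP waveform
#'
#' @param object An `averaged_aep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.averaged_aep <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_ms, y = .data$amplitude,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time re masker onset (ms)",
                  y = expression("Amplitude (" * mu * "V)"),
                  colour = "Channel")
}

#' Plot a change complex with detected peaks
#'
#' @param object A `change_complex`.
#' @param peaks Optional `peak_set` to annotate.
#' @param channel Channel to draw (default: analysis channel).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.change_complex <- function(object, peaks = NULL, channel = NULL,
                                    ...) {
  if (is.null(channel)) channel <- object$analysis_channel
  d <- tidy(object)
  d <- d[d$channel == channel, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms,
                                       y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time re signal onset (ms)",
                  y = expression("Amplitude (" * mu * "V)"),
                  title = sprintf("Change complex (%s)", channel))
  if (!is.null(peaks)) {
    pk <- tidy(peaks)
    ann <- tibble::tibble(
      time_ms = c(pk$n1_lat, pk$p2_lat),
      amplitude = c(pk$n1_amp, pk$p2_amp),
      peak = c("N1", "P2")
    )
    ann <- ann[!is.na(ann$time_ms), ]
    p <- p + ggplot2::geom_point(data = ann, colour = "red", size = 2) +
      ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$peak),
                         vjust = -1, colour = "red")
  }
  p
}

#' Plot median salience ratings against sensation level
#'
#' @param object A rating table (`rating_table` or compatible tibble).
#' @param ... Unused.
#' @return A ggplot object with one line per condition (grand medians,
#'   interquartile range as ribbon).
#' @exportS3Method ggplot2::autoplot
autoplot.rating_table <- function(object, ...) {
  g <- aggregate_ratings(object) |>
    dplyr::group_by(.data$condition, .data$level_db_sl) |>
    dplyr::summarise(
      med = stats::median(.data$median),
      lo = stats::quantile(.data$median, 0.25),
      hi = stats::quantile(.data$median, 0.75),
      .groups = "drop"
    )
  ggplot2::ggplot(g, ggplot2::aes(x = .data$level_db_sl, y = .data$med,
                                  colour = .data$condition,
                                  fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Sensation level (dB SL)",
                  y = "Median salience rating (0-10)",
                  colour = "Condition", fill = "Condition")
}
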