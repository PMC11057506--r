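# diagnostic ggplot2 figures for the main result types

#' Plot an event-triggered average with its SEM band
#'
#' @param object A `strical_eta`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strical_eta <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event onset (s)", y = "mean signal",
                  title = sprintf("event-triggered average (n = %d events)",
                                  attr(object, "n_events") %||% NA))
}

#' Plot the BA histogram with the detected movement threshold
#'
#' @param object A `strical_threshold`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strical_threshold <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid_g, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$mid_g[1:2]),
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed)) +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red") +
    ggplot2::labs(x = "total body acceleration (g)", y = "frames",
                  title = sprintf("movement threshold %.4f g",
                                  object$threshold))
}

#' Plot a distance-binned correlation curve with its regression line
#'
#' @param object A `strical_distance_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strical_distance_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$bin_center_um, y = .data$mean_r)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::labs(x = "pair distance (um)", y = "mean pairwise correlation")
}

#' Plot a population JPSTH matrix
#'
#' @param object A `strical_pop_jpsth`.
#' @param ... Unused.
#' @return A ggplot raster of the matrix with the event onset marked.
#' @export
autoplot.strical_pop_jpsth <- function(object, ...) {
  df <- tidy.strical_pop_jpsth(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag1_s, y = .data$lag2_s,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "neuron 1 time (s)", y = "neuron 2 time (s)",
                  fill = "JPSTH",
                  title = sprintf("population JPSTH (%d pairs)",
                                  object$n_pairs))
}
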