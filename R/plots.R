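# ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gel lane trace
#'
#' @param object An `rt_lane_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_lane_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mobility,
                                       y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "migration (mobility units)", y = "intensity",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a cDNA length distribution
#'
#' @param object An `rt_length_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_length_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey30") +
    ggplot2::labs(x = "cDNA length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}

#' Plot a velocity fit with its points
#'
#' @param object An `rt_velocity_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_velocity_fit <- function(object, ...) {
  lab <- sprintf("v = %.1f ± %.1f nt/s,  r² = %.3f",
                 object$slope, object$slope_se, object$r2)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$time_s, y = .data$length_nt)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "firebrick") +
    ggplot2::labs(x = "reaction time (s)", y = "cDNA length (nt)",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot a stop-site profile
#'
#' @param object An `rt_stop_profile`.
#' @param min_reaching Mask positions with lower coverage.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_stop_profile <- function(object, min_reaching = 50L, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      .data$n_reaching >= min_reaching)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$stop_frequency)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::labs(x = "template position (nt)", y = "stop frequency") +
    ggplot2::theme_minimal()
}
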