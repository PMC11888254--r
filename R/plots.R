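# ggplot2 displays for the tabular result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a directional FSC result
#'
#' One translucent curve per direction, coloured by the direction's angle
#' to the z axis, with the direction-mean curve and the threshold overlaid
#' — the standard dFSC fan plot.
#'
#' @param object A `dfsc_result`.
#' @param threshold Horizontal reference line (default 0.143).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dfsc_result
#' @export
autoplot.dfsc_result <- function(object, threshold = 0.143, ...) {
  d <- tidy(object)
  d$angle_z <- acos(pmin(1, abs(d$z))) * 180 / pi
  m <- dplyr::summarise(dplyr::group_by(d, .data$freq),
                        fsc = mean(.data$fsc, na.rm = TRUE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$dir,
                                    colour = .data$angle_z),
                       alpha = 0.25, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(data = m, linewidth = 0.9, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_colour_viridis_c(name = "angle to z (deg)") +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC",
                  title = "Directional Fourier shell correlation") +
    ggplot2::theme_minimal()
}

#' Plot a single FSC curve
#'
#' @param curve Tibble with `freq` and `fsc` columns (e.g. from
#'   [global_fsc()]).
#' @param threshold Reference threshold line (default 0.143).
#' @return A ggplot object.
#' @export
plot_fsc_curve <- function(curve, threshold = 0.143) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC") +
    ggplot2::theme_minimal()
}

#' Plot a parameter-screen table
#'
#' Score (mean map-to-reference dFSC resolution) as a heat map over the
#' smoothing/nonlinearity grid; lower is better.
#'
#' @param object A `screen_table` from [screen_parameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_table
#' @export
autoplot.screen_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$smoothing),
                               y = factor(.data$nonlinearity),
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean res (Å)",
                                  direction = -1) +
    ggplot2::labs(x = "smoothing", y = "nonlinearity",
                  title = "Deconvolution parameter screen") +
    ggplot2::theme_minimal()
}

#' Plot the objective trace of a deconvolution run
#'
#' @param object A `deconv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deconv_result
#' @export
autoplot.deconv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective (log scale)") +
    ggplot2::theme_minimal()
}
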