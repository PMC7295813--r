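#' Plot a binned edge-probability curve with an optional fit
#'
#' @param object An `edge_curve` or `edge_fit`.
#' @param ... Unused.
#' @return A ggplot object: per-bin edge fractions (point size by count) and,
#'   for fits, the fitted probability curve with the transition diameter.
#' @method autoplot edge_curve
#' @export
autoplot.edge_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_center,
                               y = .data$edge_fraction)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), alpha = 0.8) +
    ggplot2::scale_size_area(name = "droplets") +
    ggplot2::labs(x = expression("Droplet diameter" ~ (mu * m)),
                  y = "Edge-positioned probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.edge_curve
#' @method autoplot edge_fit
#' @export
autoplot.edge_fit <- function(object, ...) {
  grid <- tibble(
    D = seq(max(1, min(object$curve$bin_center) - 25),
            max(object$curve$bin_center) + 25, length.out = 200)
  )
  grid$p <- edge_probability(grid$D, object$L, object$tau, object$waves)
  autoplot.edge_curve(object$curve) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$D, y = .data$p),
                       inherit.aes = FALSE, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$dc_um, linetype = "dashed")
}

#' Plot a simulated cluster trajectory
#'
#' @param object A `cluster_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the DC-ratio `d(t)/R` over time.
#' @method autoplot cluster_trajectory
#' @export
autoplot.cluster_trajectory <- function(object, ...) {
  R <- attr(object, "droplet_diameter_um") / 2
  df <- tibble(time_s = object$time_s, dc = object$d_um / R)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$dc)) +
    ggplot2::geom_line(colour = "#7b3294") +
    ggplot2::labs(x = "Time (s)", y = "DC-ratio d(t)/R") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
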