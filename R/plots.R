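#' Plot trajectories
#'
#' @param tracks A track table.
#' @param color_by Column mapped to color (default `track_id`).
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, color_by = "track_id") {
  validate_tracks(tracks)
  ggplot2::ggplot(dplyr::arrange(tracks, .data$track_id, .data$time_min),
                  ggplot2::aes(.data$x_um, .data$y_um,
                               group = .data$track_id,
                               color = .data[[color_by]])) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msd_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_min, .data$msd,
                                       group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Delta * t ~ "(min)"),
                  y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.angle_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_min, .data$theta_mid,
                                       fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_continuous(
      breaks = c(-pi, -pi / 2, 0, pi / 2, pi),
      labels = c(expression(-pi), expression(-pi / 2), "0",
                 expression(pi / 2), expression(pi))) +
    ggplot2::labs(x = expression(Delta * t ~ "(min)"),
                  y = expression(theta), fill = "P") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.silhouette_scan <- function(object, ...) {
  best <- attr(object, "best_k")
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$prob), "–", sprintf("%.2f", .data$prob)))) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$counts))) +
    ggplot2::labs(x = "to mode j", y = "from mode i",
                  fill = expression(P[ij])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mode_sequence <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(xmin = .data$window_start_min / 60,
                               xmax = .data$window_end_min / 60,
                               y = .data$track_id, fill = .data$mode)) +
    ggplot2::geom_rect(ggplot2::aes(
      ymin = as.numeric(factor(.data$track_id)) - 0.4,
      ymax = as.numeric(factor(.data$track_id)) + 0.4)) +
    ggplot2::labs(x = "time (h)", y = "track", fill = "mode") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.displacement_pdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid, .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(x ~ (mu * m)),
                  y = expression(P(x ~ "|" ~ Delta * t))) +
    ggplot2::theme_minimal()
}
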