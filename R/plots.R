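#' Quiver plot of a PIV vector field
#'
#' Arrows at each window center showing displacement direction and
#' magnitude; invalid vectors are drawn faded. The y axis is reversed to
#' match image orientation (animal/up at the top).
#'
#' @param object A `piv_field` from [compute_piv()].
#' @param arrow_scale Multiplier applied to displacements for display.
#' @param frame_pairs Frame pairs to draw (default: first).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.piv_field <- function(object, arrow_scale = 10,
                               frame_pairs = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(frame_pairs)) frame_pairs <- min(df$frame_pair)
  df <- dplyr::filter(df, .data$frame_pair %in% frame_pairs)
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$x, y = .data$y,
                 xend = .data$x + arrow_scale * .data$dx,
                 yend = .data$y + arrow_scale * .data$dy,
                 alpha = .data$valid)) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length =
                            ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "PIV flow field") +
    ggplot2::theme_minimal()
}

#' Rose plot of flow directions
#'
#' Circular histogram of valid-vector angles (up/animal at the top).
#'
#' @param object A `directional_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.directional_summary <- function(object, ...) {
  ggplot2::ggplot(object$rose,
    ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 360 / nrow(object$rose),
                      fill = "steelblue", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270),
                                labels = c("right", "up", "left", "down")) +
    ggplot2::labs(x = NULL, y = "vectors",
                  title = sprintf("Flow directions (n = %d)",
                                  object$n_valid)) +
    ggplot2::theme_minimal()
}

#' FRAP recovery curve with its exponential fit
#'
#' @param object A `frap_fit` from [fit_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.frap_fit <- function(object, ...) {
  curve <- tibble::as_tibble(object$curve)
  post <- dplyr::filter(curve, .data$time >= 0)
  pred <- tibble::tibble(
    time = seq(0, max(post$time), length.out = 200),
    intensity_norm = object$mobile_fraction *
      (1 - exp(-seq(0, max(post$time), length.out = 200) / object$tau))
  )
  ggplot2::ggplot(curve, ggplot2::aes(.data$time, .data$intensity_norm)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$half_time,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time after bleach (s)",
                  y = "normalized intensity",
                  title = sprintf(
                    "FRAP recovery: half-time %.2f s, mobile fraction %.2f",
                    object$half_time, object$mobile_fraction)) +
    ggplot2::theme_minimal()
}

#' Gap-width kinetics after ablation
#'
#' Width of the ablation opening over time with the early linear fit whose
#' slope is the initial recoil velocity.
#'
#' @param object A `recoil_series` from [measure_gap_width()].
#' @param fit_frames Early-window length passed to [recoil_velocity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.recoil_series <- function(object, fit_frames = 5, ...) {
  df <- tibble::as_tibble(object)
  v <- recoil_velocity(object, fit_frames)
  win <- dplyr::filter(df, .data$time >= 0) |> dplyr::slice_head(n = fit_frames)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$width_um)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(data = win, method = "lm", formula = y ~ x,
                         se = FALSE, colour = "firebrick") +
    ggplot2::labs(x = "time after cut (s)", y = "gap width (um)",
                  title = sprintf("Recoil: initial velocity %.3f um/s",
                                  v$velocity_um_s)) +
    ggplot2::theme_minimal()
}

#' Display a stack frame as a raster image
#'
#' @param stack A [calibrated_stack()].
#' @param frame Frame index.
#' @return A ggplot object.
#' @export
plot_stack_frame <- function(stack, frame = 1) {
  img <- get_frame(stack, frame)
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$intensity <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
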