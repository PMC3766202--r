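#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated CoG trajectory
#'
#' Sagittal CoG path coloured by stance phase.
#'
#' @param object A `gait_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gait_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$phase)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_vline(xintercept = object$events$t * NA) +
    ggplot2::labs(x = "forward position (m)", y = "CoG height (m)",
                  colour = NULL,
                  title = sprintf("CoG trajectory (%s preset)",
                                  object$params$gait_class)) +
    ggplot2::theme_minimal()
}

#' Plot a normalized gait cycle
#'
#' Vertical CoG displacement against percent of cycle, with event
#' markers.
#'
#' @param object A `gait_cycle`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gait_cycle <- function(object, ...) {
  p <- ggplot2::ggplot(object$samples,
                       ggplot2::aes(x = .data$percent, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "% gait cycle", y = "CoG height (m)") +
    ggplot2::theme_minimal()
  if (nrow(object$events)) {
    p <- p + ggplot2::geom_vline(
      data = object$events,
      ggplot2::aes(xintercept = .data$percent, linetype = .data$event),
      colour = "grey40")
  }
  p
}

#' Plot a fitted heel-path mixture
#'
#' Fitted heel x and y curves over the cycle.
#'
#' @param object A `heel_mixture`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heel_mixture <- function(object, ...) {
  path <- evaluate_heel_path(object, 0:100)
  long <- tidyr::pivot_longer(path, -"percent", names_to = "coord",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$percent, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coord, scales = "free_y") +
    ggplot2::labs(x = "% gait cycle", y = "heel position (m)",
                  title = sprintf("heel path (%s)", object$gait_class)) +
    ggplot2::theme_minimal()
}

#' Plot hip and knee flexion-extension curves
#'
#' The clinical four-panel layout: one panel per channel, degrees on the
#' y axis, percent of cycle on the x axis.
#'
#' @param object A `joint_angles`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.joint_angles <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$percent,
                                     y = .data$angle_deg)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "% gait cycle", y = "flexion (deg)") +
    ggplot2::theme_minimal()
}

#' Stick-figure plot of one or more skeleton poses
#'
#' @param poses A `skeleton_pose` or a pose sequence from
#'   [build_pose_series()].
#' @param max_frames Subsample to at most this many frames.
#' @return A ggplot.
#' @export
plot_skeleton <- function(poses, max_frames = 12) {
  if (!"frame" %in% names(poses)) poses$frame <- 1L
  frames <- unique(poses$frame)
  if (length(frames) > max_frames) {
    keep <- frames[seq(1, length(frames),
                       length.out = max_frames)]
    poses <- poses[poses$frame %in% keep, , drop = FALSE]
  }
  ggplot2::ggplot(poses) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$prox_x, y = .data$prox_y,
                                       xend = .data$dist_x,
                                       yend = .data$dist_y)) +
    ggplot2::facet_wrap(~frame) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
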