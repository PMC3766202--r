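#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated gait trajectory
#'
#' @param x A `gait_trajectory`.
#' @param ... Unused.
#' @return The sample tibble (`t`, `x`, `y`, `phase`, `cycle`).
#' @export
tidy.gait_trajectory <- function(x, ...) x$samples

#' One-row summary of a simulated gait trajectory
#'
#' @param x A `gait_trajectory`.
#' @param ... Unused.
#' @return A tibble with cycle count, duration, stride length,
#'   post-transient double-stance fraction and event-timing columns.
#' @export
glance.gait_trajectory <- function(x, ...) {
  tm <- if (x$n_cycles >= 1) cycle_timing(x) else
    list(ds_fraction = NA_real_, contralateral_heel_strike = NA_real_,
         ipsilateral_toe_off = NA_real_)
  tibble::tibble(
    gait_class = x$params$gait_class,
    n_cycles = x$n_cycles,
    n_samples = nrow(x$samples),
    duration = if (nrow(x$samples)) diff(range(x$samples$t)) else 0,
    step_length = x$step_length,
    stride_length = 2 * x$step_length,
    ds_fraction = tm$ds_fraction,
    contralateral_heel_strike = tm$contralateral_heel_strike,
    ipsilateral_toe_off = tm$ipsilateral_toe_off,
    max_handoff_jump = if (nrow(x$events)) max(x$events$jump) else NA_real_)
}

#' Tidy a normalized gait cycle
#'
#' @param x A `gait_cycle`.
#' @param ... Unused.
#' @return The resampled tibble (`percent`, `x`, `y`, `phase`).
#' @export
tidy.gait_cycle <- function(x, ...) x$samples

#' Tidy a heel-path mixture
#'
#' @param x A `heel_mixture`.
#' @param ... Unused.
#' @return The component table (`coord`, `component`, `weight`, `mean`,
#'   `variance`).
#' @export
tidy.heel_mixture <- function(x, ...) x$components

#' One-row summary of a heel-path mixture
#'
#' @param x A `heel_mixture`.
#' @param ... Unused.
#' @return A tibble with class, component count, basis width and RMS
#'   residuals.
#' @export
glance.heel_mixture <- function(x, ...) {
  tibble::tibble(gait_class = x$gait_class, I = x$I, sigma = x$sigma,
                 refined = x$refined,
                 rmse_x = x$residual[["x"]], rmse_y = x$residual[["y"]])
}

#' Tidy joint-angle trajectories
#'
#' @param x A `joint_angles`.
#' @param ... Unused.
#' @return A long tibble (`percent`, `channel`, `angle_rad`,
#'   `angle_deg`) with channels `R.Hip`, `R.Knee`, `L.Hip`, `L.Knee`.
#' @export
tidy.joint_angles <- function(x, ...) {
  a <- x$angles
  long <- tidyr::pivot_longer(a, -"percent", names_to = "channel",
                              values_to = "angle_rad")
  long$channel <- c(hip_R = "R.Hip", knee_R = "R.Knee",
                    hip_L = "L.Hip", knee_L = "L.Knee")[long$channel]
  long$angle_deg <- long$angle_rad * 180 / pi
  long
}

#' One-row summary of joint-angle trajectories
#'
#' @param x A `joint_angles`.
#' @param ... Unused.
#' @return A tibble with knee flexion range (deg) per leg and the
#'   clamped-target fraction.
#' @export
glance.joint_angles <- function(x, ...) {
  a <- x$angles
  r2d <- 180 / pi
  tibble::tibble(
    gait_class = x$gait_class,
    n = nrow(a),
    knee_R_min_deg = min(a$knee_R) * r2d,
    knee_R_max_deg = max(a$knee_R) * r2d,
    knee_L_min_deg = min(a$knee_L) * r2d,
    knee_L_max_deg = max(a$knee_L) * r2d,
    hip_R_range_deg = diff(range(a$hip_R)) * r2d,
    clamped_fraction = x$clamped_fraction)
}
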