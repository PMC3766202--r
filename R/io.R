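#' Write a single-stance pendulum arc to CSV
#'
#' Columns `t,theta,phi,theta_dot,phi_dot`, SI units, '.' decimal.
#'
#' @param arc A `pendulum_arc` from [integrate_single_stance()] or its
#'   trajectory tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pendulum_csv <- function(arc, path) {
  tr <- if (inherits(arc, "pendulum_arc")) arc$trajectory else arc
  readr::write_csv(tr[, c("t", "theta", "phi", "theta_dot", "phi_dot")], path)
  invisible(path)
}

#' Write a double-stance arc to CSV
#'
#' Columns `t,x,y,x_dot,y_dot,ll,lr`.
#'
#' @param arc A `spring_arc` from [integrate_double_stance()] or its
#'   trajectory tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spring_csv <- function(arc, path) {
  tr <- if (inherits(arc, "spring_arc")) arc$trajectory else arc
  readr::write_csv(tr[, c("t", "x", "y", "x_dot", "y_dot", "ll", "lr")], path)
  invisible(path)
}

#' Write a fused CoG trajectory to CSV
#'
#' Columns `t,percent_cycle,x,y,phase`; `percent_cycle` is the position
#' within the sample's own cycle (empty for the lead-in before the first
#' complete cycle).
#'
#' @param traj A `gait_trajectory` from [simulate_gait()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cog_csv <- function(traj, path) {
  stopifnot(inherits(traj, "gait_trajectory"))
  sm <- traj$samples
  starts <- traj$cycle_starts
  pct <- rep(NA_real_, nrow(sm))
  for (i in seq_len(length(starts) - 1)) {
    in_cyc <- sm$t >= starts[i] & sm$t <= starts[i + 1]
    pct[in_cyc] <- 100 * (sm$t[in_cyc] - starts[i]) /
      (starts[i + 1] - starts[i])
  }
  out <- tibble::tibble(t = sm$t, percent_cycle = pct, x = sm$x, y = sm$y,
                        phase = sm$phase)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a fused CoG trajectory CSV into per-cycle form
#'
#' Reads a file written by [write_cog_csv()] and returns the samples of
#' one complete cycle as a `gait_cycle` usable by [fuse_trajectories()].
#'
#' @param path CSV file.
#' @param cycle Which complete cycle to extract (1-based, in file order).
#' @param params Optional [gait_params()] attached to the cycle (needed
#'   downstream for `d` and `l0`).
#' @param n_points Resampling grid size.
#' @return A `gait_cycle`.
#' @export
read_cog_csv <- function(path, cycle = 1, params = NULL, n_points = 101) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- df[!is.na(df$percent_cycle), , drop = FALSE]
  # cycle index from wraparound of percent_cycle
  wrap <- c(0, diff(df$percent_cycle)) < 0
  idx <- cumsum(wrap) + 1
  keep <- df[idx == cycle, , drop = FALSE]
  if (nrow(keep) < 3) stop("cycle ", cycle, " not present in ", path,
                           call. = FALSE)
  cyc <- normalize_to_cycle(
    tibble::tibble(percent = keep$percent_cycle, x = keep$x, y = keep$y),
    n_points = n_points)
  cyc$params <- params
  cyc
}

#' Write / read a heel-cycle corpus
#'
#' CSV with columns `subject,cycle,percent,heel_x,heel_y`; the gait class
#' travels in a `gait_class` column.
#'
#' @param data A `heel_cycles` tibble.
#' @param path CSV file.
#' @return `path` (write) or a `heel_cycles` tibble (read).
#' @export
write_heel_cycles_csv <- function(data, path) {
  out <- tibble::as_tibble(data)
  out$gait_class <- attr(data, "gait_class") %||% "custom"
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_heel_cycles_csv
#' @export
read_heel_cycles_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cls <- if ("gait_class" %in% names(df)) df$gait_class[1] else "custom"
  df$gait_class <- NULL
  attr(df, "gait_class") <- cls
  class(df) <- c("heel_cycles", class(df))
  df
}

#' Serialize a heel-path mixture to JSON
#'
#' Stores the gait class and, per coordinate, the arrays of weights,
#' means and variances plus the intercept.
#'
#' @param mix A `heel_mixture`.
#' @param path JSON file.
#' @return `path` (write) or a `heel_mixture` (read).
#' @export
write_heel_mixture_json <- function(mix, path) {
  stopifnot(inherits(mix, "heel_mixture"))
  per_coord <- function(coord) {
    cc <- mix$components[mix$components$coord == coord, , drop = FALSE]
    list(weight = cc$weight, mean = cc$mean, variance = cc$variance,
         intercept = mix$intercept[[coord]])
  }
  jsonlite::write_json(
    list(gait_class = mix$gait_class, I = mix$I, sigma = mix$sigma,
         refined = mix$refined,
         residual = as.list(mix$residual),
         x = per_coord("x"), y = per_coord("y")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heel_mixture_json
#' @export
read_heel_mixture_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- dplyr::bind_rows(
    tibble::tibble(coord = "x", component = seq_along(j$x$weight),
                   weight = j$x$weight, mean = j$x$mean,
                   variance = j$x$variance),
    tibble::tibble(coord = "y", component = seq_along(j$y$weight),
                   weight = j$y$weight, mean = j$y$mean,
                   variance = j$y$variance))
  structure(list(gait_class = j$gait_class, I = as.integer(j$I),
                 components = comp,
                 intercept = c(x = j$x$intercept, y = j$y$intercept),
                 residual = c(x = j$residual$x, y = j$residual$y),
                 sigma = j$sigma, refined = isTRUE(j$refined)),
            class = "heel_mixture")
}

#' Write joint-angle series to CSV
#'
#' Columns `percent,hip_R_deg,knee_R_deg,hip_L_deg,knee_L_deg` in
#' degrees, flexion positive, the clinical gait-plot convention.
#'
#' @param angles A `joint_angles` object.
#' @param path CSV file.
#' @return `path` (write) or a `joint_angles` (read).
#' @export
write_joint_angles_csv <- function(angles, path) {
  stopifnot(inherits(angles, "joint_angles"))
  a <- angles$angles
  readr::write_csv(tibble::tibble(
    percent = a$percent,
    hip_R_deg = a$hip_R * 180 / pi, knee_R_deg = a$knee_R * 180 / pi,
    hip_L_deg = a$hip_L * 180 / pi, knee_L_deg = a$knee_L * 180 / pi),
    path)
  invisible(path)
}

#' @rdname write_joint_angles_csv
#' @param l0,gait_class Metadata restored on read.
#' @export
read_joint_angles_csv <- function(path, l0 = NA_real_,
                                  gait_class = "custom") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  structure(list(
    angles = tibble::tibble(
      percent = df$percent,
      hip_R = df$hip_R_deg * pi / 180, knee_R = df$knee_R_deg * pi / 180,
      hip_L = df$hip_L_deg * pi / 180, knee_L = df$knee_L_deg * pi / 180),
    clamped_fraction = NA_real_, l0 = l0, gait_class = gait_class),
    class = "joint_angles")
}

#' Write / read a gait-parameter configuration as JSON
#'
#' The JSON mirrors [gait_params()] field for field (with the initial
#' pendulum state inlined); `read_gait_config(write_gait_config(p))`
#' reproduces `p`.
#'
#' @param params A [gait_params()].
#' @param path JSON file.
#' @return `path` (write) or a [gait_params()] (read).
#' @export
write_gait_config <- function(params, path) {
  stopifnot(inherits(params, "gait_params"))
  s0 <- params$state0
  jsonlite::write_json(
    list(gait_class = params$gait_class, M = params$M, m = params$m,
         l0 = params$l0, k_left = params$k_left, k_right = params$k_right,
         d = params$d, g = params$g, slope = params$slope,
         state0 = list(theta = s0$theta, phi = s0$phi,
                       theta_dot = s0$theta_dot, phi_dot = s0$phi_dot,
                       t = s0$t)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gait_config
#' @export
read_gait_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gait_params(gait_class = j$gait_class, M = j$M, m = j$m, l0 = j$l0,
              k_left = j$k_left, k_right = j$k_right, k = j$k_left,
              d = j$d, g = j$g, slope = j$slope,
              state0 = pendulum_state(theta = j$state0$theta,
                                      phi = j$state0$phi,
                                      theta_dot = j$state0$theta_dot,
                                      phi_dot = j$state0$phi_dot,
                                      t = j$state0$t))
}
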