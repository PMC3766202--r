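#' Single-stance pendulum state
#'
#' State of the compass pendulum during single stance: the stance-leg angle
#' `theta` (rad, measured from the slope normal, positive when the hip is
#' forward of the contact point), the inter-leg angle `phi` (rad, measured
#' from the stance leg to the swing leg so that `phi = 2 * theta` at a
#' symmetric heel strike), and their time derivatives.
#'
#' @param t Time (s).
#' @param theta Stance-leg angle (rad), in (-pi/2, pi/2).
#' @param phi Inter-leg angle (rad), in (-pi/2, pi/2).
#' @param theta_dot,phi_dot Angular rates (rad/s).
#' @return An object of class `pendulum_state`.
#' @examples
#' pendulum_state(theta = 0.2, phi = 0.4, theta_dot = -0.3, phi_dot = 0.1)
#' @export
pendulum_state <- function(theta, phi, theta_dot = 0, phi_dot = 0, t = 0) {
  vals <- c(t = t, theta = theta, phi = phi,
            theta_dot = theta_dot, phi_dot = phi_dot)
  if (!all(is.finite(vals))) {
    stop("all pendulum state fields must be finite", call. = FALSE)
  }
  if (abs(theta) >= pi / 2 || abs(phi) >= pi / 2) {
    stop("theta and phi must lie in (-pi/2, pi/2)", call. = FALSE)
  }
  structure(as.list(vals), class = "pendulum_state")
}

#' @export
format.pendulum_state <- function(x, ...) {
  sprintf(
    "<pendulum_state t=%.4g theta=%.4g phi=%.4g theta_dot=%.4g phi_dot=%.4g>",
    x$t, x$theta, x$phi, x$theta_dot, x$phi_dot)
}

#' @export
print.pendulum_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Double-stance spring-mass state
#'
#' Centre-of-gravity state during double stance, in a frame with the
#' trailing-foot contact at the origin and the leading-foot contact at
#' `(d, 0)`.
#'
#' @param t Time (s).
#' @param x,y CoG position (m); `y` must be positive.
#' @param x_dot,y_dot CoG velocity (m/s).
#' @return An object of class `spring_mass_state`.
#' @examples
#' spring_mass_state(x = 0.25, y = 0.95, x_dot = 0.8, y_dot = -0.1)
#' @export
spring_mass_state <- function(x, y, x_dot = 0, y_dot = 0, t = 0) {
  vals <- c(t = t, x = x, y = y, x_dot = x_dot, y_dot = y_dot)
  if (!all(is.finite(vals))) {
    stop("all spring-mass state fields must be finite", call. = FALSE)
  }
  if (y <= 0) stop("y must be positive during double stance", call. = FALSE)
  structure(as.list(vals), class = "spring_mass_state")
}

#' @export
format.spring_mass_state <- function(x, ...) {
  sprintf("<spring_mass_state t=%.4g x=%.4g y=%.4g x_dot=%.4g y_dot=%.4g>",
          x$t, x$x, x$y, x$x_dot, x$y_dot)
}

#' @export
print.spring_mass_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
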