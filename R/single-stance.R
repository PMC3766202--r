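#' Compass-pendulum equations of motion
#'
#' The single-support phase is modelled as a compass pendulum: a point hip
#' mass `M` at the top of a rigid stance leg of length `l0`, pivoting about
#' the stance contact, plus a point swing-foot mass `m = beta * M` at the
#' end of the swing leg.  The two Euler-Lagrange equations are linear in
#' the angular accelerations, so each evaluation assembles the 2x2 mass
#' matrix and solves it.
#'
#' In units of `M * l0^2` the mass matrix is
#' \deqn{A = \begin{pmatrix} 1 + 2\beta(1-\cos\phi) & -\beta(1-\cos\phi) \\
#'  -\beta(1-\cos\phi) & \beta \end{pmatrix}}
#' and the generalized forces are
#' \deqn{b_1 = \beta\sin\phi\,\dot\phi(\dot\phi-2\dot\theta)/1 +
#'   (g/l_0)\left[(1+\beta)\sin(\theta+\gamma) -
#'   \beta\sin(\theta-\phi+\gamma)\right]}
#' \deqn{b_2 = \beta\left[(g/l_0)\sin(\theta-\phi+\gamma) +
#'   \dot\theta^2\sin\phi\right]}
#' with `gamma` the ground slope.
#'
#' @param state A [pendulum_state()].
#' @param params A [pendulum_params()].
#' @param cond_max Condition-number bound above which the mass matrix is
#'   treated as singular.
#' @return A list of class `pendulum_state_derivative` with fields
#'   `theta_dot`, `phi_dot`, `theta_ddot`, `phi_ddot`.
#' @examples
#' st <- pendulum_state(theta = 0.2, phi = 0.5, theta_dot = -0.3,
#'                      phi_dot = 0.1)
#' single_stance_derivatives(st, pendulum_params(slope = 0))
#' @export
single_stance_derivatives <- function(state, params, cond_max = 1e12) {
  stopifnot(inherits(state, "pendulum_state"),
            inherits(params, "pendulum_params"))
  sys <- compass_system(state$theta, state$phi,
                        state$theta_dot, state$phi_dot, params)
  if (kappa(sys$A, exact = TRUE) > cond_max) {
    stop("singular mass matrix: condition number exceeds ", cond_max,
         call. = FALSE)
  }
  acc <- solve(sys$A, sys$b)
  structure(list(theta_dot = state$theta_dot, phi_dot = state$phi_dot,
                 theta_ddot = acc[1], phi_ddot = acc[2]),
            class = "pendulum_state_derivative")
}

# mass matrix and forcing in units of M * l0^2 (A) and M * l0^2 / s^2 (b)
compass_system <- function(theta, phi, theta_dot, phi_dot, params) {
  beta <- params$beta
  gl <- params$g / params$l0
  gam <- params$slope
  c1 <- beta * (1 - cos(phi))
  A <- matrix(c(1 + 2 * c1, -c1,
                -c1, beta), 2, 2, byrow = TRUE)
  b <- c(beta * sin(phi) * phi_dot * (phi_dot - 2 * theta_dot) +
           gl * ((1 + beta) * sin(theta + gam) -
                   beta * sin(theta - phi + gam)),
         beta * (gl * sin(theta - phi + gam) + theta_dot^2 * sin(phi)))
  list(A = A, b = b)
}

#' Residuals of the single-stance equations of motion
#'
#' Substitutes a pair of angular accelerations back into the two
#' Euler-Lagrange equations; both residuals vanish (to round-off) for the
#' accelerations returned by [single_stance_derivatives()].
#'
#' @param state A [pendulum_state()].
#' @param accel List or vector with `theta_ddot` and `phi_ddot`.
#' @param params A [pendulum_params()].
#' @return Numeric vector of length 2.
#' @export
single_stance_residuals <- function(state, accel, params) {
  sys <- compass_system(state$theta, state$phi,
                        state$theta_dot, state$phi_dot, params)
  acc <- c(accel$theta_ddot, accel$phi_ddot)
  as.numeric(sys$A %*% acc - sys$b)
}

#' Heel-strike event residual
#'
#' The swing foot strikes the ground when the legs are symmetric about the
#' slope normal, i.e. when `phi - 2 * theta` crosses zero.
#'
#' @param state A [pendulum_state()] (or any list with `theta` and `phi`).
#' @return `phi - 2 * theta` (rad).
#' @examples
#' heel_strike_residual(pendulum_state(theta = 0.15, phi = 0.30))
#' @export
heel_strike_residual <- function(state) {
  state$phi - 2 * state$theta
}

#' Mechanical energy of the compass pendulum
#'
#' Kinetic plus gravitational potential energy per unit hip mass, in the
#' slope-aligned frame; conserved along single-stance arcs.
#'
#' @inheritParams single_stance_derivatives
#' @return Energy (J/kg).
#' @export
pendulum_energy <- function(state, params) {
  beta <- params$beta; l <- params$l0; g <- params$g; gam <- params$slope
  thd <- state$theta_dot; phd <- state$phi_dot
  th <- state$theta; ph <- state$phi
  kin <- 0.5 * l^2 * ((1 + beta) * thd^2 + beta * (thd - phd)^2 -
                        2 * beta * thd * (thd - phd) * cos(ph))
  pot <- g * l * ((1 + beta) * cos(th + gam) - beta * cos(th - ph + gam))
  kin + pot
}

#' Integrate the single-support phase with heel-strike detection
#'
#' Integrates the compass-pendulum equations with `deSolve::lsodar` and
#' locates the heel-strike event, the zero crossing of
#' `phi - 2 * theta` with the swing foot descending onto the ground.  A
#' crossing only counts as a heel strike when the stance leg is past
#' vertical (`theta > theta_min`, so the swing foot lands ahead of the
#' contact point) and the residual is decreasing; crossings of the event
#' surface when both legs pass the vertical together are skipped.
#'
#' @param state0 Initial [pendulum_state()].
#' @param params A [pendulum_params()].
#' @param max_time Integration horizon (s, > 0).
#' @param tol Tolerance on `|phi - 2 theta|` at the located event (rad).
#' @param step Output sampling step (s).
#' @param theta_min Minimum stance angle for a valid heel strike (rad).
#' @param rtol,atol Integrator tolerances.
#' @param detect_event If `FALSE`, integrate to `max_time` with no event
#'   handling.
#' @return A list of class `pendulum_arc`: `trajectory` (tibble with
#'   columns `t`, `theta`, `phi`, `theta_dot`, `phi_dot`), `event_time`
#'   (`NULL` when no heel strike occurred within `max_time`), and
#'   `event_state` (a [pendulum_state()] or `NULL`).
#' @examples
#' p <- preset_params("normal")
#' arc <- integrate_single_stance(p$state0, as_pendulum_params(p),
#'                                max_time = 2)
#' arc$event_time
#' @export
integrate_single_stance <- function(state0, params, max_time, tol = 1e-9,
                                    step = 0.002, theta_min = 0.02,
                                    rtol = 1e-10, atol = 1e-10,
                                    detect_event = TRUE) {
  stopifnot(inherits(state0, "pendulum_state"),
            inherits(params, "pendulum_params"), max_time > 0)

  deriv <- function(t, y, parms) {
    sys <- compass_system(y[1], y[2], y[3], y[4], params)
    acc <- solve(sys$A, sys$b)
    list(c(y[3], y[4], acc[1], acc[2]))
  }
  rootf <- function(t, y, parms) y[2] - 2 * y[1]

  # heel strike: swing foot descending onto the ground ahead of the contact
  # (residual decreasing) with the stance leg past vertical
  event_ok <- function(y) {
    y[1] > theta_min && (y[4] - 2 * y[3]) < 0
  }

  y0 <- c(state0$theta, state0$phi, state0$theta_dot, state0$phi_dot)
  t0 <- state0$t

  if (detect_event && abs(y0[2] - 2 * y0[1]) <= tol && event_ok(y0)) {
    traj <- tibble::tibble(t = t0, theta = y0[1], phi = y0[2],
                           theta_dot = y0[3], phi_dot = y0[4])
    return(structure(list(trajectory = traj, event_time = t0,
                          event_state = state0),
                     class = "pendulum_arc"))
  }

  rows <- list()
  t_cur <- t0
  y_cur <- y0
  t_end <- t0 + max_time
  # lsodar cannot start on the event surface (e.g. right after toe-off,
  # where the residual is exactly zero): nudge off it first
  if (detect_event && abs(y0[2] - 2 * y0[1]) < 1e-7) {
    rows[[1]] <- matrix(c(t0, y0), nrow = 1)
    y_cur <- rk4_step(deriv, t0, y0, 1e-5)
    t_cur <- t0 + 1e-5
  }
  event_time <- NULL
  event_state <- NULL

  repeat {
    times <- unique(c(seq(t_cur, t_end, by = step), t_end))
    if (length(times) < 2) break
    out <- if (detect_event) {
      deSolve::lsodar(y = y_cur, times = times, func = deriv, parms = NULL,
                      rootfunc = rootf, rtol = rtol, atol = atol)
    } else {
      deSolve::lsodar(y = y_cur, times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
    }
    if (attr(out, "istate")[1] < 0) {
      stop("single-stance integration failed (lsodar istate ",
           attr(out, "istate")[1], ")", call. = FALSE)
    }
    rows[[length(rows) + 1]] <- out
    troot <- attr(out, "troot")
    if (detect_event && length(troot) > 0 && troot[1] > t0) {
      y_root <- as.numeric(out[nrow(out), -1])
      if (event_ok(y_root)) {
        event_time <- troot[1]
        event_state <- pendulum_state(theta = y_root[1], phi = y_root[2],
                                      theta_dot = y_root[3],
                                      phi_dot = y_root[4], t = event_time)
        break
      }
      # invalid crossing (mid-swing graze or wrong direction): nudge past it
      nudge <- rk4_step(deriv, troot[1], y_root, 1e-6)
      t_cur <- troot[1] + 1e-6
      y_cur <- nudge
      if (t_cur >= t_end) break
    } else {
      break
    }
  }

  traj <- do.call(rbind, lapply(rows, function(m) {
    m <- unclass(m); dimnames(m) <- NULL; as.data.frame(m)
  }))
  names(traj) <- c("t", "theta", "phi", "theta_dot", "phi_dot")
  traj <- tibble::as_tibble(traj)
  traj <- traj[!duplicated(traj$t), , drop = FALSE]
  if (!is.null(event_time)) {
    traj <- traj[traj$t <= event_time, , drop = FALSE]
    if (abs(heel_strike_residual(event_state)) > tol) {
      stop("heel-strike event located outside tolerance", call. = FALSE)
    }
  }
  structure(list(trajectory = traj, event_time = event_time,
                 event_state = event_state),
            class = "pendulum_arc")
}

rk4_step <- function(deriv, t, y, h) {
  k1 <- deriv(t, y, NULL)[[1]]
  k2 <- deriv(t + h / 2, y + h / 2 * k1, NULL)[[1]]
  k3 <- deriv(t + h / 2, y + h / 2 * k2, NULL)[[1]]
  k4 <- deriv(t + h, y + h * k3, NULL)[[1]]
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Centre of gravity from stance-leg angles
#'
#' During single stance the CoG sits at the hip, so in stance-contact
#' coordinates `CoG = (l0 sin(theta), l0 cos(theta))`.
#'
#' @param theta A data frame with a `theta` column (e.g. the trajectory of
#'   a [integrate_single_stance()] arc) or a numeric vector of angles.
#' @param params A [pendulum_params()] (only `l0` is used).
#' @return A tibble with columns `x`, `y` (m).
#' @examples
#' cog_from_pendulum(c(0, pi / 6), pendulum_params())
#' @export
cog_from_pendulum <- function(theta, params) {
  if (is.data.frame(theta)) theta <- theta$theta
  tibble::tibble(x = params$l0 * sin(theta), y = params$l0 * cos(theta))
}
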