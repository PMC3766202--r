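#' Leg spring force coefficients during double stance
#'
#' Each leg acts as a linear spring of rest length `l0` between its ground
#' contact and the CoG.  The force on the CoG from a leg of current length
#' `l` is `k (l0 - l)` directed along the leg, which in Cartesian
#' components is the coefficient `k (l0 / l - 1)` times the contact-to-CoG
#' vector.  The coefficient is positive when the leg is compressed, zero at
#' rest length and negative when stretched.
#'
#' @param state A [spring_mass_state()].
#' @param params A [spring_params()].
#' @return Named numeric vector `c(ll, lr)` for the trailing (origin) and
#'   leading (`(d, 0)`) legs.
#' @examples
#' leg_force_coefficients(spring_mass_state(x = 0, y = 0.9),
#'                        spring_params(k = 400, l0 = 1, d = 0.5))
#' @export
leg_force_coefficients <- function(state, params) {
  stopifnot(inherits(state, "spring_mass_state"),
            inherits(params, "spring_params"))
  coefs_at(state$x, state$y, params)
}

coefs_at <- function(x, y, params) {
  len_l <- sqrt(x^2 + y^2)
  len_r <- sqrt((params$d - x)^2 + y^2)
  if (len_l == 0 || len_r == 0) {
    stop("CoG coincides with a foot contact point", call. = FALSE)
  }
  c(ll = params$k_left * (params$l0 / len_l - 1),
    lr = params$k_right * (params$l0 / len_r - 1))
}

#' Double-stance equations of motion
#'
#' Planar two-leg spring-mass dynamics for the CoG of mass `M`:
#' `M x'' = ll x - lr (d - x)` and `M y'' = ll y + lr y - g M`, with the
#' force coefficients of [leg_force_coefficients()].
#'
#' @inheritParams leg_force_coefficients
#' @return A list of class `spring_mass_state_derivative` with fields
#'   `x_dot`, `y_dot`, `x_ddot`, `y_ddot`.
#' @examples
#' double_stance_derivatives(spring_mass_state(x = 0.25, y = 0.95, x_dot = 1),
#'                           spring_params(k = 400, d = 0.5))
#' @export
double_stance_derivatives <- function(state, params) {
  cf <- leg_force_coefficients(state, params)
  structure(list(
    x_dot = state$x_dot, y_dot = state$y_dot,
    x_ddot = (cf[["ll"]] * state$x - cf[["lr"]] * (params$d - state$x)) /
      params$M,
    y_ddot = (cf[["ll"]] * state$y + cf[["lr"]] * state$y) / params$M -
      params$g),
    class = "spring_mass_state_derivative")
}

#' Mechanical energy of the double-stance system
#'
#' Kinetic plus gravitational plus both spring potential energies; the
#' spring potential of the adopted force law `F = k (l0 - l)` along the leg
#' is `k (l - l0)^2 / 2` in closed form.  Conserved along double-stance
#' arcs.
#'
#' @inheritParams leg_force_coefficients
#' @return Energy (J; J/kg when `M = 1`).
#' @export
spring_mass_energy <- function(state, params) {
  len_l <- sqrt(state$x^2 + state$y^2)
  len_r <- sqrt((params$d - state$x)^2 + state$y^2)
  0.5 * params$M * (state$x_dot^2 + state$y_dot^2) +
    params$M * params$g * state$y +
    0.5 * params$k_left * (len_l - params$l0)^2 +
    0.5 * params$k_right * (len_r - params$l0)^2
}

#' Integrate the double-support phase with toe-off detection
#'
#' Integrates the two-leg spring-mass system until the trailing leg
#' returns to its rest length, i.e. its force coefficient `ll` crosses
#' zero from above (zero-force take-off), or until `max_time`.  Double
#' stance normally starts with the trailing leg at (or very near) rest
#' length, so a root at the initial instant with the leg still shortening
#' is skipped.
#'
#' @param state0 Initial [spring_mass_state()].
#' @param params A [spring_params()].
#' @param max_time Integration horizon (s).
#' @param tol Tolerance on `|ll|` at the located event.
#' @param step Output sampling step (s).
#' @param rtol,atol Integrator tolerances.
#' @return A list of class `spring_arc`: `trajectory` (tibble `t`, `x`,
#'   `y`, `x_dot`, `y_dot`, `ll`, `lr`), `toe_off_time` (`NULL` when no
#'   toe-off occurred), `event_state`.
#' @examples
#' p <- spring_params(k = 2200, d = 0.5)
#' s0 <- spring_mass_state(x = 0.25, y = sqrt(1 - 0.25^2),
#'                         x_dot = 0.9, y_dot = -0.24)
#' arc <- integrate_double_stance(s0, p, max_time = 1)
#' arc$toe_off_time
#' @export
integrate_double_stance <- function(state0, params, max_time, tol = 1e-9,
                                    step = 0.002, rtol = 1e-10,
                                    atol = 1e-10) {
  stopifnot(inherits(state0, "spring_mass_state"),
            inherits(params, "spring_params"), max_time > 0)

  deriv <- function(t, y, parms) {
    if (y[2] <= 0) return(list(c(0, 0, 0, 0)))
    cf <- coefs_at(y[1], y[2], params)
    list(c(y[3], y[4],
           (cf[["ll"]] * y[1] - cf[["lr"]] * (params$d - y[1])) / params$M,
           (cf[["ll"]] + cf[["lr"]]) * y[2] / params$M - params$g))
  }
  # root on trailing-leg length minus rest length: upward crossing = toe-off
  rootf <- function(t, y, parms) sqrt(y[1]^2 + y[2]^2) - params$l0
  # strictly positive radial rate; the entry velocity is tangential to the
  # trailing leg (pure pendulum motion), which must not count as lift-off
  trail_lengthening <- function(y) {
    (y[1] * y[3] + y[2] * y[4]) / sqrt(y[1]^2 + y[2]^2) > 1e-6
  }

  y0 <- c(state0$x, state0$y, state0$x_dot, state0$y_dot)
  t0 <- state0$t
  if (abs(coefs_at(y0[1], y0[2], params)[["ll"]]) <= tol &&
      trail_lengthening(y0)) {
    traj <- tibble::tibble(t = t0, x = y0[1], y = y0[2],
                           x_dot = y0[3], y_dot = y0[4])
    return(finish_spring_arc(traj, t0, y0, params, tol))
  }

  rows <- list()
  t_cur <- t0; y_cur <- y0
  t_end <- t0 + max_time
  toe_off_time <- NULL; y_event <- NULL
  # double stance opens with the trailing leg at rest length, i.e. on the
  # root surface, which lsodar rejects: nudge off it first
  if (abs(sqrt(y0[1]^2 + y0[2]^2) - params$l0) < 1e-7) {
    rows[[1]] <- matrix(c(t0, y0), nrow = 1)
    y_cur <- rk4_step(deriv, t0, y0, 1e-5)
    t_cur <- t0 + 1e-5
  }

  repeat {
    times <- unique(c(seq(t_cur, t_end, by = step), t_end))
    if (length(times) < 2) break
    out <- deSolve::lsodar(y = y_cur, times = times, func = deriv,
                           parms = NULL, rootfunc = rootf,
                           rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      stop("double-stance integration failed (lsodar istate ",
           attr(out, "istate")[1], ")", call. = FALSE)
    }
    if (any(out[, 3] <= 0)) {
      stop("ground penetration: CoG height reached zero during double stance",
           call. = FALSE)
    }
    rows[[length(rows) + 1]] <- out
    troot <- attr(out, "troot")
    if (length(troot) > 0 && troot[1] > t0) {
      y_root <- as.numeric(out[nrow(out), -1])
      if (trail_lengthening(y_root)) {
        toe_off_time <- troot[1]
        y_event <- y_root
        break
      }
      y_cur <- rk4_step(deriv, troot[1], y_root, 1e-7)
      t_cur <- troot[1] + 1e-7
      if (t_cur >= t_end) break
    } else if (length(troot) > 0 && troot[1] == t0) {
      # root flagged at the start (leg at rest length but shortening)
      y_cur <- rk4_step(deriv, t0, as.numeric(out[nrow(out), -1]), 1e-7)
      t_cur <- t0 + 1e-7
    } else {
      break
    }
  }

  traj <- do.call(rbind, lapply(rows, function(m) {
    m <- unclass(m); dimnames(m) <- NULL; as.data.frame(m)
  }))
  names(traj) <- c("t", "x", "y", "x_dot", "y_dot")
  traj <- tibble::as_tibble(traj)
  traj <- traj[!duplicated(traj$t), , drop = FALSE]
  if (!is.null(toe_off_time)) {
    traj <- traj[traj$t <= toe_off_time, , drop = FALSE]
  }
  finish_spring_arc(traj, toe_off_time, y_event, params, tol)
}

finish_spring_arc <- function(traj, toe_off_time, y_event, params, tol) {
  cf <- t(mapply(function(x, y) coefs_at(x, y, params), traj$x, traj$y))
  traj$ll <- cf[, 1]
  traj$lr <- cf[, 2]
  event_state <- NULL
  if (!is.null(toe_off_time) && !is.null(y_event)) {
    if (abs(coefs_at(y_event[1], y_event[2], params)[["ll"]]) > tol) {
      stop("toe-off event located outside tolerance", call. = FALSE)
    }
    event_state <- spring_mass_state(x = y_event[1], y = y_event[2],
                                     x_dot = y_event[3], y_dot = y_event[4],
                                     t = toe_off_time)
  }
  structure(list(trajectory = traj, toe_off_time = toe_off_time,
                 event_state = event_state),
            class = "spring_arc")
}
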