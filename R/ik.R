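#' Two-link knee angle by the law of cosines
#'
#' The leg is a two-link chain with equal thigh and shank lengths
#' `l0 / 2` (the knee sits midway along the leg).  For a
#' hip-to-heel distance `c` the knee flexion is
#' \deqn{\gamma = \arccos\!\left(\frac{c^2 - r^2 - r^2}{2 r^2}\right),}
#' with `gamma = 0` the fully straight knee and `gamma` in \[0, pi\].
#' Targets beyond the reach sphere (`c > l0`) are clamped onto it
#' (`gamma = 0`).
#'
#' @param hip,heel Numeric length-2 points (m).
#' @param l0 Leg length (m).
#' @return Knee flexion angle (rad).
#' @examples
#' knee_angle(c(0, 1), c(0, 0), l0 = 1)              # straight leg
#' knee_angle(c(0, 0), c(1 / sqrt(2), 0), l0 = 1)    # pi / 2
#' @export
knee_angle <- function(hip, heel, l0) {
  a <- b <- l0 / 2
  cc <- sqrt(sum((heel - hip)^2))
  cosg <- (cc^2 - a^2 - b^2) / (2 * a * b)
  acos(pmin(pmax(cosg, -1), 1))
}

#' Two-link hip angle
#'
#' Hip flexion measured from the vertical-down reference axis, positive
#' forward: the bearing of the hip-to-heel vector plus the interior
#' correction `atan2(r sin(gamma), r + r cos(gamma))`, so that forward
#' kinematics of `(omega, gamma)` reaches the heel exactly (anatomical
#' branch: the knee flexes backward).
#'
#' @inheritParams knee_angle
#' @param gamma Knee flexion (rad) from [knee_angle()].
#' @return Hip flexion angle (rad).
#' @export
hip_angle <- function(hip, heel, gamma, l0) {
  a <- b <- l0 / 2
  delta <- heel - hip
  bearing <- atan2(delta[1], -delta[2])
  bearing + atan2(b * sin(gamma), a + b * cos(gamma))
}

#' Forward kinematics of the two-link leg
#'
#' @inheritParams hip_angle
#' @param omega Hip flexion (rad), from vertical down, positive forward.
#' @return A list with `knee` and `heel` points; the shank direction is
#'   the thigh direction rotated backward by `gamma`.
#' @examples
#' forward_kinematics(c(0, 1), omega = 0, gamma = 0, l0 = 1)$heel
#' @export
forward_kinematics <- function(hip, omega, gamma, l0) {
  a <- b <- l0 / 2
  knee <- hip + a * c(sin(omega), -cos(omega))
  heel <- knee + b * c(sin(omega - gamma), -cos(omega - gamma))
  list(knee = knee, heel = heel)
}

#' Analytic two-link inverse kinematics
#'
#' @inheritParams knee_angle
#' @return A list with `omega`, `gamma` and `clamped` (logical: was the
#'   target beyond reach and clamped onto the reach sphere?).
#' @export
solve_leg_ik <- function(hip, heel, l0) {
  cc <- sqrt(sum((heel - hip)^2))
  clamped <- cc > l0
  gamma <- knee_angle(hip, heel, l0)
  omega <- hip_angle(hip, heel, gamma, l0)
  list(omega = omega, gamma = gamma, clamped = clamped)
}

#' Cyclic coordinate descent for the two-link leg
#'
#' Iteratively adjusts the distal (knee) then proximal (hip) joint, each
#' time rotating its sub-chain so the heel points at the target; the knee
#' is clamped to the anatomical range \[0, pi\].  Each joint update is an
#' exact one-joint minimization, so the end-effector error is
#' non-increasing across iterations.
#'
#' @inheritParams knee_angle
#' @param target Target heel point (length-2).
#' @param max_iter Maximum sweeps.  Coordinate descent converges only
#'   linearly, and its rate degrades near the workspace singularities
#'   (targets close to the hip or to full extension), so the default is
#'   generous; sweeps are cheap.
#' @param tol End-effector position tolerance (m).
#' @param init Starting `c(omega, gamma)`; the default starts with a
#'   bent knee because the fully straight chain is a coordinate-descent
#'   ridge (once the hip aligns a straight chain with the target ray,
#'   the knee update cannot improve).  If the iteration still stalls on
#'   the ridge with the knee clamped straight, the knee is re-bent and
#'   the sweep continues.
#' @return A list with `omega`, `gamma`, `error` (final heel-to-target
#'   distance), `iterations`, and `error_trace` (error after each sweep).
#'   Raises an error if the target is reachable but the tolerance is not
#'   met within `max_iter`.
#' @examples
#' ccd_solve(hip = c(0, 1), target = c(0.3, 0.2), l0 = 1)
#' @export
ccd_solve <- function(hip, target, l0, max_iter = 5000, tol = 1e-9,
                      init = c(0, pi / 2)) {
  omega <- init[1]; gamma <- min(max(init[2], 0), pi)
  a <- b <- l0 / 2
  err <- function(om, ga) {
    sqrt(sum((forward_kinematics(hip, om, ga, l0)$heel - target)^2))
  }
  reach <- sqrt(sum((target - hip)^2))
  best_possible <- max(reach - l0, 0)
  trace <- err(omega, gamma)
  if (trace <= max(tol, best_possible + tol)) {
    return(list(omega = omega, gamma = gamma, error = trace,
                iterations = 0L, error_trace = trace, nudges = 0L))
  }
  nudges <- 0L
  for (it in seq_len(max_iter)) {
    # knee: point the shank at the target
    knee <- hip + a * c(sin(omega), -cos(omega))
    dk <- target - knee
    if (any(dk != 0)) {
      shank_bearing <- atan2(dk[1], -dk[2])
      gamma <- min(max(omega - shank_bearing, 0), pi)
    }
    # hip: rotate the whole chain about the hip toward the target
    heel <- forward_kinematics(hip, omega, gamma, l0)$heel
    dh_e <- heel - hip; dh_t <- target - hip
    if (any(dh_e != 0) && any(dh_t != 0)) {
      omega <- omega + (atan2(dh_t[1], -dh_t[2]) - atan2(dh_e[1], -dh_e[2]))
    }
    trace <- c(trace, err(omega, gamma))
    if (trace[length(trace)] <= max(tol, best_possible + tol)) {
      return(list(omega = omega, gamma = gamma,
                  error = trace[length(trace)], iterations = it,
                  error_trace = trace, nudges = nudges))
    }
    # straight-chain ridge: the hip has aligned a fully extended chain
    # with the target ray, so the knee sees the target dead ahead and
    # clamps straight; flex the hip past the target bearing so the next
    # knee update bends anatomically
    if (it > 1 &&
        abs(trace[length(trace)] - trace[length(trace) - 1]) < 1e-14 &&
        (gamma < 1e-12 || gamma > pi - 1e-12)) {
      omega <- omega + if (gamma < 1e-12) 0.5 else -0.5
      nudges <- nudges + 1L
      if (nudges > 5L) break
    }
  }
  stop(sprintf("CCD did not converge: residual %.3e m after %d iterations",
               trace[length(trace)], max_iter), call. = FALSE)
}

#' Fuse the simulated CoG with a learned heel path into joint angles
#'
#' For every sample of a normalized CoG cycle, evaluates the class heel
#' path (the contralateral heel is the same path shifted by 50% of the
#' cycle and one step length back), anchors the two-link leg at the CoG
#' and solves the inverse kinematics, giving hip and knee
#' flexion-extension trajectories for both legs.  The CoG cycle is
#' translated so the cycle-opening heel strike of the right foot sits at
#' the heel-path origin.
#'
#' @param cog A `gait_cycle` from [normalize_to_cycle()].
#' @param mix A `heel_mixture` for the same gait class, fitted on a heel
#'   corpus whose step length matches the simulated one (see
#'   `step_length`).
#' @param l0 Leg length (m); default taken from the cycle's parameters.
#' @param step_length Step length (m) shared by the CoG cycle and the
#'   heel corpus; defaults to the simulated step length recorded in the
#'   cycle, falling back to the parameter `d`.
#' @param hip_offset Vertical drop (m) from the body CoG to the hip
#'   joint that anchors the leg chain: the pelvis sits below the
#'   whole-body mass centre, and anchoring the two-link leg at the raw
#'   CoG would leave the planted heel geometrically out of reach through
#'   mid-stance.  Defaults per gait class (fraction of `l0`): 0.10 for
#'   normal, 0.26 for crouch (the dropped, flexed pelvis is the clinical
#'   signature) and 0.15-0.20 for the stooped Parkinsonian classes.
#' @param max_unreachable Error threshold on the fraction of samples whose
#'   heel target had to be clamped onto the reach sphere.
#' @return An object of class `joint_angles`: `angles` (tibble `percent`,
#'   `hip_R`, `knee_R`, `hip_L`, `knee_L`, radians, flexion positive),
#'   `clamped_fraction`, `l0`, `gait_class`.
#' @export
fuse_trajectories <- function(cog, mix, l0 = NULL, step_length = NULL,
                              hip_offset = NULL,
                              max_unreachable = 0.05) {
  stopifnot(inherits(cog, "gait_cycle"), inherits(mix, "heel_mixture"))
  if (is.null(l0)) {
    if (is.null(cog$params)) stop("l0 not given and not in the cycle",
                                  call. = FALSE)
    l0 <- cog$params$l0
  }
  if (is.null(step_length)) {
    step_length <- cog$step_length %||% NA_real_
    if (is.na(step_length)) {
      # the CoG advances one stride (two steps) per cycle
      step_length <- (cog$samples$x[nrow(cog$samples)] -
                        cog$samples$x[1]) / 2
    }
    if (!is.finite(step_length) || step_length <= 0) {
      stop("step_length not given and not recoverable from the cycle",
           call. = FALSE)
    }
  }
  s <- step_length
  pct <- cog$samples$percent
  # translate the CoG into the heel-path frame: the cycle-opening strike
  # of the (right) heel defines the origin
  x_strike <- cog$strike_x %||% NA_real_
  if (is.na(x_strike)) x_strike <- cog$samples$x[1] + s / 2
  if (is.null(hip_offset)) {
    frac <- switch(mix$gait_class, crouch = 0.26,
                   parkinson = 0.15, parkinson_stage2 = ,
                   parkinson_stage3 = , parkinson_stage4 = 0.20, 0.10)
    hip_offset <- frac * l0
  }
  hip_x <- cog$samples$x - x_strike
  hip_y <- cog$samples$y - hip_offset

  # the mixture stores the class heel *shape*; its forward sweep is
  # rescaled so the per-cycle heel displacement matches the simulated
  # stride (2 * step_length)
  ends <- evaluate_heel_path(mix, c(0, 100))
  step_gen <- (ends$x[2] - ends$x[1]) / 2
  scale_x <- if (is.finite(step_gen) && step_gen > 1e-6) s / step_gen else 1
  x0 <- ends$x[1]
  heel_R <- evaluate_heel_path(mix, pct)
  heel_R$x <- x0 + (heel_R$x - x0) * scale_x
  pct_L <- (pct + 50) %% 100
  heel_L <- evaluate_heel_path(mix, pct_L)
  heel_L$x <- x0 + (heel_L$x - x0) * scale_x + ifelse(pct >= 50, s, -s)

  solve_all <- function(hx, hy) {
    out <- vapply(seq_along(pct), function(i) {
      s <- solve_leg_ik(c(hip_x[i], hip_y[i]), c(hx[i], hy[i]), l0)
      c(s$omega, s$gamma, as.numeric(s$clamped))
    }, numeric(3))
    list(omega = out[1, ], gamma = out[2, ], clamped = out[3, ] > 0)
  }
  R <- solve_all(heel_R$x, heel_R$y)
  L <- solve_all(heel_L$x, heel_L$y)
  clamped <- mean(c(R$clamped, L$clamped))
  if (clamped > max_unreachable) {
    stop(sprintf(
      "%.1f%% of heel targets unreachable (limit %.1f%%): CoG and heel path are inconsistent",
      100 * clamped, 100 * max_unreachable), call. = FALSE)
  }
  structure(list(
    angles = tibble::tibble(percent = pct, hip_R = R$omega,
                            knee_R = R$gamma, hip_L = L$omega,
                            knee_L = L$gamma),
    clamped_fraction = clamped, l0 = l0, gait_class = mix$gait_class),
    class = "joint_angles")
}

#' @export
print.joint_angles <- function(x, ...) {
  cat(sprintf(
    "<joint_angles %s: %d samples, knee flexion %.1f-%.1f deg (R)>\n",
    x$gait_class, nrow(x$angles),
    min(x$angles$knee_R) * 180 / pi, max(x$angles$knee_R) * 180 / pi))
  invisible(x)
}
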