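#' Hand-off from single stance to double stance
#'
#' At heel strike the pendulum CoG, expressed in stance-contact polar
#' coordinates, is mapped into the two-contact double-stance frame: the
#' old stance contact becomes the trailing contact at the origin and the
#' landing foot the leading contact at `(d, 0)`.  CoG position and
#' velocity are preserved exactly.  The foot separation implied by the
#' pendulum geometry is `2 l0 sin(theta)`; when it differs from the
#' configured `d` by more than `tol_geom` a warning is raised and the
#' leading contact is projected onto `(d, 0)` regardless.
#'
#' @param state A [pendulum_state()] satisfying the heel-strike condition.
#' @param params A [gait_params()].
#' @param tol_geom Foot-separation mismatch (m) above which to warn.
#' @return A [spring_mass_state()].
#' @export
handoff_pendulum_to_spring <- function(state, params, tol_geom = 0.02) {
  stopifnot(inherits(state, "pendulum_state"), inherits(params, "gait_params"))
  l0 <- params$l0
  implied <- 2 * l0 * sin(state$theta)
  if (abs(implied - params$d) > tol_geom) {
    warning(sprintf(
      "heel-strike foot separation %.4f m incompatible with d = %.4f m; projecting onto configured d",
      implied, params$d), call. = FALSE)
  }
  spring_mass_state(
    x = l0 * sin(state$theta), y = l0 * cos(state$theta),
    x_dot = l0 * state$theta_dot * cos(state$theta),
    y_dot = -l0 * state$theta_dot * sin(state$theta),
    t = state$t)
}

#' Hand-off from double stance to single stance
#'
#' At toe-off the pendulum phase restarts about the leading contact.  The
#' stance-leg angle is recovered from the orientation of the leg, the
#' angular rate from the tangential CoG velocity, and the swing-leg angle
#' and rate from the (still planted) trailing contact.  Because the
#' leading leg can retain a small residual compression at trailing-leg
#' toe-off, the pivot is relocated to the point at distance `l0` from the
#' CoG along the leg ray (a heel-to-toe rollover analogue): the CoG is
#' then exactly continuous across the hand-off, at the price of a pivot
#' offset of `l0 - r` along the leg, reported in the `anchor` attribute.
#'
#' @param state A [spring_mass_state()] at toe-off.
#' @param params A [gait_params()].
#' @param new_stance `"leading"` (the physical choice at toe-off) or
#'   `"trailing"` (the algebraic inverse of
#'   [handoff_pendulum_to_spring()]).
#' @param pivot Pivot-relocation rule: `"rollover"` places the new pivot
#'   on the ground at distance `l0` ahead of the CoG (the heel-to-toe
#'   rollover analogue, used by [simulate_gait()]); `"leg"` slides it
#'   along the leg ray through the old contact.  Both preserve the CoG
#'   exactly; they coincide when the stance leg is exactly at `l0` on the
#'   ground.
#' @param tol_geom Stance-leg length deviation from `l0` (m) above which
#'   to warn before relocating the pivot.
#' @return A [pendulum_state()] with attribute `anchor`: the pivot
#'   position in the double-stance frame.
#' @export
handoff_spring_to_pendulum <- function(state, params,
                                       new_stance = c("leading", "trailing"),
                                       pivot = c("rollover", "leg"),
                                       tol_geom = 0.02) {
  stopifnot(inherits(state, "spring_mass_state"),
            inherits(params, "gait_params"))
  new_stance <- match.arg(new_stance)
  pivot <- match.arg(pivot)
  l0 <- params$l0; d <- params$d
  foot_s <- if (new_stance == "leading") c(d, 0) else c(0, 0)
  foot_w <- if (new_stance == "leading") c(0, 0) else c(d, 0)
  cog <- c(state$x, state$y)
  vel <- c(state$x_dot, state$y_dot)

  leg_s <- cog - foot_s
  r_s <- sqrt(sum(leg_s^2))
  if (abs(r_s - l0) > tol_geom) {
    warning(sprintf(
      "stance-leg length %.4f m incompatible with l0 = %.4f m; relocating pivot onto the reach sphere",
      r_s, l0), call. = FALSE)
  }
  if (pivot == "rollover" && state$y < l0) {
    # ground point at distance l0 from the CoG, ahead of it (the toe)
    sgn <- if (new_stance == "leading") 1 else -1
    anchor <- c(cog[1] + sgn * sqrt(l0^2 - cog[2]^2), 0)
    u <- (cog - anchor) / l0
  } else {
    u <- leg_s / r_s
    anchor <- cog - l0 * u
  }
  theta <- atan2(u[1], u[2])
  theta_dot <- (vel[1] * cos(theta) - vel[2] * sin(theta)) / l0

  leg_w <- cog - foot_w
  r_w <- sqrt(sum(leg_w^2))
  sigma <- atan2(leg_w[1], leg_w[2])
  sigma_dot <- (vel[1] * leg_w[2] - leg_w[1] * vel[2]) / r_w^2

  out <- pendulum_state(theta = theta, phi = theta - sigma,
                        theta_dot = theta_dot,
                        phi_dot = theta_dot - sigma_dot, t = state$t)
  attr(out, "anchor") <- anchor
  out
}

#' Simulate full gait cycles with the fused hybrid model
#'
#' Alternates the compass-pendulum single stance and the spring-mass
#' double stance, switching at heel strike (`phi - 2 theta = 0`) and at
#' trailing-leg toe-off, with the state hand-offs of
#' [handoff_pendulum_to_spring()] and [handoff_spring_to_pendulum()].  A
#' gait cycle spans ipsilateral heel strike to ipsilateral heel strike
#' (two steps); the lead-in before the first heel strike carries
#' `cycle = 0`.  Each heel strike advances the foothold by the configured
#' step length `d`, so the stride length is `2 d` per cycle.
#'
#' @param params A [gait_params()], e.g. from [preset_params()].
#' @param n_cycles Number of complete cycles to simulate (>= 0).
#' @param seed Optional integer seed, stored with the trajectory; the
#'   dynamics is deterministic, so identical `params` and `seed` give
#'   bit-identical output.
#' @param phase_cap Time cap (s) for any one stance phase; exceeding it
#'   raises a "non-walking parameters" error naming the phase.
#' @param step Output sampling step (s).
#' @param quiet Suppress geometry-projection warnings from the hand-offs.
#' @return An object of class `gait_trajectory` with elements `samples`
#'   (tibble `t`, `x`, `y`, `phase`, `cycle`), `events` (tibble `t`,
#'   `event`, `foot`, `cycle`, `jump` -- the CoG discontinuity audited at
#'   each hand-off), `params`, `n_cycles`, `seed`.
#' @examples
#' \donttest{
#' traj <- simulate_gait(preset_params("normal"), n_cycles = 2)
#' glance(traj)
#' }
#' @export
simulate_gait <- function(params, n_cycles, seed = NULL, phase_cap = 5,
                          step = 0.002, quiet = TRUE) {
  stopifnot(inherits(params, "gait_params"), n_cycles >= 0)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  empty <- function() {
    structure(list(
      samples = tibble::tibble(t = double(), x = double(), y = double(),
                               phase = character(), cycle = integer()),
      events = tibble::tibble(t = double(), event = character(),
                              foot = character(), contact_x = double(),
                              cycle = integer(), jump = double()),
      params = params, n_cycles = 0L, seed = seed,
      cycle_starts = double(), step_length = NA_real_),
      class = "gait_trajectory")
  }
  if (n_cycles == 0) return(empty())

  pp <- as_pendulum_params(params)
  sp <- as_spring_params(params)
  n_strikes <- 2L * n_cycles + 1L

  anchor <- c(0, 0)            # global position of the current stance pivot
  stance_foot <- "R"
  other <- function(f) if (f == "R") "L" else "R"
  state <- params$state0
  samples <- list(); events <- list()
  t_now <- state$t
  strikes <- 0L
  anchor_xs <- anchor[1]

  maybe_quiet <- function(expr) {
    if (quiet) suppressWarnings(expr) else expr
  }

  while (strikes < n_strikes) {
    arc <- integrate_single_stance(state, pp, max_time = phase_cap,
                                   step = step)
    if (is.null(arc$event_time)) {
      stop("non-walking parameters: no heel strike within ", phase_cap,
           " s of single stance", call. = FALSE)
    }
    tr <- arc$trajectory
    samples[[length(samples) + 1]] <- tibble::tibble(
      t = tr$t,
      x = anchor[1] + params$l0 * sin(tr$theta),
      y = anchor[2] + params$l0 * cos(tr$theta),
      phase = "single_stance")
    strikes <- strikes + 1L
    cog_before <- anchor + params$l0 * c(sin(arc$event_state$theta),
                                         cos(arc$event_state$theta))
    if (strikes == n_strikes) {
      events[[length(events) + 1]] <- tibble::tibble(
        t = arc$event_time, event = "heel_strike",
        foot = other(stance_foot), contact_x = anchor[1] + params$d,
        jump = 0)
      break
    }

    ss <- maybe_quiet(handoff_pendulum_to_spring(arc$event_state, params))
    jump_hs <- sqrt(sum((anchor + c(ss$x, ss$y) - cog_before)^2))
    events[[length(events) + 1]] <- tibble::tibble(
      t = arc$event_time, event = "heel_strike",
      foot = other(stance_foot), contact_x = anchor[1] + params$d,
      jump = jump_hs)

    darc <- integrate_double_stance(ss, sp, max_time = phase_cap,
                                    step = step)
    if (is.null(darc$toe_off_time)) {
      stop("non-walking parameters: no toe-off within ", phase_cap,
           " s of double stance", call. = FALSE)
    }
    dtr <- darc$trajectory[-1, , drop = FALSE]  # boundary row already kept
    samples[[length(samples) + 1]] <- tibble::tibble(
      t = dtr$t, x = anchor[1] + dtr$x, y = anchor[2] + dtr$y,
      phase = "double_stance")

    cog_before <- anchor + c(darc$event_state$x, darc$event_state$y)
    ps <- maybe_quiet(handoff_spring_to_pendulum(darc$event_state, params))
    local_anchor <- attr(ps, "anchor")
    new_anchor <- anchor + local_anchor
    jump_to <- sqrt(sum((new_anchor +
                           params$l0 * c(sin(ps$theta), cos(ps$theta)) -
                           cog_before)^2))
    events[[length(events) + 1]] <- tibble::tibble(
      t = darc$toe_off_time, event = "toe_off",
      foot = stance_foot, contact_x = new_anchor[1], jump = jump_to)

    anchor <- new_anchor
    anchor_xs <- c(anchor_xs, anchor[1])
    stance_foot <- other(stance_foot)
    attr(ps, "anchor") <- NULL
    state <- ps
    t_now <- darc$toe_off_time
    # drop the duplicated boundary sample at the start of the next arc
    samples[[length(samples)]] <-
      samples[[length(samples)]][samples[[length(samples)]]$t <=
                                   darc$toe_off_time, , drop = FALSE]
  }

  samples <- dplyr::bind_rows(samples)
  samples <- samples[!duplicated(samples$t), , drop = FALSE]
  samples <- samples[order(samples$t), , drop = FALSE]
  events <- dplyr::bind_rows(events)

  hs_times <- events$t[events$event == "heel_strike"]
  cycle_starts <- hs_times[seq(1, length(hs_times), by = 2)]
  # a boundary heel strike belongs to the cycle it opens
  cyc_of <- function(t) {
    idx <- findInterval(t + 1e-12, cycle_starts)
    as.integer(pmin(idx, n_cycles))
  }
  samples$cycle <- cyc_of(samples$t)
  events$cycle <- cyc_of(events$t)

  step_length <- if (length(anchor_xs) > 1) mean(diff(anchor_xs)) else NA_real_
  structure(list(samples = samples, events = events, params = params,
                 n_cycles = as.integer(n_cycles), seed = seed,
                 cycle_starts = cycle_starts, step_length = step_length),
            class = "gait_trajectory")
}

#' @export
print.gait_trajectory <- function(x, ...) {
  cat(sprintf("<gait_trajectory %s: %d cycle(s), %d samples, %d events>\n",
              x$params$gait_class, x$n_cycles, nrow(x$samples),
              nrow(x$events)))
  invisible(x)
}

#' Normalize one gait cycle onto a uniform percent grid
#'
#' Extracts one complete cycle (ipsilateral heel strike to ipsilateral
#' heel strike) from a simulated trajectory and resamples the CoG path by
#' linear interpolation onto a uniform 0--100% grid, the gait-analysis
#' convention.  The first simulated cycle is treated as transient and
#' skipped by default.  A plain data frame with columns `percent`, `x`,
#' `y` is resampled directly.
#'
#' @param traj A `gait_trajectory` from [simulate_gait()], or a data frame
#'   with columns `percent`, `x`, `y`.
#' @param n_points Number of grid points (default 101: 0, 1, ..., 100%).
#' @param cycle Which cycle to normalize; default is the first
#'   post-transient cycle (cycle 2 when available, otherwise cycle 1).
#' @return An object of class `gait_cycle`: `samples` (tibble `percent`,
#'   `x`, `y`, `phase`), `events` (tibble `percent`, `event`, `foot`),
#'   `t_start`, `t_end`, `cycle`, `params`.
#' @export
normalize_to_cycle <- function(traj, n_points = 101, cycle = NULL) {
  grid <- seq(0, 100, length.out = n_points)
  if (is.data.frame(traj)) {
    stopifnot(all(c("percent", "x", "y") %in% names(traj)))
    samples <- tibble::tibble(
      percent = grid,
      x = stats::approx(traj$percent, traj$x, xout = grid)$y,
      y = stats::approx(traj$percent, traj$y, xout = grid)$y)
    return(structure(list(samples = samples,
                          events = tibble::tibble(percent = double(),
                                                  event = character(),
                                                  foot = character()),
                          t_start = NA_real_, t_end = NA_real_,
                          cycle = NA_integer_, params = NULL),
                     class = "gait_cycle"))
  }
  stopifnot(inherits(traj, "gait_trajectory"))
  if (traj$n_cycles < 1) stop("no complete cycle present", call. = FALSE)
  if (is.null(cycle)) cycle <- if (traj$n_cycles >= 2) 2L else 1L
  if (cycle < 1 || cycle > traj$n_cycles) {
    stop("cycle ", cycle, " not present (", traj$n_cycles,
         " simulated)", call. = FALSE)
  }
  t0 <- traj$cycle_starts[cycle]
  t1 <- traj$cycle_starts[cycle + 1]
  if (is.na(t1)) stop("incomplete cycle", call. = FALSE)
  sm <- traj$samples[traj$samples$t >= t0 & traj$samples$t <= t1, ,
                     drop = FALSE]
  pct <- function(t) 100 * (t - t0) / (t1 - t0)
  ev <- traj$events[traj$events$t > t0 & traj$events$t < t1, , drop = FALSE]
  ev_pct <- tibble::tibble(percent = pct(ev$t), event = ev$event,
                           foot = ev$foot)
  xg <- stats::approx(pct(sm$t), sm$x, xout = grid, ties = "ordered")$y
  yg <- stats::approx(pct(sm$t), sm$y, xout = grid, ties = "ordered")$y
  # phase from event bracketing: double stance after a heel strike (incl.
  # the cycle-opening one) until the next toe-off
  bounds <- c(0, ev_pct$percent, 100)
  labs <- character(length(bounds) - 1)
  state <- "double_stance"  # a cycle opens at heel strike
  k <- 1
  for (i in seq_len(length(bounds) - 1)) {
    labs[i] <- state
    if (i <= nrow(ev_pct)) {
      state <- if (ev_pct$event[i] == "heel_strike") "double_stance"
      else "single_stance"
    }
  }
  idx <- findInterval(grid, bounds, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[grid == 0] <- 1
  samples <- tibble::tibble(percent = grid, x = xg, y = yg,
                            phase = labs[idx])
  open_hs <- traj$events[traj$events$event == "heel_strike" &
                           abs(traj$events$t - t0) < 1e-9, , drop = FALSE]
  strike_x <- if (nrow(open_hs)) open_hs$contact_x[1] else NA_real_
  structure(list(samples = samples, events = ev_pct, t_start = t0,
                 t_end = t1, cycle = as.integer(cycle),
                 params = traj$params, strike_x = strike_x,
                 step_length = traj$step_length),
            class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("<gait_cycle: %d points, cycle %s>\n", nrow(x$samples),
              ifelse(is.na(x$cycle), "-", x$cycle)))
  invisible(x)
}

#' Phase timing of a simulated cycle
#'
#' Double-stance fraction and event positions for one normalized cycle.
#'
#' @param traj A `gait_trajectory`.
#' @param cycle Cycle index (default: first post-transient cycle).
#' @return A list with `ds_fraction` (% of cycle time in double stance),
#'   `contralateral_heel_strike` and `ipsilateral_toe_off` (% positions),
#'   `events` (tibble of within-cycle events with `percent`).
#' @export
cycle_timing <- function(traj, cycle = NULL) {
  stopifnot(inherits(traj, "gait_trajectory"))
  if (is.null(cycle)) cycle <- if (traj$n_cycles >= 2) 2L else 1L
  t0 <- traj$cycle_starts[cycle]
  t1 <- traj$cycle_starts[cycle + 1]
  ev <- traj$events[traj$events$t >= t0 & traj$events$t < t1, , drop = FALSE]
  ev$percent <- 100 * (ev$t - t0) / (t1 - t0)
  to <- ev[ev$event == "toe_off", , drop = FALSE]
  hs_mid <- ev[ev$event == "heel_strike" & ev$t > t0, , drop = FALSE]
  ds <- sum(to$t - c(t0, hs_mid$t)[seq_len(nrow(to))])
  list(ds_fraction = 100 * ds / (t1 - t0),
       contralateral_heel_strike = if (nrow(hs_mid)) hs_mid$percent[1]
       else NA_real_,
       ipsilateral_toe_off = if (nrow(to) >= 2) to$percent[2] else NA_real_,
       events = tibble::as_tibble(ev[, c("percent", "event", "foot")]))
}
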