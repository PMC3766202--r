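test_that("leg force coefficients follow the adopted spring law", {
  p <- spring_params(k = 400, l0 = 1, d = 0.5)
  cf <- leg_force_coefficients(spring_mass_state(x = 0, y = 1), p)
  expect_equal(cf[["ll"]], 0)
  cf <- leg_force_coefficients(spring_mass_state(x = 0, y = 0.9), p)
  expect_equal(cf[["ll"]], 400 * (1 / 0.9 - 1), tolerance = 1e-12)
  # mirror symmetry at mid-stance
  for (y in c(0.7, 0.9, 1.1)) {
    cf <- leg_force_coefficients(spring_mass_state(x = 0.25, y = y), p)
    expect_equal(cf[["ll"]], cf[["lr"]])
  }
})

test_that("accelerations agree with the vector-form spring oracle", {
  set.seed(11)
  for (i in 1:50) {
    p <- spring_params(M = runif(1, 0.5, 80), k = runif(1, 50, 800),
                       l0 = runif(1, 0.8, 1.2), d = runif(1, 0.1, 0.7))
    st <- spring_mass_state(x = runif(1, -0.2, p$d + 0.2),
                            y = runif(1, 0.5, 1.2),
                            x_dot = runif(1, -1, 1),
                            y_dot = runif(1, -1, 1))
    dv <- double_stance_derivatives(st, p)
    acc <- spring_oracle_accel(st$x, st$y, st$x_dot, st$y_dot, p)
    expect_equal(dv$x_ddot, acc[1], tolerance = 1e-10)
    expect_equal(dv$y_ddot, acc[2], tolerance = 1e-10)
  }
})

test_that("a symmetric equilibrium has zero acceleration", {
  # choose y so that the two compressed springs carry the weight at x = d/2
  p <- spring_params(M = 1, k = 400, l0 = 1, d = 0.5, g = 9.81)
  f <- function(y) {
    cf <- leg_force_coefficients(spring_mass_state(x = p$d / 2, y = y), p)
    (cf[["ll"]] + cf[["lr"]]) * y - p$g * p$M
  }
  y_eq <- uniroot(f, c(0.8, 0.99), tol = 1e-14)$root
  dv <- double_stance_derivatives(spring_mass_state(x = p$d / 2, y = y_eq), p)
  expect_equal(dv$x_ddot, 0, tolerance = 1e-9)
  expect_equal(dv$y_ddot, 0, tolerance = 1e-9)
})

test_that("rest-length legs without gravity give zero force", {
  p <- spring_params(M = 1, k = 400, l0 = 1, d = 0, g = 1e-300)
  dv <- double_stance_derivatives(spring_mass_state(x = 0, y = 1), p)
  expect_equal(dv$x_ddot, 0)
  expect_equal(dv$y_ddot, 0, tolerance = 1e-12)
})

test_that("energy is conserved along a double-stance arc", {
  p <- spring_params(M = 1, k = 150, l0 = 1, d = 0.3)
  st <- spring_mass_state(x = 0.15, y = 0.96, x_dot = 0.5, y_dot = -0.3)
  arc <- integrate_double_stance(st, p, max_time = 0.15)
  tr <- arc$trajectory
  n <- nrow(tr)
  e0 <- spring_mass_energy(st, p)
  e1 <- spring_mass_energy(
    spring_mass_state(x = tr$x[n], y = tr$y[n], x_dot = tr$x_dot[n],
                      y_dot = tr$y_dot[n]), p)
  expect_lt(abs(e1 - e0) / abs(e0), 1e-6)
})

test_that("small vertical bounces have the linearized spring period", {
  # both feet coincident (d = 0): vertical oscillation of M on two
  # parallel springs, period 2 pi sqrt(M / (2 k)) in the linear regime
  M <- 1; k <- 400; g <- 9.81; l0 <- 1
  p <- spring_params(M = M, k = k, l0 = l0, d = 0, g = g)
  y_eq <- l0 - g * M / (2 * k)
  st <- spring_mass_state(x = 0, y = y_eq - 1e-4)
  arc <- integrate_double_stance(st, p, max_time = 1, step = 5e-4)
  tr <- arc$trajectory
  # period from successive upward zero crossings of y_dot
  s <- sign(tr$y_dot)
  up <- which(diff(s) > 0)
  cross <- tr$t[up] - tr$y_dot[up] * (tr$t[up + 1] - tr$t[up]) /
    (tr$y_dot[up + 1] - tr$y_dot[up])
  period <- mean(diff(cross))
  expect_equal(period, 2 * pi * sqrt(M / (2 * k)), tolerance = 0.01)
  expect_true(all(abs(tr$x) < 1e-12))
})

test_that("toe-off is detected at trailing-leg rest length", {
  p <- as_spring_params(preset_params("normal"))
  traj <- cached_traj("normal", 2)
  hs <- traj$events[traj$events$event == "heel_strike", ][1, ]
  # rebuild the double-stance entry state at the first heel strike
  gp <- preset_params("normal")
  arc <- integrate_single_stance(gp$state0, as_pendulum_params(gp),
                                 max_time = 3)
  ss0 <- handoff_pendulum_to_spring(arc$event_state, gp)
  darc <- integrate_double_stance(ss0, p, max_time = 2)
  expect_false(is.null(darc$toe_off_time))
  len <- sqrt(darc$event_state$x^2 + darc$event_state$y^2)
  expect_lt(abs(len - p$l0) * p$k_left / p$l0, 1e-6)

  # bisection oracle on a fine reference solution
  ref <- integrate_double_stance(ss0, p, max_time = 2, step = 2e-4,
                                 tol = 1e-12)
  tr <- ref$trajectory
  res <- sqrt(tr$x^2 + tr$y^2) - p$l0
  i <- which(res < -1e-6)[1]  # safely inside compression
  j <- i + which(res[(i + 1):nrow(tr)] >= 0)[1]
  f <- approxfun(tr$t, res)
  lo <- tr$t[j - 1]; hi <- tr$t[j]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  expect_equal(darc$toe_off_time, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("a trailing leg already lengthening at rest length lifts off at once", {
  p <- spring_params(M = 1, k = 200, l0 = 1, d = 0.4)
  st <- spring_mass_state(x = 0.6, y = 0.8, x_dot = 0.6, y_dot = 0.4)
  expect_equal(sqrt(st$x^2 + st$y^2), 1)  # at rest length, moving outward
  arc <- integrate_double_stance(st, p, max_time = 1)
  expect_identical(arc$toe_off_time, st$t)
})

test_that("the dynamics is mirror symmetric in the two legs", {
  p <- spring_params(M = 2, k = 300, l0 = 1, d = 0.5)
  st <- spring_mass_state(x = 0.1, y = 0.9, x_dot = 0.7, y_dot = -0.2)
  mr <- spring_mass_state(x = p$d - st$x, y = st$y, x_dot = -st$x_dot,
                          y_dot = st$y_dot)
  dv <- double_stance_derivatives(st, p)
  dm <- double_stance_derivatives(mr, p)
  expect_equal(dm$x_ddot, -dv$x_ddot, tolerance = 1e-12)
  expect_equal(dm$y_ddot, dv$y_ddot, tolerance = 1e-12)
})

test_that("asymmetric stiffness produces asymmetric leg forces", {
  p <- spring_params(M = 1, k = 300, l0 = 1, d = 0.5,
                     k_left = 200, k_right = 400)
  st <- spring_mass_state(x = p$d / 2, y = 0.9)
  cf <- leg_force_coefficients(st, p)
  expect_gt(cf[["lr"]], cf[["ll"]])
  expect_equal(cf[["lr"]] / cf[["ll"]], 2, tolerance = 1e-12)
})

test_that("a CoG on a contact point is rejected", {
  p <- spring_params(d = 0.5)
  expect_error(gaitfuse:::coefs_at(0, 0, p), "coincides")
})

test_that("double-stance arcs export the documented CSV schema", {
  p <- spring_params(M = 1, k = 150, l0 = 1, d = 0.3)
  st <- spring_mass_state(x = 0.15, y = 0.96, x_dot = 0.5, y_dot = -0.3)
  arc <- integrate_double_stance(st, p, max_time = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spring_csv(arc, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("t", "x", "y", "x_dot", "y_dot", "ll", "lr"))
})
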