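test_that("gait-class presets carry the published model parameters", {
  p <- preset_params("crouch")
  expect_equal(c(p$k_left, p$d, p$l0), c(400, 0.65, 0.95))
  p <- preset_params("parkinson")
  expect_equal(c(p$k_left, p$d, p$l0), c(500, 0.58, 1))
  p2 <- preset_params("parkinson_stage2")
  expect_equal(c(p2$k_left, p2$d), c(52.3, 0.76105))
  p4 <- preset_params("parkinson_stage4")
  expect_equal(c(p4$k_left, p4$d), c(96.8, 0.4356))
  expect_lt(p4$d, p2$d)
  expect_error(preset_params("sprint"))
  # a custom stage table overrides the built-in one
  tab <- parkinson_stage_table()
  tab$k[1] <- 60
  expect_equal(preset_params("parkinson_stage2", stage_table = tab)$k_left, 60)
})

test_that("the heel-strike hand-off preserves CoG position and velocity", {
  p <- preset_params("normal")
  arc <- integrate_single_stance(p$state0, as_pendulum_params(p),
                                 max_time = 3)
  es <- arc$event_state
  ss <- handoff_pendulum_to_spring(es, p)
  expect_equal(c(ss$x, ss$y),
               p$l0 * c(sin(es$theta), cos(es$theta)), tolerance = 1e-14)
  expect_equal(c(ss$x_dot, ss$y_dot),
               p$l0 * es$theta_dot * c(cos(es$theta), -sin(es$theta)),
               tolerance = 1e-14)
})

test_that("an inconsistent foot separation warns and projects", {
  p <- gait_params(d = 0.9, k = 100)
  st <- pendulum_state(theta = 0.1, phi = 0.2, theta_dot = 1)
  expect_warning(ss <- handoff_pendulum_to_spring(st, p), "incompatible")
  expect_equal(ss$x, p$l0 * sin(0.1))  # projected onto the configured frame
})

test_that("the two hand-offs are algebraic inverses on the event surface", {
  p <- gait_params(d = 2 * sin(0.22), k = 150)
  st <- pendulum_state(theta = 0.22, phi = 0.44, theta_dot = 0.9,
                       phi_dot = 0.9 * (1 - cos(2 * 0.22)))
  # phi_dot chosen so the swing foot is momentarily at rest (gentle
  # landing), the configuration the planted-foot convention inverts
  ss <- handoff_pendulum_to_spring(st, p)
  back <- handoff_spring_to_pendulum(ss, p, new_stance = "trailing",
                                     pivot = "leg")
  expect_equal(back$theta, st$theta, tolerance = 1e-12)
  expect_equal(back$phi, st$phi, tolerance = 1e-12)
  expect_equal(back$theta_dot, st$theta_dot, tolerance = 1e-12)
  # spring -> pendulum -> spring closes exactly for on-sphere states
  ss2 <- handoff_pendulum_to_spring(back, p)
  expect_equal(c(ss2$x, ss2$y, ss2$x_dot, ss2$y_dot),
               c(ss$x, ss$y, ss$x_dot, ss$y_dot), tolerance = 1e-12)
})

test_that("zero cycles give an empty trajectory with no events", {
  traj <- simulate_gait(preset_params("normal"), n_cycles = 0)
  expect_identical(nrow(traj$samples), 0L)
  expect_identical(nrow(traj$events), 0L)
})

test_that("phases alternate and events bracket them exactly", {
  traj <- cached_traj("normal", 3)
  ev <- traj$events
  expect_true(all(diff(ev$t) > 0))
  expect_identical(unique(ev$event[c(TRUE, FALSE)]), "heel_strike")
  expect_identical(unique(ev$event[c(FALSE, TRUE)]), "toe_off")
  # feet alternate between consecutive heel strikes
  hs_feet <- ev$foot[ev$event == "heel_strike"]
  expect_true(all(hs_feet[-1] != hs_feet[-length(hs_feet)]))
  expect_true(all(diff(traj$samples$t) > 0))
  # phase switches happen exactly at event times
  sw <- traj$samples$t[which(diff(traj$samples$phase != "single_stance") != 0)]
  expect_true(all(vapply(sw, function(t) min(abs(ev$t - t)) < 0.0021,
                         logical(1))))
})

test_that("the CoG is continuous across every phase boundary", {
  traj <- cached_traj("normal", 3)
  expect_lt(max(traj$events$jump), 1e-9)
  traj2 <- cached_traj("crouch", 2)
  expect_lt(max(traj2$events$jump), 1e-9)
})

test_that("identical parameters and seed give bit-identical trajectories", {
  a <- simulate_gait(preset_params("crouch"), n_cycles = 1, seed = 7)
  b <- simulate_gait(preset_params("crouch"), n_cycles = 1, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
})

test_that("normal-preset cycles repeat once steady", {
  traj <- cached_traj("normal", 3)
  c1 <- normalize_to_cycle(traj, cycle = 1)
  c2 <- normalize_to_cycle(traj, cycle = 2)
  rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / diff(range(b))
  expect_lt(rel_rms(c1$samples$x - c1$samples$x[1],
                    c2$samples$x - c2$samples$x[1]), 0.01)
  expect_lt(rel_rms(c1$samples$y, c2$samples$y), 0.01)
})

test_that("simulated stride length decreases across Parkinson stages", {
  strides <- vapply(paste0("parkinson_stage", 2:4), function(cls) {
    traj <- cached_traj(cls, 1)
    2 * traj$step_length
  }, numeric(1))
  expect_true(all(diff(strides) < 0))
})

test_that("non-walking parameters fail with a phase-specific error", {
  p <- gait_params(k = 104, d = 0.17,
                   state0 = pendulum_state(theta = -0.26, phi = -0.52,
                                           theta_dot = 0.1, phi_dot = 0.1))
  expect_error(simulate_gait(p, n_cycles = 1, phase_cap = 2),
               "non-walking parameters.*single stance")
})

test_that("cycle normalization resamples onto the percent grid", {
  traj <- cached_traj("normal", 3)
  cyc <- normalize_to_cycle(traj)
  expect_identical(nrow(cyc$samples), 101L)
  expect_equal(cyc$samples$percent, seq(0, 100, length.out = 101))
  expect_identical(cyc$cycle, 2L)  # transient first cycle skipped
  expect_setequal(unique(cyc$samples$phase),
                  c("single_stance", "double_stance"))
  # a uniform input grid is reproduced identically
  df <- tibble::tibble(percent = seq(0, 100, length.out = 101),
                       x = rnorm(101), y = rnorm(101))
  out <- normalize_to_cycle(df, n_points = 101)
  expect_equal(out$samples$x, df$x)
  expect_equal(out$samples$y, df$y)
  # an irregularly sampled sine is recovered to 1e-3
  set.seed(3)
  pct <- sort(c(0, 100, runif(800, 0, 100)))
  df2 <- tibble::tibble(percent = pct, x = sin(2 * pi * pct / 100),
                        y = cos(2 * pi * pct / 100))
  out2 <- normalize_to_cycle(df2, n_points = 101)
  g <- out2$samples$percent
  expect_lt(max(abs(out2$samples$x - sin(2 * pi * g / 100))), 1e-3)
})

test_that("cycle timing reports the phase structure", {
  traj <- cached_traj("normal", 3)
  tm <- cycle_timing(traj, cycle = 2)
  expect_equal(tm$contralateral_heel_strike, 50, tolerance = 0.02)
  expect_equal(nrow(tm$events), 4L)
})

test_that("gait configuration JSON round-trips field for field", {
  p <- preset_params("parkinson_stage3")
  path <- withr::local_tempfile(fileext = ".json")
  write_gait_config(p, path)
  q <- read_gait_config(path)
  expect_identical(q$gait_class, p$gait_class)
  for (f in c("M", "m", "beta", "l0", "k_left", "k_right",
              "d", "g", "slope")) {
    expect_equal(q[[f]], p[[f]], label = f, tolerance = 1e-12)
  }
  expect_equal(unclass(q$state0), unclass(p$state0), tolerance = 1e-12)
})

test_that("tidy and glance summarize a trajectory", {
  traj <- cached_traj("normal", 3)
  td <- tidy(traj)
  expect_true(all(c("t", "x", "y", "phase", "cycle") %in% names(td)))
  g <- glance(traj)
  expect_identical(g$n_cycles, 3L)
  expect_equal(g$ds_fraction, 20, tolerance = 0.5)
})
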