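test_that("knee angle worked values are exact", {
  expect_equal(knee_angle(c(0, 1), c(0, 0), l0 = 1), 0)
  expect_equal(knee_angle(c(0, 0), c(1 / sqrt(2), 0), l0 = 1), pi / 2)
  # c = 0.8: verify by constructing explicit knee coordinates satisfying
  # both half-leg segment lengths and measuring the interior angle
  g <- knee_angle(c(0, 0), c(0.8, 0), l0 = 1)
  expect_equal(g, acos(0.28), tolerance = 1e-15)
  h <- sqrt(0.25 - 0.16)              # knee height over the chord
  knee <- c(0.4, h)
  v1 <- c(0, 0) - knee; v2 <- c(0.8, 0) - knee
  interior <- acos(sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
  expect_equal(g, pi - interior, tolerance = 1e-12)
})

test_that("hip angle reduces to the target bearing for a straight leg", {
  expect_equal(hip_angle(c(0, 1), c(0, 0), gamma = 0, l0 = 1), 0)
  hip <- c(0.3, 1.2); heel <- c(0.8, 0.4)
  expect_equal(hip_angle(hip, heel, gamma = 0, l0 = 1),
               atan2(0.5, 0.8))
})

test_that("forward kinematics places segments of length l0/2", {
  fk <- forward_kinematics(c(0, 1), omega = 0, gamma = 0, l0 = 1)
  expect_equal(fk$heel, c(0, 0))
  set.seed(5)
  for (i in 1:20) {
    hip <- runif(2); om <- runif(1, -pi, pi); ga <- runif(1, 0, pi)
    fk <- forward_kinematics(hip, om, ga, l0 = 0.9)
    expect_equal(sqrt(sum((fk$knee - hip)^2)), 0.45, tolerance = 1e-12)
    expect_equal(sqrt(sum((fk$heel - fk$knee)^2)), 0.45, tolerance = 1e-12)
  }
})

test_that("inverse then forward kinematics is the identity when reachable", {
  set.seed(8)
  worst <- 0
  for (i in 1:1000) {
    hip <- c(runif(1, -1, 1), runif(1, 0, 2))
    ang <- runif(2) * c(2 * pi, pi) - c(pi, 0)   # omega free, gamma in [0, pi]
    heel <- forward_kinematics(hip, ang[1], ang[2], l0 = 1)$heel
    s <- solve_leg_ik(hip, heel, l0 = 1)
    expect_false(s$clamped)
    back <- forward_kinematics(hip, s$omega, s$gamma, l0 = 1)$heel
    worst <- max(worst, sqrt(sum((back - heel)^2)))
  }
  expect_lt(worst, 1e-12)
})

test_that("unreachable targets are clamped onto the reach sphere", {
  s <- solve_leg_ik(c(0, 1), c(0, -0.5), l0 = 1)
  expect_true(s$clamped)
  expect_equal(s$gamma, 0)
  heel <- forward_kinematics(c(0, 1), s$omega, s$gamma, 1)$heel
  expect_equal(heel, c(0, 0))  # on the sphere, toward the target
})

test_that("CCD started at the analytic solution does not move", {
  hip <- c(0, 1); target <- c(0.25, 0.25)
  s <- solve_leg_ik(hip, target, l0 = 1)
  cc <- ccd_solve(hip, target, l0 = 1, init = c(s$omega, s$gamma))
  expect_identical(cc$iterations, 0L)
})

test_that("CCD error is non-increasing and matches the analytic heel", {
  set.seed(12)
  done <- 0
  while (done < 40) {
    hip <- c(runif(1, -0.5, 0.5), runif(1, 0.8, 1.2))
    ang <- c(runif(1, -1.2, 1.2), runif(1, 0.1, 2.0))
    target <- forward_kinematics(hip, ang[1], ang[2], l0 = 1)$heel
    if (target[2] >= hip[2]) next   # gait-like: heel below the hip
    done <- done + 1
    cc <- ccd_solve(hip, target, l0 = 1, tol = 1e-8)
    if (cc$nudges == 0L) {
      expect_true(all(diff(cc$error_trace) <= 1e-12))
    }
    s <- solve_leg_ik(hip, target, l0 = 1)
    heel_ccd <- forward_kinematics(hip, cc$omega, cc$gamma, 1)$heel
    heel_ana <- forward_kinematics(hip, s$omega, s$gamma, 1)$heel
    expect_lt(sqrt(sum((heel_ccd - heel_ana)^2)), 1e-6)
  }
})

test_that("CCD reports non-convergence with the final residual", {
  expect_error(ccd_solve(c(0, 1), c(0.3, 0.2), l0 = 1, max_iter = 2,
                         init = c(0, 0.01)),
               "did not converge")
})

test_that("fusing straight-leg synthetic inputs gives zero knee flexion", {
  pct <- seq(0, 100, length.out = 101)
  cog <- normalize_to_cycle(tibble::tibble(percent = pct, x = 0, y = 1))
  cog$step_length <- 0  # heel pinned under the hip
  mk <- structure(list(
    gait_class = "custom", I = 1,
    components = dplyr::bind_rows(
      tibble::tibble(coord = "x", component = 1L, weight = 0, mean = 50,
                     variance = 100),
      tibble::tibble(coord = "y", component = 1L, weight = 0, mean = 50,
                     variance = 100)),
    intercept = c(x = 0, y = 0), residual = c(x = 0, y = 0),
    sigma = NA_real_, refined = FALSE), class = "heel_mixture")
  ang <- fuse_trajectories(cog, mk, l0 = 1, step_length = 1e-9,
                           hip_offset = 0, max_unreachable = 1.01)
  # heel at the origin, hip at (0, 1): always exactly at full extension
  expect_true(all(abs(ang$angles$knee_R) < 1e-9))
  expect_true(all(abs(ang$angles$knee_L) < 1e-9))
  expect_identical(nrow(ang$angles), length(pct))
})

test_that("symmetric inputs give left angles as right angles shifted 50%", {
  traj <- cached_traj("normal", 3)
  cyc <- normalize_to_cycle(traj)
  mix <- fit_heel_mixture(generate_synthetic_heel_data("normal", seed = 2))
  ang <- fuse_trajectories(cyc, mix)$angles
  # the simulated steady cycle is two near-identical steps, so the left
  # series should match the right shifted by half a cycle
  shift <- function(v) c(v[51:100], v[1:51])[1:101]
  expect_lt(max(abs(ang$hip_L - shift(ang$hip_R))), 0.06)
  expect_lt(max(abs(ang$knee_L - shift(ang$knee_R))), 0.06)
})

test_that("crouch fusion keeps the knee flexed through the whole cycle", {
  traj <- cached_traj("crouch", 2)
  cyc <- normalize_to_cycle(traj)
  mix <- fit_heel_mixture(generate_synthetic_heel_data("crouch", seed = 2))
  ang <- fuse_trajectories(cyc, mix)
  expect_equal(ang$clamped_fraction, 0)
  expect_gt(min(ang$angles$knee_R), 0.1)
  expect_gt(min(ang$angles$knee_L), 0.1)
})

test_that("joint angles export in clinical degrees and read back", {
  traj <- cached_traj("normal", 3)
  mix <- fit_heel_mixture(generate_synthetic_heel_data("normal", seed = 2))
  ang <- fuse_trajectories(normalize_to_cycle(traj), mix)
  path <- withr::local_tempfile(fileext = ".csv")
  write_joint_angles_csv(ang, path)
  back <- read_joint_angles_csv(path)
  expect_equal(back$angles$knee_R, ang$angles$knee_R, tolerance = 1e-9)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(raw, c("percent", "hip_R_deg", "knee_R_deg", "hip_L_deg",
                      "knee_L_deg"))
  expect_equal(raw$knee_R_deg, ang$angles$knee_R * 180 / pi,
               tolerance = 1e-9)
})
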