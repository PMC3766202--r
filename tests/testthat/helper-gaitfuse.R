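# shared fixtures and independent oracles -----------------------------------

# cached simulations so several test files can reuse one run
.traj_cache <- new.env(parent = emptyenv())
cached_traj <- function(gait_class, n_cycles) {
  key <- paste(gait_class, n_cycles, sep = "_")
  if (is.null(.traj_cache[[key]])) {
    .traj_cache[[key]] <- simulate_gait(preset_params(gait_class),
                                        n_cycles = n_cycles, seed = 1)
  }
  .traj_cache[[key]]
}

# brute-force discrete Frechet distance: exhaustive minimisation over all
# monotone couplings (start at (1,1), end at (n,m), steps +1 in either or
# both indices); independent of the dynamic program under test
frechet_bruteforce <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P); m <- nrow(Q)
  d <- function(i, j) sqrt(sum((P[i, ] - Q[j, ])^2))
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == n && j == m) return(here)
    nxt <- Inf
    if (i < n) nxt <- min(nxt, rec(i + 1, j))
    if (j < m) nxt <- min(nxt, rec(i, j + 1))
    if (i < n && j < m) nxt <- min(nxt, rec(i + 1, j + 1))
    max(here, nxt)
  }
  rec(1, 1)
}

# vector-form double-stance oracle: per-leg spring force k (l0 - l) along
# the leg unit vector, summed, minus gravity
spring_oracle_accel <- function(x, y, x_dot, y_dot, params) {
  force_leg <- function(contact, k) {
    leg <- c(x, y) - contact
    len <- sqrt(sum(leg^2))
    k * (params$l0 - len) * leg / len
  }
  f <- force_leg(c(0, 0), params$k_left) +
    force_leg(c(params$d, 0), params$k_right) +
    c(0, -params$g * params$M)
  f / params$M
}

# frozen accelerations and energies from an independent symbolic assembly
# of the compass-pendulum Euler-Lagrange equations (computer algebra,
# 20 significant digits); columns: theta, phi, theta_dot, phi_dot, beta,
# l0, g, slope, theta_ddot, phi_ddot, energy
compass_oracle_cases <- function() {
  m <- rbind(
    c(0.2, 0.5, -0.3, 0.1, 0.01, 1, 9.81, 0,
      1.9896923161035498364, -2.6123318929095557298, 9.6620760512513162697),
    c(0.1, 0.35, 0.4, -0.6, 0.01, 1, 9.81, 0.009,
      1.1014585276761733137, -2.2197483316270668066, 9.8360768043417103845),
    c(-0.25, -0.45, 1.2, 2, 0.05, 0.95, 9.81, 0,
      -2.7347236684799564302, 1.1529222128911429130, 9.7603191247033170883),
    c(0.3, 0.2, -1, 0.5, 0.2, 1.2, 9.81, 0.05,
      3.1499603947992651706, 1.4831155540996377514, 11.706603303247179355),
    c(0.05, -0.3, 0.7, -1.1, 0.01, 1, 3.71, 0,
      0.16678648482770555429, 1.1347952343744722692, 3.9591791333163575626))
  colnames(m) <- c("theta", "phi", "theta_dot", "phi_dot", "beta", "l0",
                   "g", "slope", "theta_ddot", "phi_ddot", "energy")
  m
}

state_from_row <- function(r) {
  pendulum_state(theta = r[["theta"]], phi = r[["phi"]],
                 theta_dot = r[["theta_dot"]], phi_dot = r[["phi_dot"]])
}

params_from_row <- function(r) {
  pendulum_params(beta = r[["beta"]], l0 = r[["l0"]], g = r[["g"]],
                  slope = r[["slope"]])
}

last_state <- function(arc) {
  tr <- arc$trajectory
  n <- nrow(tr)
  pendulum_state(theta = tr$theta[n], phi = tr$phi[n],
                 theta_dot = tr$theta_dot[n], phi_dot = tr$phi_dot[n],
                 t = tr$t[n])
}
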