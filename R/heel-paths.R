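#' Synthetic per-cycle heel trajectories
#'
#' Generates a corpus of heel paths emulating gait-laboratory recordings:
#' per cycle, 101 samples of the sagittal heel position in a lab frame
#' where the cycle-opening heel strike is at the origin.  The heel stays
#' planted through stance (0--60% of the cycle), rises in late stance,
#' swings forward with a clearance arc and lands one stride (`2 d`) ahead.
#' Class-specific distortions: crouch gait gets reduced clearance and a
#' persistent forward offset (flexed posture); Parkinsonian classes
#' inherit their short step length from the preset `d` and get a reduced,
#' shuffling clearance.  Smooth cycle-level noise (half-sine harmonics,
#' which vanish at both cycle ends, so the per-cycle displacement is
#' exactly the stride) and subject-level offsets are added on top.
#'
#' @param gait_class Gait class of the corpus.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_cycles Total number of cycles, distributed round-robin over
#'   subjects (default 30 cycles over 10 subjects).
#' @param seed Integer seed; the corpus is deterministic in it.
#' @param params A [gait_params()]; defaults to `preset_params(gait_class)`.
#' @param noise_sd Amplitude (m) of the smooth cycle-level noise.
#' @return A tibble of class `heel_cycles` with columns `subject`,
#'   `cycle`, `percent`, `heel_x`, `heel_y` and attribute `gait_class`.
#' @examples
#' hc <- generate_synthetic_heel_data("normal", seed = 1)
#' dplyr::n_distinct(hc$cycle)
#' @export
generate_synthetic_heel_data <- function(gait_class = "normal",
                                         n_subjects = 10, n_cycles = 30,
                                         seed = 1,
                                         params = preset_params(gait_class),
                                         noise_sd = 0.004) {
  stopifnot(n_subjects >= 1, n_cycles >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  shape <- heel_shape_params(gait_class)
  grid <- 0:100
  subj_of <- rep_len(seq_len(n_subjects), n_cycles)
  subj_x_off <- stats::rnorm(n_subjects, 0, 0.01)
  subj_clear <- exp(stats::rnorm(n_subjects, 0, 0.10))

  one_cycle <- function(ci) {
    s <- subj_of[ci]
    base <- heel_template(grid, d = params$d,
                          clearance = shape$clearance * subj_clear[s],
                          heel_rise = shape$heel_rise * subj_clear[s],
                          x_offset = shape$x_offset + subj_x_off[s])
    nx <- smooth_half_sine_noise(grid, noise_sd)
    ny <- smooth_half_sine_noise(grid, noise_sd / 2)
    tibble::tibble(subject = s, cycle = ci, percent = grid,
                   heel_x = base$x + nx, heel_y = base$y + ny)
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_cycles), one_cycle))
  attr(out, "gait_class") <- gait_class
  class(out) <- c("heel_cycles", class(out))
  out
}

heel_shape_params <- function(gait_class) {
  switch(gait_class,
         crouch = list(clearance = 0.05, heel_rise = 0.10, x_offset = 0.05),
         parkinson = ,
         parkinson_stage2 = ,
         parkinson_stage3 = ,
         parkinson_stage4 = list(clearance = 0.06, heel_rise = 0.10,
                                 x_offset = 0),
         list(clearance = 0.10, heel_rise = 0.15, x_offset = 0))
}

# C2 quintic smoothstep on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# deterministic-looking heel template; stance 0-60%, swing 60-100%
heel_template <- function(percent, d, clearance, heel_rise, x_offset = 0) {
  u_sw <- (percent - 60) / 40
  x <- x_offset + 2 * d * smoothstep(u_sw)
  rise <- heel_rise * smoothstep((percent - 40) / 20)
  y <- ifelse(percent < 60, rise,
              heel_rise * (1 - smoothstep(u_sw)) +
                clearance * sin(pi * pmin(pmax(u_sw, 0), 1)))
  list(x = x, y = y)
}

# noise that vanishes at 0 and 100% so stride displacement is preserved
smooth_half_sine_noise <- function(percent, sd) {
  a <- stats::rnorm(3, 0, sd / (1:3))
  a[1] * sin(pi * percent / 100) +
    a[2] * sin(2 * pi * percent / 100) +
    a[3] * sin(3 * pi * percent / 100)
}

#' Mean step length of a heel-cycle corpus
#'
#' Half the mean per-cycle forward displacement of the heel (one cycle
#' covers two steps).
#'
#' @param data A `heel_cycles` tibble.
#' @return Step length (m).
#' @export
heel_step_length <- function(data) {
  per_cycle <- dplyr::summarise(
    dplyr::group_by(data, .data$subject, .data$cycle),
    disp = .data$heel_x[which.max(.data$percent)] -
      .data$heel_x[which.min(.data$percent)],
    .groups = "drop")
  mean(per_cycle$disp) / 2
}

#' Fit a Gaussian-basis heel-path mixture
#'
#' Represents the per-percent mean heel trajectory of a corpus as a
#' weighted sum of Gaussian densities over the normalized cycle,
#' \deqn{\psi(t) = \sum_{i=1}^{I} w_i \, N(t \mid \mu_i, \sigma_i^2),}
#' one such mixture per coordinate, plus a constant intercept.  Weights
#' are signed basis coefficients (the mixture models a coordinate
#' trajectory, not a density).  By default the means sit on a uniform
#' grid over \[0, 100\] with a shared width set by the grid spacing and the
#' weights come from linear least squares; `refine = TRUE` additionally
#' optimizes means and widths per component with Levenberg-Marquardt.
#'
#' @param data A `heel_cycles` tibble (columns `subject`, `cycle`,
#'   `percent`, `heel_x`, `heel_y`).
#' @param I Number of Gaussian components (>= 1).
#' @param sigma Shared basis width in % cycle; default `100 / (I - 1)`
#'   (or 25 when `I = 1`).
#' @param refine Nonlinearly refine means and widths after the linear fit.
#' @param cond_max Conditioning bound for the basis matrix.
#' @return An object of class `heel_mixture` with a component table
#'   (`coord`, `component`, `weight`, `mean`, `variance`), per-coordinate
#'   intercepts and root-mean-square fit residuals.
#' @examples
#' hc <- generate_synthetic_heel_data("normal", seed = 1)
#' mix <- fit_heel_mixture(hc, I = 12)
#' glance(mix)
#' @export
fit_heel_mixture <- function(data, I = 12, sigma = NULL, refine = FALSE,
                             cond_max = 1e10) {
  stopifnot(I >= 1, is.data.frame(data))
  gait_class <- attr(data, "gait_class") %||% "custom"
  mean_traj <- dplyr::summarise(
    dplyr::group_by(data, .data$percent),
    x = mean(.data$heel_x), y = mean(.data$heel_y), .groups = "drop")
  mean_traj <- dplyr::arrange(mean_traj, .data$percent)
  p <- mean_traj$percent
  if (is.null(sigma)) sigma <- if (I > 1) 100 / (I - 1) else 25
  mu <- if (I > 1) seq(0, 100, length.out = I) else 50

  basis <- vapply(mu, function(m) stats::dnorm(p, m, sigma), numeric(length(p)))
  X <- cbind(1, basis)
  if (kappa(X, exact = TRUE) > cond_max) {
    stop("ill-conditioned Gaussian basis (sigma too small or components ",
         "too overlapping)", call. = FALSE)
  }

  fit_coord <- function(yv) {
    fit <- stats::lm.fit(X, yv)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    w <- cf[-1]; c0 <- cf[1]
    mu_i <- mu; s2_i <- rep(sigma^2, I)
    if (refine) {
      dat <- data.frame(p = p, yv = yv)
      start <- c(c0 = unname(c0),
                 stats::setNames(unname(w), paste0("w", seq_len(I))),
                 stats::setNames(unname(mu_i), paste0("m", seq_len(I))),
                 stats::setNames(unname(sqrt(s2_i)), paste0("s", seq_len(I))))
      form <- paste0("yv ~ c0 + ",
                     paste(sprintf("w%d * dnorm(p, m%d, s%d)",
                                   seq_len(I), seq_len(I), seq_len(I)),
                           collapse = " + "))
      nl <- try(minpack.lm::nlsLM(
        stats::as.formula(form), data = dat, start = as.list(start),
        lower = c(rep(-Inf, 1 + 2 * I), rep(1e-3, I)),
        control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
      if (!inherits(nl, "try-error")) {
        cf <- stats::coef(nl)
        c0 <- cf[["c0"]]
        w <- cf[paste0("w", seq_len(I))]
        mu_i <- cf[paste0("m", seq_len(I))]
        s2_i <- cf[paste0("s", seq_len(I))]^2
      }
    }
    B <- vapply(seq_len(I),
                function(i) w[i] * stats::dnorm(p, mu_i[i], sqrt(s2_i[i])),
                numeric(length(p)))
    pred <- c0 + rowSums(matrix(B, nrow = length(p)))
    list(w = unname(w), mu = unname(mu_i), s2 = unname(s2_i),
         intercept = unname(c0),
         rmse = sqrt(mean((yv - pred)^2)))
  }

  fx <- fit_coord(mean_traj$x)
  fy <- fit_coord(mean_traj$y)
  comp <- dplyr::bind_rows(
    tibble::tibble(coord = "x", component = seq_len(I), weight = fx$w,
                   mean = fx$mu, variance = fx$s2),
    tibble::tibble(coord = "y", component = seq_len(I), weight = fy$w,
                   mean = fy$mu, variance = fy$s2))
  if (any(comp$variance <= 0)) {
    stop("non-positive component variance in fitted mixture", call. = FALSE)
  }
  structure(list(gait_class = gait_class, I = as.integer(I),
                 components = comp,
                 intercept = c(x = fx$intercept, y = fy$intercept),
                 residual = c(x = fx$rmse, y = fy$rmse),
                 sigma = sigma, refined = refine),
            class = "heel_mixture")
}

#' @export
print.heel_mixture <- function(x, ...) {
  cat(sprintf(
    "<heel_mixture %s: I=%d, rmse x=%.2e y=%.2e%s>\n",
    x$gait_class, x$I, x$residual[["x"]], x$residual[["y"]],
    if (x$refined) ", refined" else ""))
  invisible(x)
}

#' Evaluate a heel-path mixture on the percent grid
#'
#' @param mix A `heel_mixture`.
#' @param percent Positions in \[0, 100\].
#' @return A tibble with columns `percent`, `x`, `y` (m).
#' @examples
#' hc <- generate_synthetic_heel_data("normal", seed = 1)
#' mix <- fit_heel_mixture(hc, I = 12)
#' evaluate_heel_path(mix, c(0, 25, 50, 75, 100))
#' @export
evaluate_heel_path <- function(mix, percent) {
  stopifnot(inherits(mix, "heel_mixture"))
  stopifnot(all(percent >= 0 & percent <= 100))
  eval_coord <- function(coord) {
    cc <- mix$components[mix$components$coord == coord, , drop = FALSE]
    mix$intercept[[coord]] + Reduce(`+`, lapply(seq_len(nrow(cc)), function(i) {
      cc$weight[i] * stats::dnorm(percent, cc$mean[i], sqrt(cc$variance[i]))
    }), accumulate = FALSE, init = 0)
  }
  tibble::tibble(percent = percent, x = eval_coord("x"), y = eval_coord("y"))
}

#' Sample a deterministic heel-path variant
#'
#' Perturbs the mixture weights by a relative Gaussian factor (sd
#' `scale`), giving a plausible within-class gait variant; `scale = 0`
#' reproduces the mean path exactly and identical seeds give identical
#' samples.
#'
#' @param mix A `heel_mixture`.
#' @param seed Integer seed.
#' @param scale Relative standard deviation of the weight perturbation
#'   (>= 0).
#' @param percent Evaluation grid.
#' @return A tibble with columns `percent`, `x`, `y`.
#' @export
sample_heel_variation <- function(mix, seed = 1, scale = 0.05,
                                  percent = 0:100) {
  stopifnot(inherits(mix, "heel_mixture"), scale >= 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pert <- mix
  n <- nrow(pert$components)
  pert$components$weight <- pert$components$weight *
    (1 + scale * stats::rnorm(n))
  evaluate_heel_path(pert, percent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
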