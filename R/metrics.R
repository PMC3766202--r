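#' Pearson correlation between two trajectories
#'
#' Plain product-moment correlation on equal-length series, the first of
#' the two similarity measures used to score simulated against reference
#' gait curves.
#'
#' @param a,b Numeric vectors of equal length (>= 3) with nonzero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @examples
#' correlation_coefficient(c(1, 2, 3, 4), c(2, 4, 5, 4))
#' @export
correlation_coefficient <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance input to correlation_coefficient", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Discrete Fréchet distance
#'
#' The minimal, over all monotone couplings of the two point sequences,
#' of the maximal coupled point-pair distance (the "dog-leash" distance),
#' computed by the standard dynamic program over the coupling lattice
#' with Euclidean ground metric.  Unlike the Hausdorff distance it
#' respects the direction of travel along the curves: two curves can be
#' close as point sets yet far in the Fréchet sense if one backtracks.
#'
#' @param P,Q Matrices (or data frames) with one point per row; a numeric
#'   vector is taken as a 1-D curve.
#' @return The discrete Fréchet distance (curve units).
#' @examples
#' frechet_distance(cbind(c(0, 1), c(0, 0)), cbind(c(0, 1), c(0.5, 0.5)))
#' @export
frechet_distance <- function(P, Q) {
  P <- as_curve(P); Q <- as_curve(Q)
  n <- nrow(P); m <- nrow(Q)
  if (n == 0 || m == 0) stop("empty curve", call. = FALSE)
  D <- pair_dists(P, Q)
  ca <- matrix(0, n, m)
  ca[1, 1] <- D[1, 1]
  for (i in seq_len(n)[-1]) ca[i, 1] <- max(ca[i - 1, 1], D[i, 1])
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], D[1, j])
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                        D[i, j])
      }
    }
  }
  ca[n, m]
}

as_curve <- function(P) {
  if (is.data.frame(P)) P <- as.matrix(P)
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  storage.mode(P) <- "double"
  P
}

pair_dists <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  D <- matrix(0, n, m)
  for (k in seq_len(ncol(P))) {
    D <- D + outer(P[, k], Q[, k], `-`)^2
  }
  sqrt(D)
}

#' Hausdorff distance between two point sets
#'
#' Maximum of the two directed nearest-point maxima; never exceeds the
#' discrete Fréchet distance on the same sequences.  Computed from the
#' same exact pairwise Euclidean distances as [frechet_distance()], so
#' the `frechet >= hausdorff` ordering holds to machine precision.
#'
#' @inheritParams frechet_distance
#' @return The Hausdorff distance.
#' @export
hausdorff_distance <- function(P, Q) {
  P <- as_curve(P); Q <- as_curve(Q)
  if (nrow(P) == 0 || nrow(Q) == 0) stop("empty input", call. = FALSE)
  D <- pair_dists(P, Q)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

#' Compare simulated and reference gait trajectories
#'
#' Scores each joint-angle channel (R.Hip, R.Knee, L.Hip, L.Knee) and
#' optionally the planar CoG curve with the Pearson correlation and the
#' discrete Fréchet distance (plus the Hausdorff distance for contrast).
#' Angle channels are compared as angle-vs-percent curves embedded in 2D,
#' with the percent axis rescaled to the channel's value range
#' (`mode = "scaled_2d"`), or as plain value sequences
#' (`mode = "values_1d"`).  The CoG correlation is the mean of the per
#' coordinate correlations; its Fréchet distance is taken on the planar
#' curve.
#'
#' @param sim,ref `joint_angles` objects (or their `angles` tibbles) on a
#'   common percent grid.
#' @param sim_cog,ref_cog Optional `gait_cycle` objects (or tibbles with
#'   `x`, `y`) for the CoG channel.
#' @param mode Embedding used for the Fréchet distance on angle channels.
#' @return A tibble of class `gait_comparison` with columns `channel`,
#'   `correlation`, `frechet`, `hausdorff`.
#' @export
compare_trajectories <- function(sim, ref, sim_cog = NULL, ref_cog = NULL,
                                 mode = c("scaled_2d", "values_1d")) {
  mode <- match.arg(mode)
  ang <- function(x) {
    if (inherits(x, "joint_angles")) x$angles else tibble::as_tibble(x)
  }
  a <- ang(sim); b <- ang(ref)
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$percent, b$percent))) {
    stop("simulated and reference series are on different grids",
         call. = FALSE)
  }
  chans <- c(R.Hip = "hip_R", R.Knee = "knee_R",
             L.Hip = "hip_L", L.Knee = "knee_L")
  embed <- function(p, v) {
    if (mode == "values_1d") return(matrix(v, ncol = 1))
    rng <- diff(range(v))
    if (rng == 0) rng <- 1
    cbind(p / 100 * rng, v)
  }
  rows <- lapply(names(chans), function(nm) {
    va <- a[[chans[[nm]]]]; vb <- b[[chans[[nm]]]]
    tibble::tibble(
      channel = nm,
      correlation = correlation_coefficient(va, vb),
      frechet = frechet_distance(embed(a$percent, va), embed(b$percent, vb)),
      hausdorff = hausdorff_distance(embed(a$percent, va),
                                     embed(b$percent, vb)))
  })
  if (!is.null(sim_cog) && !is.null(ref_cog)) {
    cg <- function(x) {
      if (inherits(x, "gait_cycle")) x$samples else tibble::as_tibble(x)
    }
    ca <- cg(sim_cog); cb <- cg(ref_cog)
    if (nrow(ca) != nrow(cb)) stop("CoG grids differ", call. = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      channel = "CoG",
      correlation = mean(c(correlation_coefficient(ca$x, cb$x),
                           correlation_coefficient(ca$y, cb$y))),
      frechet = frechet_distance(cbind(ca$x, ca$y), cbind(cb$x, cb$y)),
      hausdorff = hausdorff_distance(cbind(ca$x, ca$y), cbind(cb$x, cb$y)))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gait_comparison", class(out))
  out
}
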