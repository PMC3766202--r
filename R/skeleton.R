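#' Synthetic arm-swing template curves
#'
#' Smooth parametric shoulder and elbow flexion-extension templates used
#' to animate the upper limbs.  These are synthetic fixture curves (no
#' patient data): the arms counter-swing the ipsilateral leg at the
#' stride frequency and the elbow keeps a slightly varying flexion.
#'
#' @param percent Evaluation grid (% cycle).
#' @param shoulder_amp Shoulder swing amplitude (rad).
#' @param elbow_mean,elbow_amp Elbow flexion mean and modulation (rad).
#' @return A tibble with columns `percent`, `shoulder_R`, `elbow_R`,
#'   `shoulder_L`, `elbow_L` (radians, flexion positive forward).
#' @export
arm_swing_template <- function(percent = 0:100, shoulder_amp = 0.30,
                               elbow_mean = 0.40, elbow_amp = 0.10) {
  ph <- 2 * pi * percent / 100
  tibble::tibble(
    percent = percent,
    shoulder_R = shoulder_amp * sin(ph + pi),
    elbow_R = elbow_mean + elbow_amp * sin(ph + pi),
    shoulder_L = shoulder_amp * sin(ph),
    elbow_L = elbow_mean + elbow_amp * sin(ph))
}

# anthropometric segment lengths as fractions of leg length
skeleton_dims <- function(l0) {
  list(pelvis = 0.10 * l0, trunk = 0.50 * l0, upper_arm = 0.35 * l0,
       forearm = 0.30 * l0, foot = 0.15 * l0)
}

#' Build one 12-segment sagittal skeleton pose
#'
#' Places the 12 rigid segments (pelvis, trunk, two thighs, two shanks,
#' two feet, two upper arms, two forearms) for one frame: the lower limbs
#' by forward kinematics from the CoG (hip joint) using the supplied hip
#' and knee angles, the trunk vertically above the pelvis, and the upper
#' limbs from the synthetic [arm_swing_template()] curves.  Connected
#' segments share endpoints exactly and segment lengths are constant
#' across frames.
#'
#' @param cog CoG position, numeric length-2 (m).
#' @param angles Named list or vector with `hip_R`, `knee_R`, `hip_L`,
#'   `knee_L` (radians).
#' @param upper_limb A tibble from [arm_swing_template()].
#' @param percent Cycle position of this frame, used to look up the
#'   upper-limb curves.
#' @param l0 Leg length (m).
#' @return A tibble of class `skeleton_pose` with columns `segment`,
#'   `prox_x`, `prox_y`, `dist_x`, `dist_y` and attribute `percent`.
#' @examples
#' pose <- build_pose(c(0, 1), c(hip_R = 0, knee_R = 0, hip_L = 0,
#'                               knee_L = 0))
#' nrow(pose)
#' @export
build_pose <- function(cog, angles, upper_limb = arm_swing_template(),
                       percent = 0, l0 = 1) {
  stopifnot(length(cog) == 2, all(is.finite(cog)),
            all(c("hip_R", "knee_R", "hip_L", "knee_L") %in% names(angles)))
  angles <- lapply(angles[c("hip_R", "knee_R", "hip_L", "knee_L")],
                   as.numeric)
  if (!all(vapply(angles, is.finite, logical(1)))) {
    stop("non-finite joint angle", call. = FALSE)
  }
  dims <- skeleton_dims(l0)
  look <- function(col) {
    stats::approx(upper_limb$percent, upper_limb[[col]],
                  xout = percent %% 100, rule = 2)$y
  }
  hip <- cog
  lumbar <- hip + c(0, dims$pelvis)
  neck <- lumbar + c(0, dims$trunk)

  leg <- function(side) {
    fk <- forward_kinematics(hip, angles[[paste0("hip_", side)]],
                             angles[[paste0("knee_", side)]], l0)
    toe <- fk$heel + c(dims$foot, 0)
    list(knee = fk$knee, heel = fk$heel, toe = toe)
  }
  arm <- function(side) {
    sh <- look(paste0("shoulder_", side))
    el <- look(paste0("elbow_", side))
    elbow <- neck + dims$upper_arm * c(sin(sh), -cos(sh))
    wrist <- elbow + dims$forearm * c(sin(sh + el), -cos(sh + el))
    list(elbow = elbow, wrist = wrist)
  }
  R <- leg("R"); L <- leg("L"); aR <- arm("R"); aL <- arm("L")

  seg <- function(name, p, q) {
    tibble::tibble(segment = name, prox_x = p[1], prox_y = p[2],
                   dist_x = q[1], dist_y = q[2])
  }
  pose <- dplyr::bind_rows(
    seg("pelvis", hip, lumbar),
    seg("trunk", lumbar, neck),
    seg("thigh_R", hip, R$knee), seg("shank_R", R$knee, R$heel),
    seg("foot_R", R$heel, R$toe),
    seg("thigh_L", hip, L$knee), seg("shank_L", L$knee, L$heel),
    seg("foot_L", L$heel, L$toe),
    seg("upper_arm_R", neck, aR$elbow), seg("forearm_R", aR$elbow, aR$wrist),
    seg("upper_arm_L", neck, aL$elbow), seg("forearm_L", aL$elbow, aL$wrist))
  attr(pose, "percent") <- percent
  class(pose) <- c("skeleton_pose", class(pose))
  pose
}

#' Build a pose sequence from a normalized cycle and joint angles
#'
#' @param cog A `gait_cycle` from [normalize_to_cycle()].
#' @param angles A `joint_angles` object on the same grid.
#' @param upper_limb Upper-limb template curves.
#' @param stride Keep every `stride`-th frame.
#' @return A tibble with columns `frame`, `percent`, `segment`, `prox_x`,
#'   `prox_y`, `dist_x`, `dist_y`.
#' @export
build_pose_series <- function(cog, angles, upper_limb = arm_swing_template(),
                              stride = 1) {
  stopifnot(inherits(cog, "gait_cycle"), inherits(angles, "joint_angles"))
  a <- angles$angles
  stopifnot(nrow(a) == nrow(cog$samples))
  l0 <- angles$l0
  idx <- seq(1, nrow(a), by = stride)
  dplyr::bind_rows(lapply(seq_along(idx), function(k) {
    i <- idx[k]
    pose <- build_pose(c(cog$samples$x[i], cog$samples$y[i]),
                       c(hip_R = a$hip_R[i], knee_R = a$knee_R[i],
                         hip_L = a$hip_L[i], knee_L = a$knee_L[i]),
                       upper_limb = upper_limb,
                       percent = a$percent[i], l0 = l0)
    tibble::tibble(frame = k, percent = a$percent[i],
                   pose[, c("segment", "prox_x", "prox_y",
                            "dist_x", "dist_y")])
  }))
}

#' Export a pose sequence
#'
#' Writes either a long-form CSV (`frame,segment,prox_x,prox_y,dist_x,
#' dist_y`, losslessly round-trippable) or a faceted stick-figure plot
#' (PDF).
#'
#' @param poses A tibble from [build_pose_series()].
#' @param path Output file.
#' @param format `"csv"` or `"pdf"`.
#' @return `path`, invisibly.
#' @export
export_animation <- function(poses, path, format = c("csv", "pdf")) {
  format <- match.arg(format)
  stopifnot(nrow(poses) >= 1)
  if (!dir.exists(dirname(path))) {
    stop("output directory does not exist: ", dirname(path), call. = FALSE)
  }
  if (format == "csv") {
    readr::write_csv(
      poses[, c("frame", "segment", "prox_x", "prox_y", "dist_x", "dist_y")],
      path)
  } else {
    p <- ggplot2::ggplot(poses) +
      ggplot2::geom_segment(ggplot2::aes(x = .data$prox_x, y = .data$prox_y,
                                         xend = .data$dist_x,
                                         yend = .data$dist_y)) +
      ggplot2::facet_wrap(~frame) +
      ggplot2::coord_equal() +
      ggplot2::theme_void()
    ggplot2::ggsave(path, p, device = "pdf",
                    width = 8, height = 8)
  }
  invisible(path)
}

#' Read a pose sequence written by [export_animation()]
#'
#' @param path CSV file.
#' @return A tibble with columns `frame`, `segment`, `prox_x`, `prox_y`,
#'   `dist_x`, `dist_y`.
#' @export
read_animation <- function(path) {
  # base read.csv parses doubles with correctly rounded strtod, so the
  # shortest-roundtrip numbers written by readr come back bit-identical
  df <- utils::read.csv(path, colClasses = c(
    frame = "integer", segment = "character", prox_x = "numeric",
    prox_y = "numeric", dist_x = "numeric", dist_y = "numeric"))
  tibble::as_tibble(df)
}
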