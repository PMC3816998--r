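#' Joint angle time series
#'
#' Anatomical joint angles in degrees, one row per sample, columns ordered
#' (flexion/extension, abduction/adduction, internal/external rotation).
#'
#' @param joint joint identifier.
#' @param angles n x 3 numeric matrix, degrees.
#' @param sample_rate Hz.
#' @param gimbal logical n, samples flagged by the gimbal tie-break.
#' @param valid logical n.
#' @return object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(joint, angles, sample_rate,
                               gimbal = rep(FALSE, nrow(angles)),
                               valid = rep(TRUE, nrow(angles))) {
  stopifnot(is.matrix(angles), ncol(angles) == 3L)
  colnames(angles) <- c("flexion_extension", "abduction_adduction", "rotation")
  structure(list(joint = joint, angles = angles, sample_rate = sample_rate,
                 gimbal = gimbal, valid = valid),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  rng <- apply(x$angles, 2L, range)
  cat(sprintf("Joint angles '%s': %d samples @ %g Hz\n", x$joint,
              nrow(x$angles), x$sample_rate))
  cat(sprintf("  flex/ext [%.1f, %.1f] deg, abd/add [%.1f, %.1f] deg, rotation [%.1f, %.1f] deg\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (any(x$gimbal)) cat("  ", sum(x$gimbal), "gimbal-flagged samples\n")
  invisible(x)
}

## joint definitions over the default chain; the elbow removes the fixed
## 90 deg z-rotation that relabels the shoulder axes into the elbow system.
default_joint_definitions <- function() {
  list(
    humerothoracic = list(proximal = "thorax", distal = "upper_arm", rz90 = FALSE),
    elbow          = list(proximal = "upper_arm", distal = "forearm", rz90 = TRUE),
    wrist          = list(proximal = "forearm", distal = "hand", rz90 = FALSE),
    sternoclavicular = list(proximal = "thorax", distal = "clavicle", rz90 = FALSE))
}

#' Extract anatomical joint angles from segment frames
#'
#' For each joint with both segments available, forms the relative rotation
#' `R = t(basis_proximal) %*% basis_distal` (with the fixed 90° z-rotation
#' factored out at the elbow) and decomposes it in the x-then-y-then-z
#' sequence via [decompose_joint_rotation()], so that
#' `joint_rotation(angles)` reproduces `R`.
#'
#' @param frames named list of `segment_frame` objects
#'   (see [build_segment_frames()] or [forward_kinematics()]).
#' @param joints joint definition list; defaults to the humerothoracic,
#'   elbow and wrist joints of the arm chain (plus sternoclavicular when a
#'   clavicle segment is present).
#' @return named list of [joint_angle_series()].
#' @export
compute_joint_angles <- function(frames, joints = default_joint_definitions()) {
  joints <- Filter(function(j) j$proximal %in% names(frames) &&
                     j$distal %in% names(frames), joints)
  if (!length(joints))
    stop("no joint has both its proximal and distal segment frames available")
  Rz90t <- t(rot_z(90))
  out <- lapply(names(joints), function(jn) {
    j <- joints[[jn]]
    fp <- frames[[j$proximal]]; fd <- frames[[j$distal]]
    n <- dim(fp$basis)[3L]
    ang <- matrix(NA_real_, n, 3L)
    gim <- rep(FALSE, n)
    valid <- fp$valid & fd$valid
    for (t in seq_len(n)) {
      if (!valid[t]) next
      R <- crossprod(fp$basis[, , t], fd$basis[, , t])
      if (j$rz90) R <- Rz90t %*% R
      d <- decompose_joint_rotation(R)
      ang[t, ] <- d$angles
      gim[t] <- d$gimbal
    }
    joint_angle_series(jn, ang, fp$sample_rate, gimbal = gim, valid = valid)
  })
  names(out) <- names(joints)
  out
}

#' Cumulative rotation chain from per-joint angle series
#'
#' Builds, per sample, the per-joint rotations `R*` from the angle series
#' and chains them with [chain_rotations()] into the cumulative shoulder,
#' elbow and wrist joint coordinate systems `R_S`, `R_E`, `R_W`.
#'
#' @param angles named list of [joint_angle_series()] containing
#'   `humerothoracic`, `elbow` and `wrist`.
#' @return list of three `3 x 3 x n` arrays `R_S`, `R_E`, `R_W`.
#' @export
rotation_chain_series <- function(angles) {
  need <- c("humerothoracic", "elbow", "wrist")
  miss <- setdiff(need, names(angles))
  if (length(miss))
    stop("angle series missing joint(s): ", paste(miss, collapse = ", "))
  n <- nrow(angles$humerothoracic$angles)
  R_S <- R_E <- R_W <- array(NA_real_, c(3L, 3L, n))
  for (t in seq_len(n)) {
    a_s <- angles$humerothoracic$angles[t, ]
    a_e <- angles$elbow$angles[t, ]
    a_w <- angles$wrist$angles[t, ]
    if (anyNA(c(a_s, a_e, a_w))) next
    ch <- chain_rotations(joint_rotation(a_s), joint_rotation(a_e),
                          joint_rotation(a_w))
    R_S[, , t] <- ch$R_S; R_E[, , t] <- ch$R_E; R_W[, , t] <- ch$R_W
  }
  list(R_S = R_S, R_E = R_E, R_W = R_W)
}
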