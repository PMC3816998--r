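#' Elementary rotation matrices of the joint coordinate systems
#'
#' `rot_x()`, `rot_y()` and `rot_z()` return the 3x3 rotation matrices about
#' the anatomical x (flexion/extension), y (abduction/adduction) and z (axial
#' rotation) axes.  Angles are in degrees at every public interface.
#'
#' The y-axis matrix follows the source model's sign layout, which places
#' `-sin` in the first row -- the transpose of the common active-rotation
#' convention.  This layout is deliberately preserved (the model's chain and
#' force transforms are self-consistent under it); set
#' `options(armdyn.strict_paper_matrices = FALSE)` to use the common
#' convention instead, e.g. for sensitivity analysis.
#'
#' @param phi angle in degrees.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' rot_x(0)             # identity
#' rot_z(90) %*% c(1, 0, 0)  # maps x onto y
#' @export
rot_x <- function(phi) {
  a <- phi * pi / 180
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s,  c), nrow = 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(phi) {
  a <- phi * pi / 180
  c <- cos(a); s <- sin(a)
  if (isTRUE(getOption("armdyn.strict_paper_matrices", TRUE))) {
    matrix(c( c, 0, -s,
              0, 1,  0,
              s, 0,  c), nrow = 3, byrow = TRUE)
  } else {
    matrix(c( c, 0,  s,
              0, 1,  0,
             -s, 0,  c), nrow = 3, byrow = TRUE)
  }
}

#' @rdname rot_x
#' @export
rot_z <- function(phi) {
  a <- phi * pi / 180
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0,
           s,  c, 0,
           0,  0, 1), nrow = 3, byrow = TRUE)
}

#' Joint rotation matrix from anatomical angles
#'
#' Composes the elementary rotations in the fixed x-then-y-then-z order used
#' throughout the model: `R* = R_x(phi_x) %*% R_y(phi_y) %*% R_z(phi_z)`,
#' with `phi_x` flexion/extension, `phi_y` abduction/adduction and `phi_z`
#' internal/external rotation.
#'
#' @param angles numeric length-3 vector `(phi_x, phi_y, phi_z)` in degrees.
#' @return 3x3 rotation matrix.
#' @export
joint_rotation <- function(angles) {
  stopifnot(length(angles) == 3L, all(is.finite(angles)))
  rot_x(angles[1L]) %*% rot_y(angles[2L]) %*% rot_z(angles[3L])
}

#' Decompose a rotation matrix into anatomical joint angles
#'
#' Inverts [joint_rotation()]: finds `(phi_x, phi_y, phi_z)` in degrees such
#' that `R_x %*% R_y %*% R_z` reproduces `R`.  Near gimbal lock
#' (`|cos(phi_y)| < gimbal_tol`) the x and z rotations are no longer
#' separable; the deterministic tie-break sets `phi_z = 0`, absorbs the
#' coupled rotation into `phi_x`, and flags the sample.
#'
#' @param R 3x3 rotation matrix.
#' @param gimbal_tol tolerance on `|cos(phi_y)|` below which the sample is
#'   treated as gimbal-locked.
#' @return list with `angles` (length-3, degrees, each in (-180, 180]) and
#'   logical `gimbal`.
#' @export
decompose_joint_rotation <- function(R, gimbal_tol = 1e-6) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  strict <- isTRUE(getOption("armdyn.strict_paper_matrices", TRUE))
  s_y <- if (strict) -R[1L, 3L] else R[1L, 3L]
  s_y <- max(-1, min(1, s_y))
  phi_y <- asin(s_y)
  if (abs(cos(phi_y)) < gimbal_tol) {
    phi_z <- 0
    phi_x <- atan2(R[3L, 2L], R[2L, 2L])
    gimbal <- TRUE
  } else {
    phi_z <- atan2(-R[1L, 2L], R[1L, 1L])
    phi_x <- atan2(-R[2L, 3L], R[3L, 3L])
    gimbal <- FALSE
  }
  list(angles = c(phi_x, phi_y, phi_z) * 180 / pi, gimbal = gimbal)
}

#' Chain the per-joint rotations into cumulative joint coordinate systems
#'
#' Given the per-joint rotation matrices `R*_S`, `R*_E`, `R*_W` (shoulder,
#' elbow, wrist) the cumulative rotations relating each joint coordinate
#' system to the thorax are
#' \deqn{R_S = R^*_S, \quad R_E = R^*_S R_z(90°) R^*_E, \quad R_W = R_E R^*_W,}
#' the fixed 90° z-rotation aligning the shoulder with the elbow joint
#' coordinate system.
#'
#' @param shoulder,elbow,wrist 3x3 per-joint rotation matrices.
#' @return list with elements `R_S`, `R_E`, `R_W`.
#' @export
chain_rotations <- function(shoulder, elbow, wrist) {
  R_S <- shoulder
  R_E <- R_S %*% rot_z(90) %*% elbow
  R_W <- R_E %*% wrist
  list(R_S = R_S, R_E = R_E, R_W = R_W)
}

#' Transform a world-frame force into anatomical (body) axes
#'
#' Applies the transpose of the cumulative joint rotation:
#' `F_body = t(R) %*% F_wcs`.  Pure rotation, so the norm is preserved.
#'
#' @param f_wcs numeric length-3 force (N) in the world coordinate system, or
#'   an n x 3 matrix of per-sample forces.
#' @param R 3x3 cumulative joint rotation.
#' @return force in body axes, same shape as `f_wcs`; columns/components are
#'   ordered (flexion/extension, abduction/adduction, rotation).
#' @export
to_body_frame <- function(f_wcs, R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  if (is.matrix(f_wcs)) {
    stopifnot(ncol(f_wcs) == 3L)
    f_wcs %*% R          # (R^T f^T)^T = f R
  } else {
    stopifnot(length(f_wcs) == 3L)
    drop(crossprod(R, f_wcs))
  }
}

## ---- internal helpers -----------------------------------------------------

## Entry-wise first and second derivatives of the elementary rotations with
## respect to the angle IN RADIANS; needed by the analytic forward kinematics.
rot_x_d <- function(a, order = 1L) {
  c <- cos(a); s <- sin(a)
  if (order == 1L)
    matrix(c(0, 0, 0, 0, -s, -c, 0, c, -s), nrow = 3, byrow = TRUE)
  else
    matrix(c(0, 0, 0, 0, -c, s, 0, -s, -c), nrow = 3, byrow = TRUE)
}

rot_y_d <- function(a, order = 1L) {
  c <- cos(a); s <- sin(a)
  if (isTRUE(getOption("armdyn.strict_paper_matrices", TRUE))) {
    ## layout (c,0,-s / 0,1,0 / s,0,c)
    if (order == 1L)
      matrix(c(-s, 0, -c, 0, 0, 0, c, 0, -s), nrow = 3, byrow = TRUE)
    else
      matrix(c(-c, 0, s, 0, 0, 0, -s, 0, -c), nrow = 3, byrow = TRUE)
  } else {
    ## layout (c,0,s / 0,1,0 / -s,0,c)
    if (order == 1L)
      matrix(c(-s, 0, c, 0, 0, 0, -c, 0, -s), nrow = 3, byrow = TRUE)
    else
      matrix(c(-c, 0, -s, 0, 0, 0, s, 0, -c), nrow = 3, byrow = TRUE)
  }
}

rot_z_d <- function(a, order = 1L) {
  c <- cos(a); s <- sin(a)
  if (order == 1L)
    matrix(c(-s, -c, 0, c, -s, 0, 0, 0, 0), nrow = 3, byrow = TRUE)
  else
    matrix(c(-c, s, 0, -s, -c, 0, 0, 0, 0), nrow = 3, byrow = TRUE)
}

## Check orthonormality + right-handedness of a rotation matrix.
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

## vee operator: skew-symmetric matrix -> axial vector
vee <- function(S) c(S[3L, 2L], S[1L, 3L], S[2L, 1L])

skew <- function(v) {
  matrix(c(0, -v[3L], v[2L],
           v[3L], 0, -v[1L],
           -v[2L], v[1L], 0), nrow = 3, byrow = TRUE)
}
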