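#' Prescription of a simulated isolated flexion/extension movement
#'
#' Describes the simulated experiment: repetitions of maximum shoulder
#' flexion and back, starting from full extension in a seated posture, with
#' the shoulder held at a constant internal-rotation position (IRO) and
#' elbow and wrist straight.  The flexion angle follows a smooth
#' minimum-jerk profile `0 -> max_flexion -> 0` per repetition, so angular
#' velocity and acceleration vanish at the repetition boundaries.
#'
#' @param iro_deg constant internal-rotation position in degrees; the
#'   default experimental grid spans 0-50°, values outside produce a
#'   warning but are allowed.
#' @param max_flexion_deg peak shoulder flexion, degrees.
#' @param n_repetitions number of flexion/extension repetitions.
#' @param duration_per_rep seconds per repetition (half up, half down).
#' @param sample_rate Hz.
#' @return object of class `movement_prescription`.
#' @export
movement_prescription <- function(iro_deg = 0, max_flexion_deg = 150,
                                  n_repetitions = 3, duration_per_rep = 4,
                                  sample_rate = 200) {
  stopifnot(max_flexion_deg > 0, n_repetitions >= 1, duration_per_rep > 0,
            sample_rate > 0)
  if (iro_deg < 0 || iro_deg > 50)
    warning("iro_deg = ", iro_deg, " deg lies outside the 0-50 deg study range")
  n <- round(n_repetitions * duration_per_rep * sample_rate) + 1L
  if (n < min_trial_samples(sample_rate, 6))
    stop("prescription too short for the downstream filter warm-up")
  structure(list(iro_deg = iro_deg, max_flexion_deg = max_flexion_deg,
                 n_repetitions = n_repetitions,
                 duration_per_rep = duration_per_rep,
                 sample_rate = sample_rate, n_samples = n),
            class = "movement_prescription")
}

## minimum-jerk position/velocity/acceleration on s in [0, 1]
min_jerk <- function(s) {
  list(p = 10 * s^3 - 15 * s^4 + 6 * s^5,
       v = 30 * s^2 - 60 * s^3 + 30 * s^4,
       a = 60 * s - 180 * s^2 + 120 * s^3)
}

#' Generate joint angle series for a prescribed movement
#'
#' Humerothoracic flexion follows the minimum-jerk profile of the
#' prescription, abduction is zero, rotation is held at `iro_deg`; elbow
#' and wrist are identically zero (straightened forearm and hand).  The
#' closed-form first and second angle derivatives are attached as
#' attributes `deriv1` (deg/s) and `deriv2` (deg/s^2) for analytic forward
#' kinematics.
#'
#' @param prescription a [movement_prescription()].
#' @return named list of [joint_angle_series()] for `humerothoracic`,
#'   `elbow` and `wrist`.
#' @export
generate_joint_angles <- function(prescription) {
  stopifnot(inherits(prescription, "movement_prescription"))
  p <- prescription
  t <- (seq_len(p$n_samples) - 1L) / p$sample_rate
  phase <- (t %% p$duration_per_rep) / (p$duration_per_rep / 2)
  up <- phase <= 1
  s <- ifelse(up, phase, 2 - phase)
  mj <- min_jerk(s)
  half <- p$duration_per_rep / 2
  phi <- p$max_flexion_deg * mj$p
  dphi <- p$max_flexion_deg * mj$v / half * ifelse(up, 1, -1)
  ddphi <- p$max_flexion_deg * mj$a / half^2   # (ds/dt)^2: sign cancels on descent
  n <- p$n_samples
  zero <- matrix(0, n, 3L)
  mk <- function(joint, ang, d1, d2)
    structure(joint_angle_series(joint, ang, p$sample_rate),
              deriv1 = d1, deriv2 = d2)
  ht_ang <- cbind(phi, 0, p$iro_deg)
  ht_d1 <- cbind(dphi, 0, 0)
  ht_d2 <- cbind(ddphi, 0, 0)
  list(humerothoracic = mk("humerothoracic", ht_ang, ht_d1, ht_d2),
       elbow = mk("elbow", zero, zero, zero),
       wrist = mk("wrist", zero, zero, zero))
}

#' Synthetic subject for simulation
#'
#' A fully specified stand-in subject: anthropometry, regression-derived
#' segment parameters, and a rigid synthetic marker geometry (four cluster
#' markers per segment, expressed in the segment's anatomical frame with
#' origin at the proximal joint centre).  The default is a child-like
#' 30 kg / 1.35 m subject matching the age band of the study population;
#' segment lengths default to standard stature fractions.
#'
#' @param body_mass kg.
#' @param stature m.
#' @param segment_lengths named lengths (m); defaults to stature fractions
#'   0.186 / 0.146 / 0.108 for upper arm / forearm / hand.
#' @param bsp_table regression table, see [default_bsp_table()].
#' @return object of class `synthetic_subject` with fields `anthropometry`,
#'   `bsp`, `marker_local`, `marker_set`, `shoulder_origin`.
#' @export
synthetic_subject <- function(body_mass = 30, stature = 1.35,
                              segment_lengths = NULL,
                              bsp_table = default_bsp_table()) {
  if (is.null(segment_lengths))
    segment_lengths <- c(upper_arm = 0.186, forearm = 0.146, hand = 0.108) * stature
  anthro <- subject_anthropometry(body_mass, stature, segment_lengths)
  bsp <- estimate_segment_parameters(anthro, table = bsp_table)
  ms <- default_marker_set()
  plate <- function(r, L) {
    m <- rbind(c(r, 0.00, -0.30 * L),
               c(r, 0.05, -0.38 * L),
               c(r + 0.03, -0.02, -0.50 * L),
               c(r, 0.03, -0.60 * L))
    m
  }
  loc <- list(
    thorax = rbind(c(-0.10, -0.05, 0.02),
                   c(-0.10, 0.03, 0.04),
                   c(-0.16, -0.01, -0.03),
                   c(-0.12, 0.05, -0.05)),
    upper_arm = plate(0.04, segment_lengths[["upper_arm"]]),
    forearm = plate(0.035, segment_lengths[["forearm"]]),
    hand = plate(0.025, segment_lengths[["hand"]]))
  for (s in names(loc)) rownames(loc[[s]]) <- ms$segments[[s]]
  structure(list(anthropometry = anthro, bsp = bsp, marker_local = loc,
                 marker_set = ms, shoulder_origin = c(0, 0, 1.0)),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("Synthetic subject\n")
  print(x$anthropometry)
  invisible(x)
}

## Rotation series R(t), Rdot, Rddot from Euler angles (deg) and their
## closed-form derivatives, for one joint.
euler_rotation_series <- function(angles, d1 = NULL, d2 = NULL) {
  a <- angles$angles * pi / 180
  n <- nrow(a)
  if (is.null(d1)) d1 <- attr(angles, "deriv1")
  if (is.null(d2)) d2 <- attr(angles, "deriv2")
  if (is.null(d1) || is.null(d2))
    stop("angle series carries no derivative attributes; use the measurement pipeline for sampled data")
  d1 <- d1 * pi / 180; d2 <- d2 * pi / 180
  R <- Rd <- Rdd <- array(0, c(3L, 3L, n))
  for (t in seq_len(n)) {
    ax <- a[t, 1L]; ay <- a[t, 2L]; az <- a[t, 3L]
    A <- rot_x(ax * 180 / pi); B <- rot_y(ay * 180 / pi); C <- rot_z(az * 180 / pi)
    A1 <- rot_x_d(ax); B1 <- rot_y_d(ay); C1 <- rot_z_d(az)
    A2 <- rot_x_d(ax, 2L); B2 <- rot_y_d(ay, 2L); C2 <- rot_z_d(az, 2L)
    va <- d1[t, 1L]; vb <- d1[t, 2L]; vc <- d1[t, 3L]
    aa <- d2[t, 1L]; ab <- d2[t, 2L]; ac <- d2[t, 3L]
    R[, , t] <- A %*% B %*% C
    Rd[, , t] <- (A1 * va) %*% B %*% C + A %*% (B1 * vb) %*% C +
      A %*% B %*% (C1 * vc)
    Rdd[, , t] <- (A2 * va^2 + A1 * aa) %*% B %*% C +
      A %*% (B2 * vb^2 + B1 * ab) %*% C +
      A %*% B %*% (C2 * vc^2 + C1 * ac) +
      2 * ((A1 * va) %*% (B1 * vb) %*% C +
           (A1 * va) %*% B %*% (C1 * vc) +
           A %*% (B1 * vb) %*% (C1 * vc))
  }
  list(R = R, Rd = Rd, Rdd = Rdd)
}

## product rule for two rotation series (B constant matrix between them)
series_product <- function(x, mid, y) {
  n <- dim(x$R)[3L]
  R <- Rd <- Rdd <- array(0, c(3L, 3L, n))
  for (t in seq_len(n)) {
    R[, , t] <- x$R[, , t] %*% mid %*% y$R[, , t]
    Rd[, , t] <- x$Rd[, , t] %*% mid %*% y$R[, , t] +
      x$R[, , t] %*% mid %*% y$Rd[, , t]
    Rdd[, , t] <- x$Rdd[, , t] %*% mid %*% y$R[, , t] +
      2 * x$Rd[, , t] %*% mid %*% y$Rd[, , t] +
      x$R[, , t] %*% mid %*% y$Rdd[, , t]
  }
  list(R = R, Rd = Rd, Rdd = Rdd)
}

#' Analytic forward kinematics of the synthetic arm
#'
#' Chains the per-joint rotations (with closed-form derivatives from the
#' generator) into segment frames, joint-centre and centre-of-mass
#' trajectories with analytic accelerations (no numerical
#' differentiation), segment angular velocity/acceleration, and synthetic
#' marker trajectories so the complete measurement pipeline
#' (calibrate -> frames -> angles -> differentiation) can be run
#' end-to-end against the analytic reference.
#'
#' @param angles output of [generate_joint_angles()].
#' @param subject a [synthetic_subject()].
#' @return list with `frames` (per-segment `segment_frame`), `kinematics`
#'   (per-segment `segment_kinematics`, analytic), `markers`
#'   (a [marker_trajectory()]) and `chain` (`R_S`, `R_E`, `R_W` arrays).
#' @export
forward_kinematics <- function(angles, subject) {
  stopifnot(inherits(subject, "synthetic_subject"))
  fs <- angles$humerothoracic$sample_rate
  n <- nrow(angles$humerothoracic$angles)
  sS <- euler_rotation_series(angles$humerothoracic)
  sE0 <- euler_rotation_series(angles$elbow)
  sW0 <- euler_rotation_series(angles$wrist)
  C90 <- rot_z(90)
  sE <- series_product(sS, C90, sE0)            # R_E = R*_S C90 R*_E
  sW <- series_product(sE, diag(3), sW0)        # R_W = R_E R*_W
  sT <- list(R = array(diag(3), c(3L, 3L, n)),
             Rd = array(0, c(3L, 3L, n)), Rdd = array(0, c(3L, 3L, n)))
  L <- subject$anthropometry$segment_lengths
  p0 <- subject$shoulder_origin
  axis <- function(len) c(0, 0, -len)
  ## joint-centre trajectories with derivatives
  traj_point <- function(base, series, v_local) {
    p <- d <- dd <- matrix(0, n, 3L)
    for (t in seq_len(n)) {
      p[t, ] <- base$p[t, ] + drop(series$R[, , t] %*% v_local)
      d[t, ] <- base$d[t, ] + drop(series$Rd[, , t] %*% v_local)
      dd[t, ] <- base$dd[t, ] + drop(series$Rdd[, , t] %*% v_local)
    }
    list(p = p, d = d, dd = dd)
  }
  fixed <- list(p = matrix(p0, n, 3L, byrow = TRUE),
                d = matrix(0, n, 3L), dd = matrix(0, n, 3L))
  p_elbow <- traj_point(fixed, sS, axis(L[["upper_arm"]]))
  p_wrist <- traj_point(p_elbow, sE, axis(L[["forearm"]]))
  p_tip <- traj_point(p_wrist, sW, axis(L[["hand"]]))
  series <- list(thorax = sT, upper_arm = sS, forearm = sE, hand = sW)
  prox <- list(thorax = fixed, upper_arm = fixed, forearm = p_elbow,
               hand = p_wrist)
  dist <- list(thorax = fixed, upper_arm = p_elbow, forearm = p_wrist,
               hand = p_tip)
  frames <- list(); kin <- list()
  for (seg in names(series)) {
    sr <- series[[seg]]
    frames[[seg]] <- structure(
      list(segment = seg, origin = prox[[seg]]$p, dist = dist[[seg]]$p,
           basis = sr$R, valid = rep(TRUE, n), sample_rate = fs),
      class = "segment_frame")
    if (seg == "thorax") next
    f <- subject$bsp[[seg]]$com_fraction
    com <- traj_point(prox[[seg]], sr, axis(f * L[[seg]]))
    omega <- matrix(0, n, 3L); alpha <- matrix(0, n, 3L)
    for (t in seq_len(n)) {
      W <- sr$Rd[, , t] %*% t(sr$R[, , t])
      W <- (W - t(W)) / 2
      A <- sr$Rdd[, , t] %*% t(sr$R[, , t]) - W %*% W
      A <- (A - t(A)) / 2
      omega[t, ] <- vee(W)
      alpha[t, ] <- vee(A)
    }
    kin[[seg]] <- structure(
      list(segment = seg, com_position = com$p, com_velocity = com$d,
           com_acceleration = com$dd, omega = omega, alpha = alpha,
           prox = prox[[seg]]$p, dist = dist[[seg]]$p, basis = sr$R,
           valid = rep(TRUE, n), endpoint = rep(FALSE, n), sample_rate = fs),
      class = "segment_kinematics")
  }
  ## synthetic marker trajectories
  labels <- unlist(subject$marker_set$segments, use.names = FALSE)
  pos <- array(NA_real_, c(n, length(labels), 3L),
               dimnames = list(NULL, labels, c("x", "y", "z")))
  for (seg in names(subject$marker_local)) {
    loc <- subject$marker_local[[seg]]
    sr <- series[[seg]]
    base <- prox[[seg]]$p
    for (m in seq_len(nrow(loc))) {
      lab <- rownames(loc)[m]
      for (t in seq_len(n))
        pos[t, lab, ] <- base[t, ] + drop(sr$R[, , t] %*% loc[m, ])
    }
  }
  list(frames = frames, kinematics = kin,
       markers = marker_trajectory(pos, fs),
       chain = list(R_S = sS$R, R_E = sE$R, R_W = sW$R))
}

#' Simulated static calibration trial
#'
#' Generates a stationary trial in the neutral pose (all joint angles
#' zero, arm hanging) containing both the cluster markers and the joint
#' markers required by [calibrate()].
#'
#' @param subject a [synthetic_subject()].
#' @param n_frames number of frames.
#' @param sample_rate Hz.
#' @return a [marker_trajectory()].
#' @export
simulate_static_trial <- function(subject, n_frames = 100L, sample_rate = 200) {
  L <- subject$anthropometry$segment_lengths
  p0 <- subject$shoulder_origin
  ## neutral pose: shoulder frame identity; forearm/hand carry the 90 deg
  ## z relabeling, which leaves the (longitudinal) z axis unchanged
  Rseg <- list(thorax = diag(3), upper_arm = diag(3),
               forearm = rot_z(90), hand = rot_z(90))
  origin <- list(thorax = p0, upper_arm = p0,
                 forearm = p0 + c(0, 0, -L[["upper_arm"]]),
                 hand = p0 + c(0, 0, -L[["upper_arm"]] - L[["forearm"]]))
  joints <- rbind(SJC = p0,
                  EJC = p0 + c(0, 0, -L[["upper_arm"]]),
                  WJC = p0 + c(0, 0, -L[["upper_arm"]] - L[["forearm"]]),
                  HTIP = p0 + c(0, 0, -sum(L[c("upper_arm", "forearm", "hand")])))
  labels <- c(unlist(subject$marker_set$segments, use.names = FALSE),
              rownames(joints))
  pos <- array(NA_real_, c(n_frames, length(labels), 3L),
               dimnames = list(NULL, labels, c("x", "y", "z")))
  for (seg in names(subject$marker_local)) {
    loc <- subject$marker_local[[seg]]
    for (m in seq_len(nrow(loc))) {
      p <- origin[[seg]] + drop(Rseg[[seg]] %*% loc[m, ])
      pos[, rownames(loc)[m], ] <- matrix(p, n_frames, 3L, byrow = TRUE)
    }
  }
  for (j in rownames(joints))
    pos[, j, ] <- matrix(joints[j, ], n_frames, 3L, byrow = TRUE)
  marker_trajectory(pos, sample_rate)
}

#' Add measurement noise to a marker trajectory
#'
#' Isotropic gaussian noise, reproducible under a fixed seed; the global
#' RNG state is restored on exit.
#'
#' @param trajectory a [marker_trajectory()].
#' @param sigma_mm noise standard deviation in millimetres, >= 0.
#' @param seed integer seed.
#' @return a noisy [marker_trajectory()].
#' @export
add_noise <- function(trajectory, sigma_mm, seed = 1L) {
  stopifnot(sigma_mm >= 0)
  if (sigma_mm == 0) return(trajectory)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pos <- trajectory$positions
  pos <- pos + stats::rnorm(length(pos), sd = sigma_mm / 1000)
  marker_trajectory(pos, trajectory$sample_rate)
}

#' Run the internal-rotation simulation experiment
#'
#' For each internal-rotation position in `grid`, generates the prescribed
#' isolated flexion/extension movement, computes net joint loads by
#' inverse dynamics (zero external load by default, matching the simulated
#' free movement), and summarises the humerothoracic force per anatomical
#' axis with [sweep_peak_force()].
#'
#' Two computation routes are available: `"analytic"` feeds the exact
#' forward-kinematic accelerations into the recursion; `"markers"` runs
#' the complete measurement pipeline (synthetic markers -> static
#' calibration -> segment frames -> joint angles -> filtered numerical
#' differentiation) first, as a real recording would.
#'
#' @param grid numeric vector of IRO levels in degrees.
#' @param subject a [synthetic_subject()].
#' @param prescription base [movement_prescription()]; its `iro_deg` is
#'   overridden per grid level.
#' @param pipeline `"analytic"` or `"markers"`.
#' @param ext external load or `NULL`.
#' @param g gravity vector.
#' @param cutoff_hz filter cutoff for the `"markers"` route.
#' @return an `iro_sweep` data frame (see [sweep_peak_force()]) with the
#'   per-level loads attached as attribute `loads`.
#' @export
run_iro_experiment <- function(grid = seq(0, 50, by = 10),
                               subject = synthetic_subject(),
                               prescription = movement_prescription(),
                               pipeline = c("analytic", "markers"),
                               ext = NULL, g = gravity_vector(),
                               cutoff_hz = 6) {
  if (!length(grid)) stop("empty IRO grid")
  if (any(grid < 0 | grid > 50))
    warning("IRO level(s) ", paste(grid[grid < 0 | grid > 50], collapse = ", "),
            " deg lie outside the 0-50 deg study range")
  pipeline <- match.arg(pipeline)
  loads_by_iro <- list()
  for (iro in grid) {
    p <- prescription
    p$iro_deg <- iro
    ang <- generate_joint_angles(p)
    fk <- forward_kinematics(ang, subject)
    if (pipeline == "analytic") {
      kin <- fk$kinematics
      chain <- fk$chain
    } else {
      static <- simulate_static_trial(subject, sample_rate = p$sample_rate)
      cal <- calibrate(static, subject$marker_set)
      frames <- build_segment_frames(fk$markers, cal)
      meas <- compute_joint_angles(frames)
      kin <- compute_com_kinematics(frames, subject$bsp, cutoff_hz = cutoff_hz)
      chain <- rotation_chain_series(meas)
    }
    loads_by_iro <- c(loads_by_iro, stats::setNames(
      list(compute_net_joint_loads(subject$bsp, kin, chain, ext = ext, g = g)),
      as.character(iro)))
  }
  out <- sweep_peak_force(loads_by_iro)
  attr(out, "loads") <- loads_by_iro
  attr(out, "pipeline") <- pipeline
  out
}
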