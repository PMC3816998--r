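## small helper: constant-pose trajectory from a marker matrix
const_trajectory <- function(points, n = 20L, fs = 100) {
  pos <- array(NA_real_, c(n, nrow(points), 3L),
               dimnames = list(NULL, rownames(points), c("x", "y", "z")))
  for (m in seq_len(nrow(points)))
    pos[, m, ] <- matrix(points[m, ], n, 3L, byrow = TRUE)
  marker_trajectory(pos, fs)
}

test_that("joint marker at the cluster centroid calibrates to a zero offset", {
  sub <- synthetic_subject()
  static <- simulate_static_trial(sub, n_frames = 10L)
  ## move the shoulder joint marker onto the thorax cluster centroid
  centroid <- colMeans(static$positions[1, paste0("TH", 1:4), ])
  static$positions[, "SJC", ] <- matrix(centroid, 10L, 3L, byrow = TRUE)
  cal <- calibrate(static, sub$marker_set)
  expect_equal(unname(cal$segments$thorax$prox_offset), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("calibrated joint centres track a rigid transform of the cluster", {
  sub <- synthetic_subject()
  static <- simulate_static_trial(sub, n_frames = 5L)
  cal <- calibrate(static, sub$marker_set)
  ## rigidly move the whole scene and rebuild frames: the reconstructed
  ## elbow centre must follow the analytic transform
  R0 <- joint_rotation(c(25, -40, 60))
  t0 <- c(0.3, -1.2, 0.5)
  pos <- static$positions
  for (m in seq_len(dim(pos)[2L]))
    pos[, m, ] <- t(R0 %*% t(pos[, m, , drop = TRUE])) +
      matrix(t0, dim(pos)[1L], 3L, byrow = TRUE)
  moved <- marker_trajectory(pos[, unlist(sub$marker_set$segments), ,
                                 drop = FALSE], static$sample_rate)
  frames <- build_segment_frames(moved, cal)
  p_elbow_true <- drop(R0 %*% (sub$shoulder_origin +
    c(0, 0, -sub$anthropometry$segment_lengths[["upper_arm"]]))) + t0
  expect_equal(unname(frames$upper_arm$dist[3, ]), p_elbow_true,
               tolerance = 1e-10)
})

test_that("joint-centre offsets from a noisy static trial converge at the Monte-Carlo rate", {
  sub <- synthetic_subject()
  static <- simulate_static_trial(sub, n_frames = 100L)
  cal0 <- calibrate(static, sub$marker_set)
  noisy <- add_noise(static, sigma_mm = 1, seed = 99L)
  cal1 <- calibrate(noisy, sub$marker_set)
  sigma <- 1e-3
  for (seg in names(cal0$segments)) {
    d <- abs(cal1$segments[[seg]]$prox_offset - cal0$segments[[seg]]$prox_offset)
    ## Monte-Carlo rate of a 100-frame average: the joint-marker average
    ## contributes sigma/sqrt(n) per axis, and cluster-orientation noise is
    ## amplified by the joint-centre lever over the cluster radius; both
    ## shrink as 1/sqrt(n)
    lever <- sqrt(sum(cal0$segments[[seg]]$prox_offset^2))
    pts <- sub$marker_local[[seg]]
    radius <- sqrt(mean(rowSums(sweep(pts, 2L, colMeans(pts))^2)))
    bound <- 3 * sigma / sqrt(100) * (1 + lever / radius)
    expect_true(all(d < bound))
  }
  ## quadrupling the frames roughly halves the error (rate check)
  static4 <- simulate_static_trial(sub, n_frames = 400L)
  cal4 <- calibrate(add_noise(static4, sigma_mm = 1, seed = 99L),
                    sub$marker_set)
  e1 <- sqrt(sum((cal1$segments$hand$prox_offset -
                    cal0$segments$hand$prox_offset)^2))
  e4 <- sqrt(sum((cal4$segments$hand$prox_offset -
                    cal0$segments$hand$prox_offset)^2))
  expect_lt(e4, e1)
})

test_that("segment frames are orthonormal, right-handed and constant for stationary markers", {
  sub <- synthetic_subject()
  static <- simulate_static_trial(sub, n_frames = 8L)
  cal <- calibrate(static, sub$marker_set)
  move <- marker_trajectory(
    static$positions[, unlist(sub$marker_set$segments), , drop = FALSE],
    static$sample_rate)
  frames <- build_segment_frames(move, cal)
  for (fr in frames) {
    for (t in seq_len(dim(fr$basis)[3L])) {
      B <- fr$basis[, , t]
      expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
      expect_equal(det(B), 1, tolerance = 1e-9)
      expect_lt(max(abs(B - fr$basis[, , 1L])), 1e-12)
    }
  }
  ## mirrored (left-side) cluster still yields a right-handed frame
  pts <- sub$marker_local$upper_arm
  pts[, 2L] <- -pts[, 2L]
  tf <- technical_frame(pts)
  expect_equal(det(tf$basis), 1, tolerance = 1e-12)
})

test_that("frames generated from a known rotation recover it", {
  sub <- synthetic_subject()
  static <- simulate_static_trial(sub, n_frames = 5L)
  cal <- calibrate(static, sub$marker_set)
  Rtrue <- joint_rotation(c(35, 10, -20))
  pos <- static$positions[, unlist(sub$marker_set$segments), , drop = FALSE]
  for (m in dimnames(pos)[[2L]]) {
    if (m %in% sub$marker_set$segments$upper_arm) {
      loc <- sub$marker_local$upper_arm[m, ]
      p <- sub$shoulder_origin + drop(Rtrue %*% loc)
      pos[, m, ] <- matrix(p, dim(pos)[1L], 3L, byrow = TRUE)
    }
  }
  frames <- build_segment_frames(marker_trajectory(pos, 100), cal)
  expect_lt(max(abs(frames$upper_arm$basis[, , 1L] - Rtrue)), 1e-9)
})

test_that("joint angle extraction inverts the frame construction", {
  sub <- synthetic_subject()
  fk <- static_kinematics(sub, shoulder_angles = c(0, 0, 0))
  ang <- compute_joint_angles(fk$frames)
  expect_equal(max(abs(ang$humerothoracic$angles)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ang$elbow$angles)), 0, tolerance = 1e-9)
  fk2 <- static_kinematics(sub, shoulder_angles = c(30, 0, 0))
  ang2 <- compute_joint_angles(fk2$frames)
  expect_equal(unname(ang2$humerothoracic$angles[1, ]), c(30, 0, 0),
               tolerance = 1e-9)
})

test_that("CoM differentiation recovers closed-form accelerations", {
  sub <- synthetic_subject()
  fs <- 200
  n <- 400L
  fk <- static_kinematics(sub, n = n, sample_rate = fs)
  frames <- fk$frames
  t <- (seq_len(n) - 1L) / fs
  ## stationary arm: numerical floor
  kin0 <- compute_com_kinematics(frames, sub$bsp, cutoff_hz = 6)
  expect_lt(max(abs(kin0$hand$com_acceleration)), 1e-8)
  ## uniform gravity drop: a = (0,0,-9.81) in the interior
  drop_z <- 0.5 * -9.81 * t^2
  fr <- frames
  for (seg in names(fr)) {
    fr[[seg]]$origin[, 3L] <- fr[[seg]]$origin[, 3L] + drop_z
    fr[[seg]]$dist[, 3L] <- fr[[seg]]$dist[, 3L] + drop_z
  }
  kin <- compute_com_kinematics(fr, sub$bsp, cutoff_hz = 6)
  interior <- 60:(n - 60)
  expect_lt(max(abs(kin$hand$com_acceleration[interior, 3L] + 9.81)), 1e-3)
  expect_lt(max(abs(kin$hand$com_acceleration[interior, 1:2])), 1e-3)
  ## 1 Hz sinusoid: amplitude within 1 % of A (2 pi f)^2
  A <- 0.1; f <- 1
  fr2 <- frames
  for (seg in names(fr2)) {
    fr2[[seg]]$origin[, 2L] <- fr2[[seg]]$origin[, 2L] + A * sin(2 * pi * f * t)
    fr2[[seg]]$dist[, 2L] <- fr2[[seg]]$dist[, 2L] + A * sin(2 * pi * f * t)
  }
  kin2 <- compute_com_kinematics(fr2, sub$bsp, cutoff_hz = 6)
  amp <- max(abs(kin2$hand$com_acceleration[interior, 2L]))
  expect_equal(amp, A * (2 * pi * f)^2, tolerance = 0.01)
})

test_that("accelerations are invariant under rigid world translation", {
  sub <- synthetic_subject()
  p <- movement_prescription(n_repetitions = 1, duration_per_rep = 2,
                             sample_rate = 25)
  fk <- forward_kinematics(generate_joint_angles(p), sub)
  shift <- c(0.5, -0.25, 0.4)
  fr <- fk$frames
  for (seg in names(fr)) {
    fr[[seg]]$origin <- sweep(fr[[seg]]$origin, 2L, shift, "+")
    fr[[seg]]$dist <- sweep(fr[[seg]]$dist, 2L, shift, "+")
  }
  k0 <- compute_com_kinematics(fk$frames, sub$bsp, cutoff_hz = 6)
  k1 <- compute_com_kinematics(fr, sub$bsp, cutoff_hz = 6)
  expect_lt(max(abs(k0$hand$com_acceleration - k1$hand$com_acceleration)), 1e-12)
})

test_that("short trials and short gaps are handled per contract", {
  sub <- synthetic_subject()
  fk <- static_kinematics(sub, n = 5L, sample_rate = 200)
  expect_error(compute_com_kinematics(fk$frames, sub$bsp, cutoff_hz = 6),
               "need >=")
  ## a 3-sample gap is interpolated; a 10-sample gap flags frames invalid
  p <- movement_prescription(n_repetitions = 1, duration_per_rep = 2,
                             sample_rate = 100)
  fk2 <- forward_kinematics(generate_joint_angles(p), sub)
  static <- simulate_static_trial(sub, sample_rate = 100)
  cal <- calibrate(static, sub$marker_set)
  traj <- fk2$markers
  traj$positions[50:52, "UA1", ] <- NA
  traj$positions[80:89, "UA1", ] <- NA
  traj <- marker_trajectory(traj$positions, traj$sample_rate)
  frames <- build_segment_frames(traj, cal, max_gap = 5L)
  expect_true(all(frames$upper_arm$valid[50:52]))
  expect_true(all(!frames$upper_arm$valid[80:89]))
  expect_lt(max(abs(frames$upper_arm$origin[51, ] -
                      fk2$frames$upper_arm$origin[51, ])), 1e-3)
})

test_that("marker CSV round trip preserves data and rejects malformed input", {
  sub <- synthetic_subject()
  static <- simulate_static_trial(sub, n_frames = 10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_csv(static, path)
  back <- read_marker_csv(path)
  expect_equal(back$sample_rate, static$sample_rate, tolerance = 1e-6)
  expect_equal(back$positions, static$positions, tolerance = 1e-7,
               ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,M1_x,M1_y", "0,1,2", "0.01,1,2"), bad)
  expect_error(read_marker_csv(bad), "M1_z")
})
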