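## minimal one-sample kinematics for algebraic checks
point_kin <- function(acc = c(0, 0, 0), n = 1L, fs = 100) {
  structure(list(segment = "hand",
                 com_position = matrix(0, n, 3L),
                 com_acceleration = matrix(acc, n, 3L, byrow = TRUE),
                 omega = matrix(0, n, 3L), alpha = matrix(0, n, 3L),
                 prox = matrix(0, n, 3L), dist = matrix(0, n, 3L),
                 basis = array(diag(3), c(3L, 3L, n)),
                 valid = rep(TRUE, n), endpoint = rep(FALSE, n),
                 sample_rate = fs),
            class = "segment_kinematics")
}

test_that("wrist equation reproduces its hand-evaluated cases", {
  g <- gravity_vector()
  ## static hand, no external load: weight only
  f1 <- wrist_net_force(NULL, list(mass = 0.5), point_kin(), g)
  expect_equal(drop(f1$force_wcs), c(0, 0, -4.905))
  expect_equal(sqrt(sum(f1$force_wcs^2)), 0.5 * 9.81)
  ## free fall: weight cancels inertia exactly
  f2 <- wrist_net_force(NULL, list(mass = 0.5), point_kin(acc = g), g)
  expect_identical(drop(f2$force_wcs), c(0, 0, 0))
  ## default sensor sign matrix on a massless hand
  ext <- external_load(matrix(c(10, 20, 30), 1L, 3L))
  f3 <- wrist_net_force(ext, list(mass = 0), point_kin(), g)
  expect_identical(drop(f3$force_wcs), c(-10, -20, 30))
  ## a load already expressed in world axes bypasses the sign matrix
  extw <- external_load(matrix(c(10, 20, 30), 1L, 3L), frame = "wcs")
  f4 <- wrist_net_force(extw, list(mass = 0), point_kin(), g)
  expect_identical(drop(f4$force_wcs), c(10, 20, 30))
})

test_that("recursion accumulates static weight and passes zero-mass segments through", {
  g <- gravity_vector()
  w <- wrist_net_force(NULL, list(mass = 0.4), point_kin(), g)
  e <- recurse_proximal(w, list(mass = 0.9), point_kin(), "elbow", g)
  s <- recurse_proximal(e, list(mass = 1.6), point_kin(), "humerothoracic", g)
  expect_equal(drop(s$force_wcs), c(0, 0, -(0.4 + 0.9 + 1.6) * 9.81))
  e0 <- recurse_proximal(w, list(mass = 0), point_kin(), "elbow", g)
  expect_identical(e0$force_wcs, w$force_wcs)
})

test_that("static humerothoracic force equals supported weight at any posture", {
  sub <- synthetic_subject()
  mtot <- total_arm_mass(sub)
  for (pose in list(c(0, 0, 0), c(45, 0, 20), c(90, 30, -10), c(150, -20, 50))) {
    fk <- static_kinematics(sub, shoulder_angles = pose)
    loads <- compute_net_joint_loads(sub$bsp, fk$kinematics, fk$chain)
    f <- loads$humerothoracic$force_wcs[2, ]
    expect_equal(unname(f), c(0, 0, -mtot * 9.81), tolerance = 1e-9)
    ## BCS redistributes with posture but preserves the norm
    expect_equal(sqrt(sum(loads$humerothoracic$force_bcs[2, ]^2)),
                 mtot * 9.81, tolerance = 1e-9)
  }
})

test_that("net joint force is linear in the external load at fixed kinematics", {
  sub <- synthetic_subject()
  fk <- static_kinematics(sub, shoulder_angles = c(60, 10, 25), n = 4L)
  n <- 4L
  ext1 <- external_load(matrix(c(5, -8, 12), n, 3L, byrow = TRUE))
  ext2 <- external_load(2 * matrix(c(5, -8, 12), n, 3L, byrow = TRUE))
  l0 <- compute_net_joint_loads(sub$bsp, fk$kinematics, fk$chain)
  l1 <- compute_net_joint_loads(sub$bsp, fk$kinematics, fk$chain, ext = ext1)
  l2 <- compute_net_joint_loads(sub$bsp, fk$kinematics, fk$chain, ext = ext2)
  for (j in names(l0)) {
    d1 <- l1[[j]]$force_wcs - l0[[j]]$force_wcs
    d2 <- l2[[j]]$force_wcs - l0[[j]]$force_wcs
    expect_equal(d2, 2 * d1, tolerance = 1e-12)
  }
})

test_that("body-axis transform matches per-sample rotation and distributes over terms", {
  sub <- synthetic_subject()
  fk <- static_kinematics(sub, shoulder_angles = c(40, 15, 30), n = 3L)
  ext <- external_load(matrix(c(4, 7, -2), 3L, 3L, byrow = TRUE))
  g <- gravity_vector()
  loads <- compute_net_joint_loads(sub$bsp, fk$kinematics, fk$chain, ext = ext)
  ## identity chain leaves forces untouched
  idchain <- list(R_S = array(diag(3), c(3, 3, 3)),
                  R_E = array(diag(3), c(3, 3, 3)),
                  R_W = array(diag(3), c(3, 3, 3)))
  lid <- express_in_body_axes(loads, idchain)
  expect_equal(unname(lid$wrist$force_bcs), lid$wrist$force_wcs)
  ## transforming the wrist equation term-by-term equals transforming the sum
  t <- 2L
  RW <- fk$chain$R_W[, , t]
  S <- ext$sign_matrix
  m_h <- sub$bsp$hand$mass
  a_h <- fk$kinematics$hand$com_acceleration[t, ]
  term_by_term <- drop(crossprod(RW, S %*% ext$force[t, ])) +
    m_h * drop(crossprod(RW, g)) - m_h * drop(crossprod(RW, a_h))
  expect_equal(unname(loads$wrist$force_bcs[t, ]), term_by_term,
               tolerance = 1e-12)
  ## norms preserved at every joint and sample
  for (j in names(loads))
    expect_equal(sqrt(rowSums(loads[[j]]$force_bcs^2)),
                 sqrt(rowSums(loads[[j]]$force_wcs^2)), tolerance = 1e-9)
})

test_that("static moments reduce to gravitational levers and vanish without them", {
  ## horizontal forearm-like single link, point mass at the CoM lever
  m <- 1.2; lever <- 0.13
  kin <- point_kin()
  kin$com_position <- matrix(c(0, lever, 0), 1L, 3L)   # horizontal along +y
  kin$prox <- matrix(0, 1L, 3L)
  kin$dist <- matrix(c(0, 2 * lever, 0), 1L, 3L)
  par <- list(mass = m, principal_inertia = c(0, 0, 0))
  loads <- list(elbow = wrist_net_force(NULL, par, kin))
  loads <- net_joint_moments(loads, list(seg = par), list(seg = kin),
                             chain = data.frame(joint = "elbow", segment = "seg"))
  expect_equal(sqrt(sum(loads$elbow$moment_wcs^2)), m * 9.81 * lever,
               tolerance = 1e-12)
  ## force through the joint centre, no external moment: zero moment
  kin0 <- point_kin()
  par0 <- list(mass = 0.8, principal_inertia = c(0, 0, 0))
  l0 <- list(elbow = wrist_net_force(NULL, par0, kin0))
  l0 <- net_joint_moments(l0, list(seg = par0), list(seg = kin0),
                          chain = data.frame(joint = "elbow", segment = "seg"))
  expect_equal(unname(l0$elbow$moment_wcs), matrix(0, 1L, 3L),
               tolerance = 1e-12)
})

test_that("WCS outputs rotate with the world frame while BCS outputs are invariant", {
  sub <- synthetic_subject()
  p <- movement_prescription(n_repetitions = 1, duration_per_rep = 2,
                             sample_rate = 100, iro_deg = 20)
  fk <- forward_kinematics(generate_joint_angles(p), sub)
  g <- gravity_vector()
  l0 <- compute_net_joint_loads(sub$bsp, fk$kinematics, fk$chain, g = g)
  R0 <- joint_rotation(c(15, -30, 45))
  rot_kin <- lapply(fk$kinematics, function(k) {
    k$com_position <- k$com_position %*% t(R0)
    k$com_acceleration <- k$com_acceleration %*% t(R0)
    k$prox <- k$prox %*% t(R0); k$dist <- k$dist %*% t(R0)
    k$omega <- k$omega %*% t(R0); k$alpha <- k$alpha %*% t(R0)
    for (t in seq_len(dim(k$basis)[3L])) k$basis[, , t] <- R0 %*% k$basis[, , t]
    k
  })
  rot_chain <- fk$chain
  for (nm in names(rot_chain))
    for (t in seq_len(dim(rot_chain[[nm]])[3L]))
      rot_chain[[nm]][, , t] <- R0 %*% rot_chain[[nm]][, , t]
  l1 <- compute_net_joint_loads(sub$bsp, rot_kin, rot_chain,
                                g = drop(R0 %*% g))
  for (j in names(l0)) {
    expect_lt(max(abs(l1[[j]]$force_wcs - l0[[j]]$force_wcs %*% t(R0))), 1e-9)
    expect_lt(max(abs(l1[[j]]$force_bcs - l0[[j]]$force_bcs)), 1e-9)
  }
})

test_that("external loads resample onto the kinematic time base and mismatches raise", {
  ext <- external_load(matrix(seq_len(30), 10L, 3L))
  attr(ext, "time_s") <- seq(0, 0.9, by = 0.1)
  rs <- resample_load(ext, seq(0, 0.9, by = 0.05))
  expect_equal(nrow(rs$force), 19L)
  expect_equal(rs$force[2L, 1L], mean(ext$force[1:2, 1L]))
  expect_error(wrist_net_force(ext, list(mass = 1), point_kin(n = 5L)),
               "time-base mismatch.*10.*5")
})
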