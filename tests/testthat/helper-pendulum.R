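## Independent closed-form oracle: planar compound pendula swinging about
## the world x axis in the y-z plane (gravity -z), absolute link angles
## measured from straight down.  Equations of motion are the standard
## Lagrangian form for one and two compound links; joint loads are computed
## from the whole-subsystem linear and angular momentum theorems -- a
## recursion-free route against which the package's per-segment
## Newton-Euler recursion is checked.

pendulum_accel <- function(theta, omega, par) {
  g <- 9.81
  if (par$n == 1L) {
    with(par, {
      th <- theta[1L]
      dd <- -(m1 * d1 * g * sin(th)) / (I1 + m1 * d1^2)
      c(dd)
    })
  } else {
    with(par, {
      dth <- theta[1L] - theta[2L]
      M11 <- I1 + m1 * d1^2 + m2 * L1^2
      M12 <- m2 * L1 * d2 * cos(dth)
      M22 <- I2 + m2 * d2^2
      b1 <- -m2 * L1 * d2 * sin(dth) * omega[2L]^2 -
        (m1 * d1 + m2 * L1) * g * sin(theta[1L])
      b2 <- m2 * L1 * d2 * sin(dth) * omega[1L]^2 -
        m2 * d2 * g * sin(theta[2L])
      solve(matrix(c(M11, M12, M12, M22), 2L, 2L), c(b1, b2))
    })
  }
}

## integrate the pendulum and return per-sample state + angular accelerations
pendulum_trajectory <- function(par, theta0, omega0 = rep(0, par$n),
                                duration = 0.5, fs = 200) {
  times <- seq(0, duration, by = 1 / fs)
  rhs <- function(t, y, p) {
    th <- y[seq_len(p$n)]; om <- y[p$n + seq_len(p$n)]
    list(c(om, pendulum_accel(th, om, p)))
  }
  sol <- deSolve::ode(y = c(theta0, omega0), times = times, func = rhs,
                      parms = par, rtol = 1e-11, atol = 1e-11)
  th <- sol[, 1L + seq_len(par$n), drop = FALSE]
  om <- sol[, 1L + par$n + seq_len(par$n), drop = FALSE]
  al <- vapply(seq_len(nrow(th)),
               function(i) pendulum_accel(th[i, ], om[i, ], par),
               numeric(par$n))
  al <- if (par$n == 1L) matrix(al, ncol = 1L) else t(al)
  list(theta = th, omega = om, alpha = al, times = times, par = par)
}

dir_vec <- function(th) cbind(0, sin(th), -cos(th))      # unit along link
dir_vec_d <- function(th) cbind(0, cos(th), sin(th))     # d/dth

## analytic link kinematics: joint positions, CoM pos/vel/acc, omega/alpha
pendulum_kinematics <- function(traj) {
  par <- traj$par
  th <- traj$theta; om <- traj$omega; al <- traj$alpha
  n <- nrow(th)
  links <- list()
  p_prox <- matrix(0, n, 3L)
  a_prox <- matrix(0, n, 3L)
  Ls <- c(par$L1, if (par$n == 2L) par$L2)
  ds <- c(par$d1, if (par$n == 2L) par$d2)
  ms <- c(par$m1, if (par$n == 2L) par$m2)
  Is <- list(par$I1vec, if (par$n == 2L) par$I2vec)
  for (k in seq_len(par$n)) {
    u <- dir_vec(th[, k]); up <- dir_vec_d(th[, k])
    com <- p_prox + ds[k] * u
    a_com <- a_prox + ds[k] * (al[, k] * up - om[, k]^2 * u)
    p_dist <- p_prox + Ls[k] * u
    a_dist <- a_prox + Ls[k] * (al[, k] * up - om[, k]^2 * u)
    basis <- array(0, c(3L, 3L, n))
    for (t in seq_len(n)) basis[, , t] <- rot_x(th[t, k] * 180 / pi)
    links[[k]] <- structure(
      list(segment = paste0("link", k), com_position = com,
           com_velocity = NULL, com_acceleration = a_com,
           omega = cbind(om[, k], 0, 0), alpha = cbind(al[, k], 0, 0),
           prox = p_prox, dist = p_dist, basis = basis,
           valid = rep(TRUE, n), endpoint = rep(FALSE, n),
           sample_rate = 1 / diff(traj$times[1:2])),
      class = "segment_kinematics")
    attr(links[[k]], "mass") <- ms[k]
    attr(links[[k]], "inertia") <- Is[[k]]
    p_prox <- p_dist
    a_prox <- a_dist
  }
  links
}

## oracle joint loads (distal-on-proximal reporting convention) by the
## momentum theorems applied to the subsystem distal of each joint
pendulum_oracle_loads <- function(traj, kin) {
  g <- c(0, 0, -9.81)
  par <- traj$par
  n <- nrow(traj$theta)
  out <- list()
  for (j in seq_len(par$n)) {           # joint j connects link j to parent
    segs <- j:par$n                     # subsystem distal of joint j
    pj <- kin[[j]]$prox
    F <- matrix(0, n, 3L); M <- matrix(0, n, 3L)
    for (k in segs) {
      m <- attr(kin[[k]], "mass")
      Iv <- attr(kin[[k]], "inertia")
      F <- F + m * matrix(g, n, 3L, byrow = TRUE) - m * kin[[k]]$com_acceleration
      for (t in seq_len(n)) {
        r <- kin[[k]]$com_position[t, ] - pj[t, ]
        R <- kin[[k]]$basis[, , t]
        Iw <- R %*% diag(Iv) %*% t(R)
        rot <- drop(Iw %*% kin[[k]]$alpha[t, ]) +
          cross3_test(kin[[k]]$omega[t, ], drop(Iw %*% kin[[k]]$omega[t, ]))
        M[t, ] <- M[t, ] + cross3_test(r, m * g) - rot -
          m * cross3_test(r, kin[[k]]$com_acceleration[t, ])
      }
    }
    out[[j]] <- list(force = F, moment = M)
  }
  out
}

cross3_test <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## package-side recursion on the same analytic kinematics
pendulum_recursion_loads <- function(kin) {
  par_of <- function(k) list(segment = kin[[k]]$segment,
                             mass = attr(kin[[k]], "mass"),
                             com_fraction = NA,
                             principal_inertia = attr(kin[[k]], "inertia"))
  nl <- length(kin)
  distal <- kin[[nl]]
  loads <- list()
  joints <- rev(paste0("j", seq_len(nl)))   # distal first
  loads[[joints[1L]]] <- wrist_net_force(NULL, par_of(nl), distal)
  if (nl == 2L)
    loads[[joints[2L]]] <- recurse_proximal(loads[[joints[1L]]], par_of(1L),
                                            kin[[1L]], joints[2L])
  segs <- rev(seq_len(nl))
  bsp <- lapply(segs, par_of)
  names(bsp) <- paste0("seg", segs)
  kin2 <- kin[segs]
  names(kin2) <- names(bsp)
  chain <- data.frame(joint = joints, segment = names(bsp),
                      stringsAsFactors = FALSE)
  loads <- net_joint_moments(loads, bsp, kin2, ext = NULL, chain = chain)
  loads
}

## standard two-link test case: rods released from horizontal
pendulum_par_2link <- function(L1 = 0.3, L2 = 0.25, m1 = 2.0, m2 = 1.5) {
  list(n = 2L, L1 = L1, L2 = L2, m1 = m1, m2 = m2,
       d1 = L1 / 2, d2 = L2 / 2,
       I1 = m1 * L1^2 / 12, I2 = m2 * L2^2 / 12,
       I1vec = c(m1 * L1^2 / 12, m1 * L1^2 / 12, 1e-5),
       I2vec = c(m2 * L2^2 / 12, m2 * L2^2 / 12, 1e-5))
}

pendulum_par_1link <- function(L = 0.3, m = 2.0) {
  list(n = 1L, L1 = L, m1 = m, d1 = L / 2, I1 = m * L^2 / 12,
       I1vec = c(m * L^2 / 12, m * L^2 / 12, 1e-5))
}
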