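#' External end-effector load
#'
#' 6-DoF force/torque time series from the end-effector sensor.  The
#' model's wrist equation applies a diagonal sign matrix (default
#' `diag(-1, -1, 1)`) to the external force, mapping the sensor convention
#' into the world coordinate system; the sign matrix is configurable and is
#' applied to the force only.
#'
#' @param force n x 3 matrix, N.
#' @param moment n x 3 matrix, N m (zeros when absent).
#' @param frame `"sensor"` or `"wcs"` tag.
#' @param sign_matrix 3 x 3 diagonal matrix with entries +-1.
#' @return object of class `external_load`.
#' @export
external_load <- function(force, moment = NULL, frame = c("sensor", "wcs"),
                          sign_matrix = diag(c(-1, -1, 1))) {
  frame <- match.arg(frame)
  force <- as.matrix(force)
  stopifnot(ncol(force) == 3L)
  if (is.null(moment)) moment <- matrix(0, nrow(force), 3L)
  moment <- as.matrix(moment)
  stopifnot(ncol(moment) == 3L, nrow(moment) == nrow(force))
  d <- diag(sign_matrix)
  if (!all(sign_matrix == diag(d)) || !all(abs(d) == 1))
    stop("sign_matrix must be diagonal with entries +1 or -1")
  structure(list(force = force, moment = moment, frame = frame,
                 sign_matrix = sign_matrix),
            class = "external_load")
}

#' Read an external load from a force-sensor CSV
#'
#' Columns `time_s, fx_N, fy_N, fz_N, mx_Nm, my_Nm, mz_Nm`, header required.
#'
#' @param path CSV file path.
#' @param ... passed to [external_load()].
#' @return an [external_load()] with attribute `time_s`.
#' @export
read_force_csv <- function(path, ...) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "fx_N", "fy_N", "fz_N", "mx_Nm", "my_Nm", "mz_Nm")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("force CSV ", path, " is missing columns: ", paste(miss, collapse = ", "))
  out <- external_load(as.matrix(tab[c("fx_N", "fy_N", "fz_N")]),
                       as.matrix(tab[c("mx_Nm", "my_Nm", "mz_Nm")]), ...)
  attr(out, "time_s") <- tab$time_s
  out
}

#' Resample an external load onto a kinematic time base
#'
#' Robot sensor and camera system are in general unsynchronized in rate;
#' the load is linearly interpolated onto the target times.
#'
#' @param load an [external_load()] with a `time_s` attribute (or with
#'   `time` given explicitly).
#' @param target_time_s numeric vector of kinematic sample times.
#' @param time_s source sample times, overriding the attribute.
#' @return an [external_load()] on the target time base.
#' @export
resample_load <- function(load, target_time_s, time_s = attr(load, "time_s")) {
  stopifnot(inherits(load, "external_load"))
  if (is.null(time_s)) stop("load carries no time base; supply time_s")
  interp <- function(m) apply(m, 2L, function(col)
    stats::approx(time_s, col, xout = target_time_s, rule = 2)$y)
  out <- external_load(interp(load$force), interp(load$moment),
                       frame = load$frame, sign_matrix = load$sign_matrix)
  attr(out, "time_s") <- target_time_s
  out
}

#' Gravity vector
#'
#' @param g numeric length-3, m/s^2; default world z-up with magnitude 9.81.
#' @return validated gravity vector.
#' @export
gravity_vector <- function(g = c(0, 0, -9.81)) {
  stopifnot(length(g) == 3L, all(is.finite(g)))
  if (abs(sqrt(sum(g^2)) - 9.81) > 0.5)
    warning("gravity magnitude ", sqrt(sum(g^2)), " m/s^2 is far from 9.81")
  g
}

## external force in the WCS: the sign matrix maps the sensor convention
## into world axes and is skipped when the load is already tagged as WCS
ext_force_wcs <- function(ext, n) {
  if (is.null(ext)) return(matrix(0, n, 3L))
  if (ext$frame == "sensor") ext$force %*% t(ext$sign_matrix) else ext$force
}

new_net_joint_load <- function(joint, force_wcs, moment_wcs = NULL,
                               force_bcs = NULL, moment_bcs = NULL,
                               valid = rep(TRUE, nrow(force_wcs)),
                               sample_rate = NA_real_) {
  structure(list(joint = joint, force_wcs = force_wcs,
                 moment_wcs = moment_wcs, force_bcs = force_bcs,
                 moment_bcs = moment_bcs, valid = valid,
                 sample_rate = sample_rate),
            class = "net_joint_load")
}

#' @export
print.net_joint_load <- function(x, ...) {
  pk <- max(sqrt(rowSums(x$force_wcs^2)), na.rm = TRUE)
  cat(sprintf("Net joint load '%s': %d samples, peak |F| = %.3f N%s\n",
              x$joint, nrow(x$force_wcs), pk,
              if (!is.null(x$force_bcs)) " (BCS available)" else ""))
  invisible(x)
}

#' Net joint force at the wrist
#'
#' The distal starting point of the inverse-dynamics recursion:
#' \deqn{F^{wcs}_W(t) = S\,F_{ext}(t) + m_h\,g - m_h\,a_h(t)}
#' with `S` the configured sensor sign matrix (default `diag(-1, -1, 1)`),
#' `m_h` the hand mass and `a_h` the acceleration of the hand's centre of
#' mass.  The reported force is the force exerted by the distal segment on
#' the proximal one, which is the convention that makes the static
#' humerothoracic force equal the supported weight.
#'
#' @param ext an [external_load()] or `NULL` for free movement
#'   (`F_ext = 0`).
#' @param hand `SegmentInertialParameters`-style entry for the hand (an
#'   element of a [estimate_segment_parameters()] result).
#' @param hand_kin `segment_kinematics` of the hand.
#' @param g gravity vector, see [gravity_vector()].
#' @return `net_joint_load` for the wrist (WCS force filled).
#' @export
wrist_net_force <- function(ext, hand, hand_kin, g = gravity_vector()) {
  if (is.null(hand$mass)) stop("hand segment parameters carry no mass")
  a <- hand_kin$com_acceleration
  n <- nrow(a)
  if (!is.null(ext)) {
    stopifnot(inherits(ext, "external_load"))
    if (nrow(ext$force) != n)
      stop(sprintf("time-base mismatch: external load has %d samples, kinematics %d; resample first",
                   nrow(ext$force), n))
  }
  fext_w <- ext_force_wcs(ext, n)
  f <- fext_w + matrix(g, n, 3L, byrow = TRUE) * hand$mass - hand$mass * a
  new_net_joint_load("wrist", f, valid = hand_kin$valid & !is.na(a[, 1L]),
                     sample_rate = hand_kin$sample_rate)
}

#' Carry the recursion one joint proximally
#'
#' Given the load already computed at the distal joint of `segment`, the
#' net force at its proximal joint is
#' `F_prox(t) = F_dist(t) + m g - m a(t)`, the segment's Newton balance
#' under the distal-on-proximal reporting convention.  Applied once with
#' the forearm (wrist -> elbow) and once with the upper arm
#' (elbow -> humerothoracic).
#'
#' @param distal_load `net_joint_load` at the segment's distal joint.
#' @param segment segment inertial parameters (mass used here).
#' @param segment_kin `segment_kinematics` of the spanning segment.
#' @param joint name of the proximal joint for the returned load.
#' @param g gravity vector.
#' @return `net_joint_load` at the proximal joint (WCS force filled).
#' @export
recurse_proximal <- function(distal_load, segment, segment_kin,
                             joint, g = gravity_vector()) {
  stopifnot(inherits(distal_load, "net_joint_load"))
  a <- segment_kin$com_acceleration
  n <- nrow(a)
  if (nrow(distal_load$force_wcs) != n)
    stop("time-base mismatch between distal load and segment kinematics")
  f <- distal_load$force_wcs +
    matrix(g, n, 3L, byrow = TRUE) * segment$mass - segment$mass * a
  new_net_joint_load(joint, f,
                     valid = distal_load$valid & segment_kin$valid & !is.na(a[, 1L]),
                     sample_rate = segment_kin$sample_rate)
}

#' Net joint moments by Newton-Euler recursion
#'
#' The source model computes moments but prints no moment equations; this
#' formulation is the package's own extension.  Per segment, the Euler
#' equation about the centre of mass with the rotational inertia term
#' `I alpha + omega x (I omega)` (inertia tensor rotated into the world
#' frame from the principal axes) yields the couple at the proximal joint;
#' moments are reported with the same distal-on-proximal convention as the
#' forces.  The external load acts at the hand's distal endpoint.
#'
#' @param loads named list of `net_joint_load` (wrist, elbow,
#'   humerothoracic) with WCS forces filled.
#' @param bsp segment parameters.
#' @param kin named list of `segment_kinematics`.
#' @param ext external load or `NULL`; acts on the first (most distal)
#'   segment of the chain.
#' @param chain data frame with columns `joint`, `segment` ordered distal
#'   to proximal; defaults to the arm chain.
#' @return `loads` with `moment_wcs` filled.
#' @export
net_joint_moments <- function(loads, bsp, kin, ext = NULL,
                              chain = data.frame(
                                joint = c("wrist", "elbow", "humerothoracic"),
                                segment = c("hand", "forearm", "upper_arm"),
                                stringsAsFactors = FALSE)) {
  chain <- chain[chain$joint %in% names(loads), , drop = FALSE]
  if (!nrow(chain)) stop("no joint of the chain is present in 'loads'")
  n <- nrow(loads[[chain$joint[1L]]]$force_wcs)
  m_ext <- if (is.null(ext)) matrix(0, n, 3L) else ext$moment
  f_ext_w <- ext_force_wcs(ext, n)
  M_dist <- matrix(0, n, 3L)
  F_dist <- matrix(0, n, 3L)
  p_dist_prev <- NULL
  for (k in seq_len(nrow(chain))) {
    jn <- chain$joint[k]; sn <- chain$segment[k]
    sk <- kin[[sn]]; sp <- bsp[[sn]]
    com <- sk$com_position
    M <- matrix(NA_real_, n, 3L)
    for (t in seq_len(n)) {
      if (anyNA(sk$omega[t, ]) || anyNA(sk$basis[, , t])) next
      R <- sk$basis[, , t]
      Iw <- R %*% diag(sp$principal_inertia) %*% t(R)
      rot <- Iw %*% sk$alpha[t, ] +
        skew(sk$omega[t, ]) %*% (Iw %*% sk$omega[t, ])
      Mt <- -drop(rot)
      ## action of the more-distal segment at the distal joint centre
      if (k > 1L) {
        Mt <- Mt + M_dist[t, ] +
          cross3(p_dist_prev[t, ] - com[t, ], F_dist[t, ])
      }
      ## external load, applied at the hand's distal endpoint
      if (k == 1L) {
        Mt <- Mt + m_ext[t, ] + cross3(sk$dist[t, ] - com[t, ], f_ext_w[t, ])
      }
      ## lever of the (reaction to the) reported proximal force
      Mt <- Mt - cross3(sk$prox[t, ] - com[t, ], loads[[jn]]$force_wcs[t, ])
      M[t, ] <- Mt
    }
    loads[[jn]]$moment_wcs <- M
    M_dist <- M
    F_dist <- loads[[jn]]$force_wcs
    p_dist_prev <- sk$prox
  }
  loads
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Express net joint loads in anatomical (body) axes
#'
#' Applies, per sample, the transpose of the cumulative joint rotation to
#' the world-frame force (and moment when present): `R_W` for the wrist,
#' `R_E` for the elbow, `R_S` for the humerothoracic joint.  Components are
#' ordered (flexion/extension, abduction/adduction, rotation).  Samples
#' with a missing rotation are flagged invalid.
#'
#' @param loads named list of `net_joint_load` with WCS parts filled.
#' @param chain list of `3 x 3 x n` arrays `R_S`, `R_E`, `R_W`, see
#'   [rotation_chain_series()].
#' @return `loads` with `force_bcs` (and `moment_bcs`) filled.
#' @export
express_in_body_axes <- function(loads, chain) {
  pick <- c(wrist = "R_W", elbow = "R_E", humerothoracic = "R_S")
  for (jn in names(loads)) {
    Rarr <- chain[[pick[[jn]]]]
    f <- loads[[jn]]$force_wcs
    n <- nrow(f)
    fb <- matrix(NA_real_, n, 3L)
    mb <- if (!is.null(loads[[jn]]$moment_wcs)) matrix(NA_real_, n, 3L) else NULL
    for (t in seq_len(n)) {
      R <- Rarr[, , t]
      if (anyNA(R)) {
        loads[[jn]]$valid[t] <- FALSE
        next
      }
      fb[t, ] <- drop(crossprod(R, f[t, ]))
      if (!is.null(mb)) mb[t, ] <- drop(crossprod(R, loads[[jn]]$moment_wcs[t, ]))
    }
    colnames(fb) <- c("flexion_extension", "abduction_adduction", "rotation")
    loads[[jn]]$force_bcs <- fb
    if (!is.null(mb)) colnames(mb) <- colnames(fb)
    loads[[jn]]$moment_bcs <- mb
  }
  loads
}

#' Full distal-to-proximal recursion over the arm
#'
#' Convenience wrapper running [wrist_net_force()], two
#' [recurse_proximal()] steps, [net_joint_moments()] and
#' [express_in_body_axes()].
#'
#' @param bsp segment parameters for `hand`, `forearm`, `upper_arm`.
#' @param kin named list of `segment_kinematics` for the same segments.
#' @param chain rotation chain arrays, see [rotation_chain_series()].
#' @param ext external load or `NULL`.
#' @param g gravity vector.
#' @param moments compute net joint moments as well.
#' @return named list of `net_joint_load` for `wrist`, `elbow`,
#'   `humerothoracic`.
#' @export
compute_net_joint_loads <- function(bsp, kin, chain, ext = NULL,
                                    g = gravity_vector(), moments = TRUE) {
  need <- c("hand", "forearm", "upper_arm")
  miss <- setdiff(need, intersect(names(bsp), names(kin)))
  if (length(miss))
    stop("missing segment parameters/kinematics for: ", paste(miss, collapse = ", "))
  loads <- list()
  loads$wrist <- wrist_net_force(ext, bsp$hand, kin$hand, g)
  loads$elbow <- recurse_proximal(loads$wrist, bsp$forearm, kin$forearm,
                                  "elbow", g)
  loads$humerothoracic <- recurse_proximal(loads$elbow, bsp$upper_arm,
                                           kin$upper_arm, "humerothoracic", g)
  if (moments) loads <- net_joint_moments(loads, bsp, kin, ext)
  express_in_body_axes(loads, chain)
}

#' Peak anatomical-axis forces across an internal-rotation sweep
#'
#' Summarises, per internal-rotation position (IRO), the humerothoracic
#' net joint force in body axes: the peak absolute force per anatomical
#' axis, the sign of each axis component at its peak, and the unit vector
#' of the force at the sample of peak magnitude (used to track the
#' direction change of the force with increasing IRO).
#'
#' @param loads_by_iro named list: `"<iro>"` -> humerothoracic
#'   `net_joint_load` (or a full loads list, from which the humerothoracic
#'   entry is taken).
#' @return data frame of class `iro_sweep`, one row per IRO level.
#' @export
sweep_peak_force <- function(loads_by_iro) {
  if (!length(loads_by_iro)) stop("empty IRO sweep")
  keys <- names(loads_by_iro)
  rows <- lapply(seq_along(loads_by_iro), function(i) {
    key <- keys[i]
    ld <- loads_by_iro[[i]]
    if (!inherits(ld, "net_joint_load")) ld <- ld$humerothoracic
    fb <- ld$force_bcs[ld$valid & stats::complete.cases(ld$force_bcs), , drop = FALSE]
    if (!nrow(fb)) stop("no valid samples for IRO level ", key)
    peak_ax <- apply(abs(fb), 2L, max)
    sign_ax <- vapply(1:3, function(a) sign(fb[which.max(abs(fb[, a])), a]),
                      numeric(1))
    nrm <- sqrt(rowSums(fb^2))
    u <- fb[which.max(nrm), ] / max(nrm)
    data.frame(iro_deg = as.numeric(key),
               peak_flexion_extension = peak_ax[1L],
               peak_abduction_adduction = peak_ax[2L],
               peak_rotation = peak_ax[3L],
               sign_flexion_extension = sign_ax[1L],
               sign_abduction_adduction = sign_ax[2L],
               sign_rotation = sign_ax[3L],
               peak_norm = max(nrm),
               ux = u[1L], uy = u[2L], uz = u[3L])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$iro_deg), ]
  rownames(out) <- NULL
  class(out) <- c("iro_sweep", "data.frame")
  out
}
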