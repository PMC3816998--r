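## Technical (cluster) frame from >= 3 non-collinear markers.
## Convention: x along marker1 -> marker2, plane normal from marker3,
## re-orthogonalized right-handed; origin at the cluster centroid.
technical_frame <- function(points, segment = "?", tol = 1e-10) {
  stopifnot(is.matrix(points), nrow(points) >= 3L, ncol(points) == 3L)
  if (any(!is.finite(points))) return(NULL)
  x <- points[2L, ] - points[1L, ]
  nx <- sqrt(sum(x^2))
  if (nx < tol) stop("degenerate marker cluster for segment '", segment,
                     "': coincident markers")
  x <- x / nx
  v <- points[3L, ] - points[1L, ]
  z <- c(x[2L] * v[3L] - x[3L] * v[2L],
         x[3L] * v[1L] - x[1L] * v[3L],
         x[1L] * v[2L] - x[2L] * v[1L])
  nz <- sqrt(sum(z^2))
  if (nz < tol) stop("degenerate marker cluster for segment '", segment,
                     "': collinear markers")
  z <- z / nz
  y <- c(z[2L] * x[3L] - z[3L] * x[2L],
         z[3L] * x[1L] - z[1L] * x[3L],
         z[1L] * x[2L] - z[2L] * x[1L])
  list(origin = colMeans(points), basis = cbind(x, y, z, deparse.level = 0))
}

#' Static calibration: joint centres and anatomical frame corrections
#'
#' Processes a static calibration trial in which, in addition to the rigid
#' marker clusters of every segment, markers sit on the joint centres
#' (shoulder, elbow, wrist) and on the hand's distal endpoint.  The joint
#' markers are removed for movement trials; this calibration expresses each
#' joint centre as a constant offset in the technical (cluster) frame of the
#' adjacent segments, from the time-average of the static trial.
#'
#' The static posture defines the neutral (zero-angle) pose: each segment's
#' anatomical frame during the static trial is the world frame, except for
#' forearm and hand, whose joint coordinate systems are rotated by +90°
#' about z relative to the shoulder system (the fixed shoulder-to-elbow
#' axis relabeling of the model).  The constant technical-to-anatomical
#' rotation is stored per segment.
#'
#' @param static_trial a [marker_trajectory()] of the static pose including
#'   joint markers.
#' @param marker_set marker model, see [default_marker_set()].
#' @return object of class `calibration_model`: per segment the cluster
#'   labels, the technical-to-anatomical rotation and the proximal/distal
#'   joint-centre offsets in the technical frame.
#' @export
calibrate <- function(static_trial, marker_set = default_marker_set()) {
  stopifnot(inherits(static_trial, "marker_trajectory"))
  mp <- mean_marker_positions(static_trial)
  need_joint <- unlist(marker_set$joints)
  missing <- setdiff(need_joint, rownames(mp))
  if (length(missing))
    stop("static trial is missing joint marker(s): ",
         paste(missing, collapse = ", "))
  segs <- names(marker_set$segments)
  model <- lapply(segs, function(seg) {
    labs <- marker_set$segments[[seg]]
    miss <- setdiff(labs, rownames(mp))
    if (length(miss))
      stop("static trial is missing cluster marker(s) for segment '", seg,
           "': ", paste(miss, collapse = ", "))
    tf <- technical_frame(mp[labs, , drop = FALSE], segment = seg)
    anat0 <- if (seg %in% c("forearm", "hand")) rot_z(90) else diag(3)
    topo <- marker_set$topology[[seg]]
    off <- function(joint) {
      p <- mp[marker_set$joints[[joint]], ]
      drop(crossprod(tf$basis, p - tf$origin))
    }
    list(segment = seg, markers = labs,
         R_corr = crossprod(tf$basis, anat0),
         prox_joint = unname(topo["proximal"]),
         dist_joint = unname(topo["distal"]),
         prox_offset = off(topo["proximal"]),
         dist_offset = off(topo["distal"]))
  })
  names(model) <- segs
  structure(list(segments = model, marker_set = marker_set),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model (", length(x$segments), " segments)\n", sep = "")
  for (s in x$segments)
    cat(sprintf("  %-10s cluster [%s]  joints %s->%s\n", s$segment,
                paste(s$markers, collapse = ","), s$prox_joint, s$dist_joint))
  invisible(x)
}

#' Reconstruct anatomical segment frames from a movement trial
#'
#' For each segment and sample, builds the technical frame from the marker
#' cluster, applies the calibrated technical-to-anatomical correction, and
#' reconstructs the proximal and distal joint centres from their calibrated
#' offsets.  Samples whose cluster markers are still missing after gap
#' filling are flagged invalid instead of raising.
#'
#' @param trial a [marker_trajectory()] movement trial (no joint markers
#'   required).
#' @param calibration a [calibrate()] result.
#' @param max_gap passed to [fill_gaps()].
#' @return named list of `segment_frame` objects with fields `origin`
#'   (n x 3, the proximal joint centre), `dist` (n x 3, distal endpoint),
#'   `basis` (3 x 3 x n orthonormal, det +1), `valid` (logical n) and
#'   `sample_rate`.
#' @export
build_segment_frames <- function(trial, calibration, max_gap = 5L) {
  stopifnot(inherits(trial, "marker_trajectory"),
            inherits(calibration, "calibration_model"))
  trial <- fill_gaps(trial, max_gap = max_gap)
  n <- dim(trial$positions)[1L]
  out <- lapply(calibration$segments, function(seg) {
    idx <- match(seg$markers, trial$labels)
    if (anyNA(idx))
      stop("movement trial is missing cluster marker(s) for segment '",
           seg$segment, "': ",
           paste(seg$markers[is.na(idx)], collapse = ", "))
    origin <- matrix(NA_real_, n, 3L)
    dist <- matrix(NA_real_, n, 3L)
    basis <- array(NA_real_, c(3L, 3L, n))
    valid <- rep(FALSE, n)
    for (t in seq_len(n)) {
      pts <- trial$positions[t, idx, , drop = TRUE]
      tf <- technical_frame(pts, segment = seg$segment)
      if (is.null(tf)) next
      basis[, , t] <- tf$basis %*% seg$R_corr
      origin[t, ] <- tf$origin + drop(tf$basis %*% seg$prox_offset)
      dist[t, ] <- tf$origin + drop(tf$basis %*% seg$dist_offset)
      valid[t] <- TRUE
    }
    structure(list(segment = seg$segment, origin = origin, dist = dist,
                   basis = basis, valid = valid,
                   sample_rate = trial$sample_rate),
              class = "segment_frame")
  })
  names(out) <- names(calibration$segments)
  out
}
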