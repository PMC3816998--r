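#' Labelled 3D marker trajectories
#'
#' Container for optoelectronic motion-capture marker data: a
#' `time x marker x 3` array of positions (m) in the world coordinate system
#' (WCS) sampled at a constant rate.  Missing samples (occlusions) are `NA`
#' and tracked in a gap mask.
#'
#' @param positions numeric array `n_samples x n_markers x 3`, metres, with
#'   marker names as the second dimnames.
#' @param sample_rate sampling rate in Hz, > 0.
#' @return object of class `marker_trajectory` with fields `positions`,
#'   `labels`, `sample_rate`, `gaps` (logical `n_samples x n_markers`).
#' @export
marker_trajectory <- function(positions, sample_rate) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3L] == 3L,
            is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0)
  labels <- dimnames(positions)[[2L]]
  if (is.null(labels)) stop("positions must carry marker names as dimnames[[2]]")
  gaps <- apply(positions, c(1L, 2L), function(p) any(!is.finite(p)))
  structure(list(positions = positions, labels = labels,
                 sample_rate = sample_rate, gaps = gaps),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("Marker trajectory: %d samples x %d markers @ %g Hz (%.2f s)\n",
              d[1L], d[2L], x$sample_rate, d[1L] / x$sample_rate))
  cat("  markers:", paste(x$labels, collapse = ", "), "\n")
  ng <- sum(x$gaps)
  if (ng) cat(sprintf("  %d gap samples\n", ng))
  invisible(x)
}

#' @export
dim.marker_trajectory <- function(x) dim(x$positions)

#' Default marker model of the upper-extremity segment chain
#'
#' Maps model segments to their technical marker clusters and joints to the
#' calibration joint markers.  Each segment carries a rigid cluster of four
#' markers; joint markers (`SJC` shoulder, `EJC` elbow, `WJC` wrist, `HTIP`
#' 3rd metacarpal head) are present only in the static calibration trial and
#' removed for movement trials.  Users may supply their own mapping in the
#' same structure to any function that accepts `marker_set`.
#'
#' @return list with `segments` (segment -> cluster marker labels), `joints`
#'   (joint -> marker label) and `topology` (segment -> proximal/distal
#'   joint names).
#' @export
default_marker_set <- function() {
  list(
    segments = list(
      thorax    = paste0("TH", 1:4),
      upper_arm = paste0("UA", 1:4),
      forearm   = paste0("FA", 1:4),
      hand      = paste0("HA", 1:4)),
    joints = list(shoulder = "SJC", elbow = "EJC", wrist = "WJC",
                  hand_tip = "HTIP"),
    topology = list(
      thorax    = c(proximal = "shoulder", distal = "shoulder"),
      upper_arm = c(proximal = "shoulder", distal = "elbow"),
      forearm   = c(proximal = "elbow",    distal = "wrist"),
      hand      = c(proximal = "wrist",    distal = "hand_tip")))
}

#' Read / write marker trajectories as wide-format CSV
#'
#' Columns `time_s, <label>_x, <label>_y, <label>_z` (metres), one header
#' row; the sample rate is taken from the time column (which must be
#' uniform).  Empty cells or NA denote occluded samples.
#'
#' @param path CSV file path.
#' @return [read_marker_csv()] returns a [marker_trajectory()];
#'   `write_marker_csv()` returns `path` invisibly.
#' @export
read_marker_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(tab)) stop("marker CSV must have a 'time_s' column")
  t <- tab$time_s
  if (length(t) < 2L) stop("marker CSV must contain at least two samples")
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L] + 1e-12)
    stop("time column of ", path, " is not uniformly sampled")
  cols <- setdiff(names(tab), "time_s")
  lab <- unique(sub("_[xyz]$", "", cols))
  miss <- setdiff(c(paste0(lab, "_x"), paste0(lab, "_y"), paste0(lab, "_z")), cols)
  if (length(miss))
    stop("marker CSV is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(tab)
  pos <- array(NA_real_, c(n, length(lab), 3L), dimnames = list(NULL, lab, c("x", "y", "z")))
  for (i in seq_along(lab)) {
    pos[, i, 1L] <- tab[[paste0(lab[i], "_x")]]
    pos[, i, 2L] <- tab[[paste0(lab[i], "_y")]]
    pos[, i, 3L] <- tab[[paste0(lab[i], "_z")]]
  }
  marker_trajectory(pos, sample_rate = 1 / dt[1L])
}

#' @rdname read_marker_csv
#' @param trajectory a [marker_trajectory()].
#' @param digits significant digits used when formatting (pinned for
#'   reproducible, diffable output).
#' @export
write_marker_csv <- function(trajectory, path, digits = 9L) {
  stopifnot(inherits(trajectory, "marker_trajectory"))
  n <- dim(trajectory$positions)[1L]
  out <- list(time_s = fmt_num((seq_len(n) - 1L) / trajectory$sample_rate, digits))
  for (i in seq_along(trajectory$labels)) {
    lab <- trajectory$labels[i]
    out[[paste0(lab, "_x")]] <- fmt_num(trajectory$positions[, i, 1L], digits)
    out[[paste0(lab, "_y")]] <- fmt_num(trajectory$positions[, i, 2L], digits)
    out[[paste0(lab, "_z")]] <- fmt_num(trajectory$positions[, i, 3L], digits)
  }
  utils::write.csv(as.data.frame(out, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x, digits = 9L) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[!is.finite(x)] <- NA
  out
}

#' Fill short marker gaps by linear interpolation
#'
#' Gaps of at most `max_gap` consecutive samples are filled per marker and
#' axis by linear interpolation; longer gaps (and leading/trailing gaps)
#' remain `NA` and keep their gap flag, so downstream frames are marked
#' invalid rather than crashing.
#'
#' @param trajectory a [marker_trajectory()].
#' @param max_gap longest run of missing samples that is interpolated.
#' @return a gap-filled [marker_trajectory()].
#' @export
fill_gaps <- function(trajectory, max_gap = 5L) {
  pos <- trajectory$positions
  n <- dim(pos)[1L]
  for (m in seq_len(dim(pos)[2L])) {
    bad <- trajectory$gaps[, m]
    if (!any(bad) || all(bad)) next
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      if (runs$lengths[r] > max_gap) next
      i0 <- starts[r] - 1L; i1 <- ends[r] + 1L
      if (i0 < 1L || i1 > n) next          # edge gaps stay missing
      idx <- starts[r]:ends[r]
      w <- (idx - i0) / (i1 - i0)
      for (a in 1:3)
        pos[idx, m, a] <- (1 - w) * pos[i0, m, a] + w * pos[i1, m, a]
    }
  }
  marker_trajectory(pos, trajectory$sample_rate)
}

## time-average marker position over a (static) trial, per marker
mean_marker_positions <- function(trajectory) {
  apply(trajectory$positions, c(2L, 3L), mean, na.rm = TRUE)
}
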