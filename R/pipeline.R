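#' Run the complete analysis pipeline on one movement trial
#'
#' Static calibration, segment frames, joint angles, filtered CoM
#' differentiation, distal-to-proximal recursion and the transform into
#' anatomical axes, in one call.  Inputs may be in-memory objects or file
#' paths (marker CSVs per [read_marker_csv()], force CSV per
#' [read_force_csv()]).
#'
#' @param markers movement-trial [marker_trajectory()] or CSV path.
#' @param static static-calibration [marker_trajectory()] or CSV path.
#' @param subject [subject_anthropometry()], [synthetic_subject()] or
#'   subject file path ([read_subject_file()]).
#' @param ext [external_load()], force CSV path, or `NULL` for free
#'   movement (`F_ext = 0`).
#' @param bsp_table regression table for segment parameters.
#' @param marker_set marker model, see [default_marker_set()].
#' @param cutoff_hz low-pass cutoff for differentiation (Hz).
#' @param g gravity vector.
#' @param moments also compute net joint moments.
#' @param output_dir when non-`NULL`, writes `joint_angles.csv`,
#'   `net_joint_loads.csv` and `manifest.json` there.
#' @param digits significant digits for file output (pinned for
#'   byte-reproducible files).
#' @return object of class `njf_analysis` with fields `angles`, `loads`,
#'   `bsp`, `warnings` and `manifest`.
#' @export
analyze_trial <- function(markers, static, subject, ext = NULL,
                          bsp_table = default_bsp_table(),
                          marker_set = default_marker_set(),
                          cutoff_hz = 6, g = gravity_vector(),
                          moments = TRUE, output_dir = NULL, digits = 9L) {
  if (is.character(markers)) markers <- read_marker_csv(markers)
  if (is.character(static)) static <- read_marker_csv(static)
  if (is.character(subject)) subject <- read_subject_file(subject)
  if (is.character(ext)) ext <- read_force_csv(ext)
  if (inherits(subject, "synthetic_subject")) {
    bsp <- subject$bsp
    anthro <- subject$anthropometry
    marker_set <- subject$marker_set
  } else {
    anthro <- subject
    bsp <- estimate_segment_parameters(subject, table = bsp_table)
  }
  warns <- validate_for_children(anthro, bsp_table)
  for (w in warns) warning(w, call. = FALSE)
  cal <- calibrate(static, marker_set)
  frames <- build_segment_frames(markers, cal)
  angles <- compute_joint_angles(frames)
  kin <- compute_com_kinematics(frames, bsp, cutoff_hz = cutoff_hz)
  chain <- rotation_chain_series(angles)
  n <- nrow(angles$humerothoracic$angles)
  if (!is.null(ext) && !is.null(attr(ext, "time_s")) &&
      nrow(ext$force) != n) {
    tt <- (seq_len(n) - 1L) / markers$sample_rate
    ext <- resample_load(ext, tt)
  }
  loads <- compute_net_joint_loads(bsp, kin, chain, ext = ext, g = g,
                                   moments = moments)
  manifest <- list(
    package = "armdyn",
    version = as.character(utils::packageVersion("armdyn")),
    sample_rate_hz = markers$sample_rate,
    n_samples = n,
    cutoff_hz = cutoff_hz,
    gravity = g,
    sign_matrix_diag = if (is.null(ext)) c(-1, -1, 1) else diag(ext$sign_matrix),
    external_load = !is.null(ext),
    strict_paper_matrices = isTRUE(getOption("armdyn.strict_paper_matrices", TRUE)),
    subject = list(body_mass_kg = anthro$body_mass,
                   stature_m = anthro$stature,
                   segment_lengths_m = as.list(anthro$segment_lengths)),
    bsp_provenance = attr(bsp, "provenance"),
    output_digits = digits,
    valid_samples = lapply(loads, function(l) sum(l$valid)),
    gimbal_samples = lapply(angles, function(a) sum(a$gimbal)),
    range_warnings = warns)
  out <- structure(list(angles = angles, loads = loads, bsp = bsp,
                        warnings = warns, manifest = manifest,
                        sample_rate = markers$sample_rate),
                   class = "njf_analysis")
  if (!is.null(output_dir)) write_analysis(out, output_dir, digits = digits)
  out
}

#' @export
print.njf_analysis <- function(x, ...) {
  cat("Upper-extremity net joint force analysis\n")
  cat(sprintf("  %d samples @ %g Hz\n", x$manifest$n_samples, x$sample_rate))
  for (l in x$loads) print(l)
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
summary.njf_analysis <- function(object, ...) {
  cat("Peak absolute humerothoracic force per anatomical axis (N):\n")
  fb <- object$loads$humerothoracic$force_bcs
  print(round(apply(abs(fb), 2L, max, na.rm = TRUE), 3))
  invisible(object)
}

#' Convert net joint loads to a long-format data frame
#'
#' One row per sample x joint x frame x axis, matching the on-disk CSV
#' schema `(time_s, joint, frame, axis, force_N, moment_Nm, valid)`.
#'
#' @param x a `net_joint_load` or named list of them.
#' @param sample_rate Hz (taken from the object when present).
#' @param ... unused.
#' @return data frame.
#' @export
as.data.frame.net_joint_load <- function(x, ..., sample_rate = x$sample_rate) {
  n <- nrow(x$force_wcs)
  t <- (seq_len(n) - 1L) / sample_rate
  axes_w <- c("x", "y", "z")
  axes_b <- c("flexion_extension", "abduction_adduction", "rotation")
  blocks <- list()
  for (a in 1:3) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      time_s = t, joint = x$joint, frame = "wcs", axis = axes_w[a],
      force_N = x$force_wcs[, a],
      moment_Nm = if (!is.null(x$moment_wcs)) x$moment_wcs[, a] else NA_real_,
      valid = x$valid, stringsAsFactors = FALSE)
    if (!is.null(x$force_bcs))
      blocks[[length(blocks) + 1L]] <- data.frame(
        time_s = t, joint = x$joint, frame = "bcs", axis = axes_b[a],
        force_N = x$force_bcs[, a],
        moment_Nm = if (!is.null(x$moment_bcs)) x$moment_bcs[, a] else NA_real_,
        valid = x$valid, stringsAsFactors = FALSE)
  }
  do.call(rbind, blocks)
}

write_analysis <- function(analysis, output_dir, digits = 9L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ## joint angles
  ang <- do.call(rbind, lapply(analysis$angles, function(a) {
    n <- nrow(a$angles)
    data.frame(time_s = (seq_len(n) - 1L) / a$sample_rate,
               joint = a$joint,
               flexion_extension_deg = a$angles[, 1L],
               abduction_adduction_deg = a$angles[, 2L],
               rotation_deg = a$angles[, 3L],
               gimbal = a$gimbal, valid = a$valid,
               stringsAsFactors = FALSE)
  }))
  num <- vapply(ang, is.numeric, logical(1))
  ang[num] <- lapply(ang[num], fmt_num, digits = digits)
  utils::write.csv(ang, file.path(output_dir, "joint_angles.csv"),
                   row.names = FALSE, quote = FALSE)
  ## net joint loads
  lds <- do.call(rbind, lapply(analysis$loads, as.data.frame))
  num <- vapply(lds, is.numeric, logical(1))
  lds[num] <- lapply(lds[num], fmt_num, digits = digits)
  utils::write.csv(lds, file.path(output_dir, "net_joint_loads.csv"),
                   row.names = FALSE, quote = FALSE)
  ## manifest
  mpath <- file.path(output_dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(analysis$manifest, mpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    writeLines(paste(names(analysis$manifest),
                     vapply(analysis$manifest, function(v)
                       paste(format(unlist(v)), collapse = " "), ""),
                     sep = ": "), mpath)
  }
  invisible(output_dir)
}

#' Summarise an internal-rotation sweep
#'
#' Produces the per-IRO peak-force table, a monotonicity verdict for the
#' flexion/extension-axis peak and a summary of the force-direction
#' migration along the grid.
#'
#' @param sweep an `iro_sweep` (see [sweep_peak_force()] /
#'   [run_iro_experiment()]).
#' @param tol numeric slack on the monotonicity check (N).
#' @return object of class `iro_report` with fields `table`, `verdict`
#'   (`"monotone"`, `"non-monotone"` or `"insufficient levels"`),
#'   `offending` (violating IRO pairs, if any) and `direction_deg`
#'   (angle in degrees between each level's peak-force direction and the
#'   first level's).
#' @export
report <- function(sweep, tol = 1e-9) {
  stopifnot(inherits(sweep, "iro_sweep"))
  tab <- as.data.frame(sweep)
  if (nrow(tab) < 2L) {
    verdict <- "insufficient levels"
    offending <- NULL
    direction <- 0
  } else {
    d <- diff(tab$peak_flexion_extension)
    bad <- which(d < -tol)
    if (length(bad)) {
      verdict <- "non-monotone"
      offending <- data.frame(iro_from = tab$iro_deg[bad],
                              iro_to = tab$iro_deg[bad + 1L],
                              drop_N = -d[bad])
    } else {
      verdict <- "monotone"
      offending <- NULL
    }
    u0 <- unlist(tab[1L, c("ux", "uy", "uz")])
    direction <- vapply(seq_len(nrow(tab)), function(i) {
      ui <- unlist(tab[i, c("ux", "uy", "uz")])
      acos(max(-1, min(1, sum(u0 * ui)))) * 180 / pi
    }, numeric(1))
  }
  structure(list(table = tab, verdict = verdict, offending = offending,
                 direction_deg = direction),
            class = "iro_report")
}

#' @export
print.iro_report <- function(x, ...) {
  cat("Internal-rotation sweep of humerothoracic net joint forces\n\n")
  cols <- c("iro_deg", "peak_flexion_extension", "peak_abduction_adduction",
            "peak_rotation", "peak_norm")
  tab <- x$table[cols]
  tab[-1] <- lapply(tab[-1], round, digits = 3)
  print(tab, row.names = FALSE)
  cat("\nflexion/extension-axis peak across the grid:", x$verdict, "\n")
  if (!is.null(x$offending)) {
    cat("  decreasing between IRO levels:\n")
    print(x$offending, row.names = FALSE)
  }
  if (length(x$direction_deg) > 1L)
    cat(sprintf("peak-force direction rotates by %.1f deg from first to last level\n",
                x$direction_deg[length(x$direction_deg)]))
  invisible(x)
}

#' @export
print.iro_sweep <- function(x, ...) {
  cat("IRO sweep (", nrow(x), " levels); peak humerothoracic |F| per anatomical axis [N]\n",
      sep = "")
  NextMethod()
}

#' @export
plot.iro_sweep <- function(x, ...) {
  graphics::matplot(x$iro_deg,
                    cbind(x$peak_flexion_extension, x$peak_abduction_adduction,
                          x$peak_rotation),
                    type = "b", pch = 19, lty = 1,
                    col = c("firebrick", "steelblue", "darkgreen"),
                    xlab = "internal rotation position [deg]",
                    ylab = "peak |F| humerothoracic [N]", ...)
  graphics::legend("topleft", bty = "n",
                   legend = c("flexion/extension", "abduction/adduction", "rotation"),
                   col = c("firebrick", "steelblue", "darkgreen"),
                   lty = 1, pch = 19)
  invisible(x)
}

#' @export
plot.net_joint_load <- function(x, frame = c("bcs", "wcs"), ...) {
  frame <- match.arg(frame)
  f <- if (frame == "bcs" && !is.null(x$force_bcs)) x$force_bcs else x$force_wcs
  t <- (seq_len(nrow(f)) - 1L) / x$sample_rate
  graphics::matplot(t, f, type = "l", lty = 1,
                    col = c("firebrick", "steelblue", "darkgreen"),
                    xlab = "time [s]", ylab = sprintf("F %s [N]", frame),
                    main = paste("net joint force:", x$joint), ...)
  invisible(x)
}
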