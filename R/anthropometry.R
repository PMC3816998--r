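#' Subject anthropometry
#'
#' Bundles the whole-body and per-segment measurements needed to personalize
#' the rigid-body model: body mass (kg), stature (m) and the lengths (m) of
#' the arm segments.  Segment lengths are measured joint centre to joint
#' centre; hand length runs from the wrist centre to the 3rd metacarpal head.
#'
#' @param body_mass body mass in kg, > 0.
#' @param stature standing height in m, > 0.
#' @param segment_lengths named numeric vector of segment lengths in m; must
#'   contain `upper_arm`, `forearm` and `hand`, each positive and smaller
#'   than the stature, and jointly shorter than the stature.
#' @return object of class `subject_anthropometry`.
#' @examples
#' subject_anthropometry(30, 1.35,
#'   c(upper_arm = 0.25, forearm = 0.20, hand = 0.15))
#' @export
subject_anthropometry <- function(body_mass, stature, segment_lengths) {
  stopifnot(is.numeric(body_mass), length(body_mass) == 1L, body_mass > 0,
            is.numeric(stature), length(stature) == 1L, stature > 0)
  required <- c("upper_arm", "forearm", "hand")
  missing <- setdiff(required, names(segment_lengths))
  if (length(missing))
    stop("segment_lengths is missing: ", paste(missing, collapse = ", "))
  if (any(segment_lengths <= 0))
    stop("all segment lengths must be strictly positive")
  if (any(segment_lengths >= stature))
    stop("each segment length must be smaller than the stature")
  if (sum(segment_lengths[required]) >= stature)
    stop("the summed arm segment lengths must be smaller than the stature")
  structure(
    list(body_mass = body_mass, stature = stature,
         segment_lengths = segment_lengths),
    class = "subject_anthropometry")
}

#' @export
print.subject_anthropometry <- function(x, ...) {
  cat("Subject anthropometry\n")
  cat(sprintf("  body mass: %.2f kg, stature: %.3f m\n", x$body_mass, x$stature))
  for (s in names(x$segment_lengths))
    cat(sprintf("  %-10s %.4f m\n", s, x$segment_lengths[[s]]))
  invisible(x)
}

#' Read a subject description from a key-value file
#'
#' Flat `key = value` (or `key: value`) text file with keys `mass_kg`,
#' `stature_m` and `<segment>_length_m` for each arm segment.
#'
#' @param path file path.
#' @return a [subject_anthropometry()] object.
#' @export
read_subject_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[:=]")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  names(vals) <- keys
  seg_keys <- grep("_length_m$", keys, value = TRUE)
  lens <- vals[seg_keys]
  names(lens) <- sub("_length_m$", "", seg_keys)
  subject_anthropometry(vals[["mass_kg"]], vals[["stature_m"]], lens)
}

#' Body segment parameter regression tables
#'
#' `default_bsp_table()` returns the coefficient table shipped with the
#' package: adult male mass regressions of Zatsiorsky and Seluyanov, with
#' centre-of-mass fractions and radii of gyration from de Leva's adjustment
#' of the same dataset.  `read_bsp_table()` reads a user table in the same
#' schema: CSV with columns `segment, quantity, b0, b_mass, b_stature`,
#' where each quantity `q` of a segment is evaluated as
#' `q = b0 + b_mass * body_mass + b_stature * stature` (mass in kg, stature
#' in m).  Required quantities per segment: `mass` (kg), `com_fraction`
#' (fraction of segment length from the proximal joint centre) and
#' `rgyr_x`, `rgyr_y`, `rgyr_z` (radii of gyration as fractions of segment
#' length about the flexion, abduction and longitudinal axes).
#'
#' @param path CSV file path.
#' @param provenance short string naming the source of the table.
#' @param mass_range,stature_range closed calibration intervals of the
#'   regression sample, used by [validate_for_children()].
#' @return data frame of class `bsp_table` with attributes `provenance`,
#'   `mass_range` and `stature_range`.
#' @export
read_bsp_table <- function(path, provenance = basename(path),
                           mass_range = c(50, 100),
                           stature_range = c(1.50, 1.90)) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("segment", "quantity", "b0", "b_mass", "b_stature")
  if (!all(need %in% names(tab)))
    stop("coefficient table must have columns: ", paste(need, collapse = ", "))
  structure(tab, class = c("bsp_table", "data.frame"),
            provenance = provenance,
            mass_range = mass_range, stature_range = stature_range)
}

#' @rdname read_bsp_table
#' @export
default_bsp_table <- function() {
  path <- system.file("extdata", "zatsiorsky_seluyanov.csv", package = "armdyn",
                      mustWork = TRUE)
  read_bsp_table(path,
                 provenance = "Zatsiorsky-Seluyanov adult male regressions; de Leva 1996 CoM/gyration adjustments")
}

coef_row <- function(table, segment, quantity) {
  i <- table$segment == segment & table$quantity == quantity
  if (!any(i))
    stop(sprintf("coefficient table '%s' has no row for segment '%s', quantity '%s'",
                 attr(table, "provenance") %||% "user", segment, quantity))
  unlist(table[which(i)[1L], c("b0", "b_mass", "b_stature")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate body segment parameters by linear regression
#'
#' Evaluates, for each requested segment, the linear forms
#' `q = b0 + b_mass * body_mass + b_stature * stature` for segment mass,
#' centre-of-mass fraction and the three radii of gyration, and converts the
#' radii to principal moments of inertia about the segment's anatomical axes
#' at the CoM: `I_k = mass * (rgyr_k * L)^2` with `L` the measured segment
#' length.  Deterministic given its inputs.
#'
#' @param subject a [subject_anthropometry()] object.
#' @param table a `bsp_table`; defaults to [default_bsp_table()].
#' @param segments character vector of segments to estimate; defaults to the
#'   dynamic segments of the arm model.
#' @return named list of class `bsp_set`; each element has `segment`,
#'   `mass` (kg), `com_fraction`, `length` (m) and `principal_inertia`
#'   (kg m^2, named x/y/z).
#' @examples
#' sub <- subject_anthropometry(70, 1.75,
#'   c(upper_arm = 0.32, forearm = 0.26, hand = 0.19))
#' estimate_segment_parameters(sub)
#' @export
estimate_segment_parameters <- function(subject, table = default_bsp_table(),
                                        segments = c("upper_arm", "forearm", "hand")) {
  stopifnot(inherits(subject, "subject_anthropometry"))
  missing <- setdiff(segments, names(subject$segment_lengths))
  if (length(missing))
    stop("subject has no length for segment(s): ", paste(missing, collapse = ", "))
  lin <- function(b) unname(b[1L] + b[2L] * subject$body_mass + b[3L] * subject$stature)
  out <- lapply(segments, function(seg) {
    m <- lin(coef_row(table, seg, "mass"))
    if (m <= 0)
      stop(sprintf("estimated mass for segment '%s' is non-positive (%.4f kg); subject outside regression range",
                   seg, m))
    f <- lin(coef_row(table, seg, "com_fraction"))
    if (f <= 0 || f >= 1)
      stop(sprintf("estimated CoM fraction for segment '%s' outside (0,1): %.4f", seg, f))
    L <- subject$segment_lengths[[seg]]
    r <- vapply(c("rgyr_x", "rgyr_y", "rgyr_z"),
                function(q) lin(coef_row(table, seg, q)), numeric(1))
    I <- m * (r * L)^2
    names(I) <- c("x", "y", "z")
    if (any(I < 0)) stop("negative moment of inertia for segment ", seg)
    if (any(I > sum(I) - I + 1e-12))
      stop("principal moments of segment ", seg, " violate the triangle inequality")
    list(segment = seg, mass = m, com_fraction = f, length = L,
         principal_inertia = I)
  })
  names(out) <- segments
  structure(out, class = "bsp_set", provenance = attr(table, "provenance"))
}

#' @export
print.bsp_set <- function(x, ...) {
  cat("Body segment parameters (", attr(x, "provenance") %||% "unknown source",
      ")\n", sep = "")
  for (p in x)
    cat(sprintf("  %-10s mass %6.3f kg  CoM %5.1f%%  I (%.2e, %.2e, %.2e) kg m^2\n",
                p$segment, p$mass, 100 * p$com_fraction,
                p$principal_inertia[1], p$principal_inertia[2],
                p$principal_inertia[3]))
  invisible(x)
}

#' Warn when a subject lies outside the regression calibration range
#'
#' The shipped regressions were calibrated on adults; applying them to
#' children is a documented extrapolation.  This check returns non-fatal
#' warnings (as a character vector) when body mass or stature fall outside
#' the closed calibration interval of the active table; it never blocks the
#' computation.
#'
#' @param subject a [subject_anthropometry()] object.
#' @param table the coefficient table whose calibration range applies.
#' @return character vector of warnings; empty when the subject is in range.
#' @export
validate_for_children <- function(subject, table = default_bsp_table()) {
  mr <- attr(table, "mass_range") %||% c(50, 100)
  sr <- attr(table, "stature_range") %||% c(1.50, 1.90)
  out <- character(0)
  bad <- character(0)
  if (subject$body_mass < mr[1L] || subject$body_mass > mr[2L])
    bad <- c(bad, sprintf("body_mass %.1f kg outside [%.0f, %.0f] kg",
                          subject$body_mass, mr[1L], mr[2L]))
  if (subject$stature < sr[1L] || subject$stature > sr[2L])
    bad <- c(bad, sprintf("stature %.2f m outside [%.2f, %.2f] m",
                          subject$stature, sr[1L], sr[2L]))
  if (length(bad))
    out <- paste0("subject outside adult calibration range of the regression table: ",
                  paste(bad, collapse = "; "))
  out
}
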