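## Zero-lag low-pass Butterworth.  A 2nd-order design run forward and
## backward gives the 4th-order zero-phase response standard in movement
## analysis.  Edge handling: the first sample is subtracted as baseline
## (making the filter exactly invariant under rigid translation of the
## signal), the series is extended at both ends by extrapolating a local
## least-squares quadratic (exact for constant, linear and quadratic
## motion), and start-up transients decay inside the padding before
## trimming.
butter_lowpass <- function(x, sample_rate, cutoff_hz) {
  if (is.null(cutoff_hz)) return(x)
  stopifnot(cutoff_hz > 0)
  if (cutoff_hz >= sample_rate / 2)
    stop(sprintf("filter cutoff (%g Hz) must be below the Nyquist rate (%g Hz)",
                 cutoff_hz, sample_rate / 2))
  n <- length(x)
  np <- min(n - 1L, ceiling(3 * sample_rate / cutoff_hz))
  if (np < 1L) return(x)
  x0 <- x[1L]
  y <- x - x0
  w <- min(n, max(5L, ceiling(sample_rate / cutoff_hz)))
  pre <- quad_extrapolate(y[w:1L], np)          # backwards from the start
  post <- quad_extrapolate(y[(n - w + 1L):n], np)
  bf <- signal::butter(2, cutoff_hz / (sample_rate / 2), type = "low")
  ext <- c(rev(pre), y, post)
  z <- signal::filter(bf, ext)
  z <- rev(signal::filter(bf, rev(z)))
  as.numeric(z[(np + 1L):(np + n)]) + x0
}

## least-squares quadratic through the window, evaluated 1..np beyond it
quad_extrapolate <- function(window, np) {
  w <- length(window)
  if (w < 3L) return(rep(window[w], np))
  i <- seq_len(w)
  fit <- stats::lm.fit(cbind(1, i, i^2), window)
  j <- w + seq_len(np)
  drop(cbind(1, j, j^2) %*% fit$coefficients)
}

## Second-order central difference; endpoints copied from their neighbours
## (one-sided estimate) and reported via the attached endpoint flag.
central_second_diff <- function(x, sample_rate) {
  n <- length(x)
  a <- rep(NA_real_, n)
  if (n >= 3L) {
    a[2:(n - 1L)] <- (x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]) * sample_rate^2
    a[1L] <- a[2L]
    a[n] <- a[n - 1L]
  }
  a
}

central_first_diff <- function(x, sample_rate) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 3L) {
    v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * sample_rate / 2
    v[1L] <- v[2L]
    v[n] <- v[n - 1L]
  }
  v
}

min_trial_samples <- function(sample_rate, cutoff_hz) {
  if (is.null(cutoff_hz)) 3L else max(9L, ceiling(sample_rate / cutoff_hz))
}

#' Segment centre-of-mass kinematics by filtered numerical differentiation
#'
#' Places each segment's centre of mass at `com_fraction` of the way from
#' the proximal joint centre to the distal endpoint, low-pass filters the
#' CoM trajectory (4th-order zero-lag Butterworth, default cutoff 6 Hz) and
#' differentiates twice by central differences.  Segment angular velocity
#' and acceleration are recovered from the (filtered) rotation series via
#' `omega = vee(Rdot R^T)`, `alpha = vee(Rddot R^T - (Rdot R^T)^2)`.
#' Endpoint samples use one-sided estimates and are flagged.
#'
#' @param frames named list of `segment_frame` objects.
#' @param bsp [estimate_segment_parameters()] result (supplies CoM
#'   fractions).
#' @param cutoff_hz low-pass cutoff in Hz; `NULL` disables filtering (for
#'   noise-free synthetic data).
#' @return named list of `segment_kinematics` objects with fields
#'   `com_position`, `com_velocity`, `com_acceleration` (n x 3, m, m/s,
#'   m/s^2), `omega`, `alpha` (n x 3, rad/s, rad/s^2), `prox`, `dist`,
#'   `basis`, `valid`, `endpoint` (logical n) and `sample_rate`.
#' @export
compute_com_kinematics <- function(frames, bsp, cutoff_hz = 6) {
  stopifnot(inherits(bsp, "bsp_set"))
  out <- lapply(names(bsp), function(seg) {
    if (!seg %in% names(frames))
      stop("no segment frames available for segment '", seg, "'")
    fr <- frames[[seg]]
    fs <- fr$sample_rate
    n <- nrow(fr$origin)
    nmin <- min_trial_samples(fs, cutoff_hz)
    if (n < nmin)
      stop(sprintf("trial too short for differentiation: %d samples, need >= %d at %g Hz (cutoff %s Hz)",
                   n, nmin, fs, format(cutoff_hz)))
    f <- bsp[[seg]]$com_fraction
    com <- fr$origin + f * (fr$dist - fr$origin)
    comf <- apply(com, 2L, butter_lowpass, sample_rate = fs, cutoff_hz = cutoff_hz)
    vel <- apply(comf, 2L, central_first_diff, sample_rate = fs)
    acc <- apply(comf, 2L, central_second_diff, sample_rate = fs)
    ## angular kinematics from the rotation series
    Rf <- fr$basis
    if (!is.null(cutoff_hz)) {
      Rf <- array(apply(matrix(fr$basis, nrow = 9L), 1L, function(row)
        butter_lowpass(row, fs, cutoff_hz)), dim = c(n, 3L, 3L))
      Rf <- aperm(Rf, c(2L, 3L, 1L))
    }
    Rd <- array(NA_real_, dim(Rf)); Rdd <- array(NA_real_, dim(Rf))
    for (i in 1:3) for (j in 1:3) {
      Rd[i, j, ] <- central_first_diff(Rf[i, j, ], fs)
      Rdd[i, j, ] <- central_second_diff(Rf[i, j, ], fs)
    }
    omega <- matrix(NA_real_, n, 3L); alpha <- matrix(NA_real_, n, 3L)
    for (t in seq_len(n)) {
      if (anyNA(Rd[, , t])) next
      W <- Rd[, , t] %*% t(Rf[, , t])
      W <- (W - t(W)) / 2
      A <- Rdd[, , t] %*% t(Rf[, , t]) - W %*% W
      A <- (A - t(A)) / 2
      omega[t, ] <- vee(W)
      alpha[t, ] <- vee(A)
    }
    endpoint <- rep(FALSE, n); endpoint[c(1L, n)] <- TRUE
    structure(list(segment = seg, com_position = com, com_velocity = vel,
                   com_acceleration = acc, omega = omega, alpha = alpha,
                   prox = fr$origin, dist = fr$dist, basis = fr$basis,
                   valid = fr$valid, endpoint = endpoint, sample_rate = fs),
              class = "segment_kinematics")
  })
  names(out) <- names(bsp)
  out
}
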