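## Small fixture builders shared across tests.

## subject with round numbers inside the adult calibration range
adult_subject <- function() {
  subject_anthropometry(70, 1.75,
                        c(upper_arm = 0.32, forearm = 0.26, hand = 0.19))
}

child_subject <- function() {
  subject_anthropometry(30, 1.35,
                        c(upper_arm = 0.25, forearm = 0.20, hand = 0.15))
}

## in-memory coefficient table with the read_bsp_table schema
make_bsp_table <- function(rows, mass_range = c(50, 100),
                           stature_range = c(1.50, 1.90)) {
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  structure(tab, class = c("bsp_table", "data.frame"),
            provenance = "test fixture",
            mass_range = mass_range, stature_range = stature_range)
}

bsp_rows_for <- function(segment, mass_b = c(0.5, 0, 0)) {
  list(
    list(segment = segment, quantity = "mass", b0 = mass_b[1],
         b_mass = mass_b[2], b_stature = mass_b[3]),
    list(segment = segment, quantity = "com_fraction", b0 = 0.5, b_mass = 0,
         b_stature = 0),
    list(segment = segment, quantity = "rgyr_x", b0 = 0.3, b_mass = 0,
         b_stature = 0),
    list(segment = segment, quantity = "rgyr_y", b0 = 0.28, b_mass = 0,
         b_stature = 0),
    list(segment = segment, quantity = "rgyr_z", b0 = 0.15, b_mass = 0,
         b_stature = 0))
}

intercept_table <- function(k = 0.5) {
  make_bsp_table(c(bsp_rows_for("upper_arm", c(k, 0, 0)),
                   bsp_rows_for("forearm", c(k, 0, 0)),
                   bsp_rows_for("hand", c(k, 0, 0))))
}

## static segment_kinematics at a given posture (accelerations identically 0)
static_kinematics <- function(subject, shoulder_angles = c(0, 0, 0),
                              n = 5L, sample_rate = 100) {
  ang <- list(
    humerothoracic = structure(
      joint_angle_series("humerothoracic",
                         matrix(shoulder_angles, n, 3L, byrow = TRUE),
                         sample_rate),
      deriv1 = matrix(0, n, 3L), deriv2 = matrix(0, n, 3L)),
    elbow = structure(
      joint_angle_series("elbow", matrix(0, n, 3L), sample_rate),
      deriv1 = matrix(0, n, 3L), deriv2 = matrix(0, n, 3L)),
    wrist = structure(
      joint_angle_series("wrist", matrix(0, n, 3L), sample_rate),
      deriv1 = matrix(0, n, 3L), deriv2 = matrix(0, n, 3L)))
  forward_kinematics(ang, subject)
}

total_arm_mass <- function(subject)
  sum(vapply(subject$bsp, function(p) p$mass, numeric(1)))

random_angle_triples <- function(n, lim = 80, seed = 42L) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -lim, lim), ncol = 3L)
}
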