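# Nine-accelerometer kinematics: reconstruction of 6-DOF head motion about
# the centre of mass from a 3-2-2-2 array, channel-frequency-class phaseless
# low-pass filtering, and forward integration to velocities.

#' Nine-accelerometer (3-2-2-2) transform to COM kinematics
#'
#' Reconstructs angular acceleration about each anatomical axis from the
#' symmetric paired-arm channel combination that cancels the
#' angular-velocity product (centripetal) terms exactly for rigid-body
#' motion:
#' \deqn{\alpha_x = \tfrac12\left[(a_z^{(y)} - a_z^{(0)})/\rho_y -
#'       (a_y^{(z)} - a_y^{(0)})/\rho_z\right]}
#' and cyclic permutations, where superscripts denote the arm a channel sits
#' on (0 = array centre). No integration or differentiation of angular
#' velocity is involved. COM linear acceleration is read from the central
#' triax.
#'
#' @param recording An `impact_recording` whose geometry is a valid 3-2-2-2
#'   array.
#' @return List with `time`, `a_cm` (n x 3, m/s^2) and `alpha` (n x 3,
#'   rad/s^2).
#' @export
nap_transform <- function(recording) {
  geom <- recording$geometry
  validate_nap_geometry(geom)
  ch <- recording$channels
  if (ncol(ch) != 9L) stop("recording must carry 9 channels")
  s <- geom$sensors
  pick <- function(label) {
    i <- match(label, s$label)
    if (is.na(i)) stop("geometry missing channel: ", label)
    ch[, s$channel[i]]
  }
  rho <- geom$rho
  a_cm <- cbind(x = pick("cx"), y = pick("cy"), z = pick("cz"))
  alpha <- cbind(
    x = ((pick("yz") - pick("cz")) / rho[2] - (pick("zy") - pick("cy")) / rho[3]) / 2,
    y = ((pick("zx") - pick("cx")) / rho[3] - (pick("xz") - pick("cz")) / rho[1]) / 2,
    z = ((pick("xy") - pick("cy")) / rho[1] - (pick("yx") - pick("cx")) / rho[2]) / 2
  )
  list(time = recording$time, a_cm = a_cm, alpha = alpha)
}

#' Filter specification for channel-frequency-class low-pass filtering
#'
#' @param cfc Channel frequency class (dimensionless); class 1000
#'   corresponds to a nominal -3 dB frequency of 1650 Hz per pass.
#' @param fs Sampling rate (Hz); must exceed twice the nominal cutoff.
#' @return Object of class `filter_spec` with `cfc`, `fs` and the nominal
#'   per-pass cutoff `fc` (Hz).
#' @export
filter_spec <- function(cfc = 1000, fs = 1e5) {
  if (cfc <= 0) stop("CFC class must be positive")
  fc <- 1.65 * cfc
  if (fs <= 2 * fc) {
    stop(sprintf(paste0("sampling rate %g Hz too low for CFC %g: ",
                        "must exceed %g Hz"), fs, cfc, 2 * fc))
  }
  structure(list(cfc = cfc, fs = fs, fc = fc), class = "filter_spec")
}

#' Phaseless channel-frequency-class low-pass filter
#'
#' Two-pole Butterworth low-pass (nominal -3 dB at `1.65 * cfc` Hz per pass)
#' applied forward and then backward, giving a four-pole zero-phase net
#' response with unit DC gain. Ends are extended by odd reflection before
#' filtering to suppress warm-up transients.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param spec A [filter_spec()].
#' @return Filtered series, same shape as `x`.
#' @export
cfc_filter <- function(x, spec = filter_spec()) {
  if (is.matrix(x)) {
    out <- apply(x, 2, cfc_filter, spec = spec)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  if (n < 8L) stop("series too short for filter warm-up")
  bf <- signal::butter(2, spec$fc / (spec$fs / 2), type = "low")
  np <- min(n - 1L, max(9L, 3L * round(spec$fs / spec$fc)))
  pre <- 2 * x[1] - x[seq(np + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - np)]
  xp <- c(pre, x, post)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y <- as.numeric(y)[np + seq_len(n)]
  y
}

#' Cumulative trapezoidal integration of acceleration to velocity
#'
#' @param accel Numeric vector or n x 3 matrix of accelerations.
#' @param time Uniform time base (s).
#' @param initial Initial velocity (scalar, recycled across columns, or one
#'   value per column). The first output sample equals it exactly.
#' @return Velocity series, same shape as `accel`.
#' @export
integrate_velocity <- function(accel, time, initial = 0) {
  check_uniform_time(time)
  if (is.matrix(accel)) {
    initial <- rep(initial, length.out = ncol(accel))
    out <- vapply(seq_len(ncol(accel)),
                  function(j) integrate_velocity(accel[, j], time, initial[j]),
                  numeric(length(time)))
    dimnames(out) <- dimnames(accel)
    return(out)
  }
  if (length(accel) != length(time)) stop("series and time base differ in length")
  as.numeric(initial + pracma::cumtrapz(time, accel))
}

#' Pointwise Euclidean resultant of a three-axis series
#'
#' @param xyz An n x 3 matrix (or three equal-length vectors passed as a
#'   data frame / matrix).
#' @return Nonnegative numeric vector of pointwise norms.
#' @export
resultant <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("resultant expects three aligned axis series")
  sqrt(rowSums(xyz^2))
}

#' Process a nine-channel recording into filtered COM kinematics
#'
#' The processing window starts 5 ms before the first sample at which the
#' resultant centre-of-mass acceleration exceeds the trigger level (5 g by
#' default). The per-channel mean of the pre-trigger segment is subtracted
#' first (accelerometer bias removal). The nine-accelerometer transform is
#' applied, both accelerations are low-pass filtered per the channel
#' frequency class, and velocities are obtained by trapezoidal integration
#' from zero initial conditions (angular velocity starts at rest; linear
#' velocity excursions are initial-value invariant, and the gate-measured
#' impact speed is reintroduced when peak resultant linear velocity is
#' computed downstream).
#'
#' @param recording An `impact_recording`.
#' @param spec A [filter_spec()]; its `fs` is replaced by the recording rate.
#' @param trigger_g Trigger level in g on resultant COM acceleration.
#' @param pretrigger Pre-trigger interval retained before the trigger (s).
#' @return Object of class `head_kinematics`: `time`, `a_cm`, `alpha`, `v`,
#'   `omega` (n x 3), `v_i`, `location`, `fs`.
#' @export
process_recording <- function(recording, spec = NULL, trigger_g = 5,
                              pretrigger = 0.005) {
  dt <- check_uniform_time(recording$time)
  fs <- 1 / dt
  if (is.null(spec)) spec <- filter_spec(1000, fs) else spec <- filter_spec(spec$cfc, fs)
  raw <- nap_transform(recording)
  res <- resultant(raw$a_cm)
  thr <- trigger_g * standard_gravity()
  hit <- which(res > thr)
  start <- 1L
  bias <- rep(0, 9)
  if (length(hit)) {
    trig <- hit[1]
    start <- max(1L, trig - as.integer(round(pretrigger * fs)))
    # bias from the quiet segment preceding the retained window, so the
    # sub-trigger onset of the pulse itself does not leak into the estimate
    if (start > 2L) {
      bias <- colMeans(recording$channels[seq_len(start - 1L), , drop = FALSE])
    }
  }
  rec2 <- recording
  rec2$channels <- sweep(recording$channels, 2, bias)
  rec2$channels <- rec2$channels[start:nrow(rec2$channels), , drop = FALSE]
  rec2$time <- recording$time[start:length(recording$time)]
  kin <- nap_transform(rec2)
  a_f <- cfc_filter(kin$a_cm, spec)
  al_f <- cfc_filter(kin$alpha, spec)
  v <- integrate_velocity(a_f, kin$time, 0)
  om <- integrate_velocity(al_f, kin$time, 0)
  structure(list(time = kin$time, a_cm = a_f, alpha = al_f, v = v, omega = om,
                 v_i = recording$v_i, location = recording$location, fs = fs),
            class = "head_kinematics")
}

#' Write head kinematics to CSV
#'
#' @param kin A `head_kinematics` object.
#' @param path Output path; header
#'   `t,ax,ay,az,alx,aly,alz,vx,vy,vz,wx,wy,wz`.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(kin, path) {
  df <- data.frame(t = kin$time,
                   ax = kin$a_cm[, 1], ay = kin$a_cm[, 2], az = kin$a_cm[, 3],
                   alx = kin$alpha[, 1], aly = kin$alpha[, 2], alz = kin$alpha[, 3],
                   vx = kin$v[, 1], vy = kin$v[, 2], vz = kin$v[, 3],
                   wx = kin$omega[, 1], wy = kin$omega[, 2], wz = kin$omega[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
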