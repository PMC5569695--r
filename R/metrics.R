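# Reduction of kinematic time series to the thirteen scalar predictors used
# in the regression stage, plus severity and axonal-injury annotations.
#
# Conventions (applied identically to linear and angular quantities):
#   directional excursion  dq_i = max(q_i(t)) - min(q_i(t))
#   directional peak        q_i = max |q_i(t)|
#   resultant peak          q_R = max_t ||q(t)||
#   excursion resultant    dq_R = sqrt(dq_x^2 + dq_y^2 + dq_z^2)
# Maxima are taken irrespective of when they occur in the window.

#' Names of the thirteen kinematic predictors
#'
#' @return Character vector: `peak_g`, `v_i`, `dv_r`, `v_r`, `alpha_r`,
#'   `dw_x`, `dw_y`, `dw_z`, `dw_r`, `w_x`, `w_y`, `w_z`, `w_r`.
#' @export
kinematic_predictors <- function() {
  c("peak_g", "v_i", "dv_r", "v_r", "alpha_r",
    "dw_x", "dw_y", "dw_z", "dw_r", "w_x", "w_y", "w_z", "w_r")
}

#' Extract the thirteen scalar kinematic metrics from head kinematics
#'
#' The gate-measured impact speed is carried through as `v_i`, never
#' recomputed from integration. Peak resultant linear velocity `v_r` is
#' evaluated on the velocity series re-initialized with the gate speed along
#' the (vertical) drop axis; all excursion quantities are initial-value
#' invariant and use the zero-initialized series.
#'
#' @param kin A `head_kinematics` object.
#' @param v_i Gate-measured impact speed (m/s); defaults to the value stored
#'   in `kin`.
#' @param location Impact location label; defaults to the stored value.
#' @return One-row data frame with the 13 predictors plus `location`,
#'   `severity` and `dai`.
#' @export
extract_metrics <- function(kin, v_i = kin$v_i, location = kin$location) {
  if (length(kin$time) == 0L) stop("empty processing window")
  exc <- function(m) apply(m, 2, function(x) max(x) - min(x))
  pk <- function(m) apply(m, 2, function(x) max(abs(x)))
  dv <- exc(kin$v)
  dw <- exc(kin$omega)
  wpk <- pk(kin$omega)
  v0 <- c(0, 0, -as.numeric(v_i))
  v_init <- sweep(kin$v, 2, -v0)   # add initial velocity along the drop axis
  out <- data.frame(
    peak_g = max(resultant(kin$a_cm)) / standard_gravity(),
    v_i = as.numeric(v_i),
    dv_r = sqrt(sum(dv^2)),
    v_r = max(resultant(v_init)),
    alpha_r = max(resultant(kin$alpha)),
    dw_x = dw[1], dw_y = dw[2], dw_z = dw[3],
    dw_r = sqrt(sum(dw^2)),
    w_x = wpk[1], w_y = wpk[2], w_z = wpk[3],
    w_r = max(resultant(kin$omega)),
    location = location,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$severity <- classify_severity(out$peak_g)
  out$dai <- flag_dai(out$dw_r)
  out
}

#' Severity bin from peak resultant linear acceleration
#'
#' Partitions `[0, Inf)` into `<45 g`, `45-80 g` and `>80 g`. Boundary
#' convention: 45 g falls in the middle bin, 80 g falls in the middle bin
#' (bins are `[0,45)`, `[45,80]`, `(80,Inf)`).
#'
#' @param peak_g Nonnegative numeric vector (g units).
#' @return Factor with levels `<45 g`, `45-80 g`, `>80 g`.
#' @export
classify_severity <- function(peak_g) {
  if (any(peak_g < 0)) stop("peak_g must be nonnegative")
  lev <- c("<45 g", "45-80 g", ">80 g")
  bin <- ifelse(peak_g < 45, lev[1], ifelse(peak_g <= 80, lev[2], lev[3]))
  factor(bin, levels = lev)
}

#' Diffuse-axonal-injury capability flag
#'
#' True iff the resultant angular-velocity change strictly exceeds the
#' injury-capable level of 46.5 rad/s.
#'
#' @param dw_r Nonnegative resultant angular-velocity change (rad/s).
#' @param threshold Threshold (rad/s).
#' @return Logical vector.
#' @export
flag_dai <- function(dw_r, threshold = 46.5) {
  dw_r > threshold
}
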