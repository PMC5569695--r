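# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller-visible RNG state so that seeded generator
#' calls do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-record seed from a master seed
#'
#' One master seed governs a whole synthetic study; each record draws from an
#' independent stream keyed by its index so any record can be regenerated in
#' isolation. Kept below 2^31 so the result is a valid integer seed.
#'
#' @param seed Master seed (integer).
#' @param index Record index (1-based) or any small integer stream key.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  mixed <- ((as.double(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((mixed + as.double(index) * 7919) %% 2147483647)
}

# Haversine (sin^2) pulse: zero outside [t0, t0 + duration], peak `amp` at the
# midpoint. Integral over the pulse is amp * duration / 2.
haversine_pulse <- function(t, amp, t0, duration) {
  u <- (t - t0) / duration
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- amp * sin(pi * u[inside])^2
  out
}

# Running integral of a haversine pulse (analytic): amp * (tau/2 -
# duration * sin(2 pi tau / duration) / (4 pi)) inside the pulse, then
# amp * duration / 2 after it.
haversine_integral <- function(t, amp, t0, duration) {
  tau <- pmin(pmax(t - t0, 0), duration)
  amp * (tau / 2 - duration * sin(2 * pi * tau / duration) / (4 * pi))
}

# Uniform-time-base check with a relative tolerance on the step.
check_uniform_time <- function(time, what = "time base") {
  if (length(time) < 2L) stop(what, " must contain at least two samples")
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
    stop(what, " must be uniformly sampled")
  }
  dt[1]
}

# Cross product for 3-vectors.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Standard gravity used for the peak-g conversion
#'
#' @return Standard gravity in m/s^2 (9.80665).
#' @export
standard_gravity <- function() 9.80665
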