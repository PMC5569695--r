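# Shared fixtures and independent oracles used across the suite.

# Small study configuration for fast tests.
quick_config <- function(n = 12, seed = 101, ...) {
  synth_config(n = n, seed = seed, ...)
}

# Independent pointwise rigid-body forward model: a sensor at position r with
# sensing axis nvec reads (a_cm + alpha x r + omega x (omega x r)) . nvec.
# Written as an explicit per-sample loop with R's own cross products, kept
# separate from the vectorized implementation it checks.
oracle_channel <- function(motion, r, nvec) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  vapply(seq_along(motion$time), function(k) {
    a <- motion$a_cm[k, ]
    al <- motion$alpha[k, ]
    om <- motion$omega[k, ]
    sum((a + cross(al, r) + cross(om, cross(om, r))) * nvec)
  }, numeric(1))
}

# Hand-built rigid motion (no generator involved) for transform checks.
manual_motion <- function(time, a_cm, alpha, omega, location = "front", v_i = 3) {
  structure(list(time = time, a_cm = a_cm, alpha = alpha, omega = omega,
                 location = location, v_i = v_i,
                 params = NULL), class = "ground_truth_motion")
}

# Hand-built head_kinematics object for metric-extraction checks.
manual_kinematics <- function(time, a_cm = NULL, alpha = NULL, v = NULL,
                              omega = NULL, v_i = 0, location = "front") {
  z <- matrix(0, nrow = length(time), ncol = 3)
  structure(list(time = time,
                 a_cm = if (is.null(a_cm)) z else a_cm,
                 alpha = if (is.null(alpha)) z else alpha,
                 v = if (is.null(v)) z else v,
                 omega = if (is.null(omega)) z else omega,
                 v_i = v_i, location = location, fs = 1 / diff(time[1:2])),
            class = "head_kinematics")
}

# Brute-force strain reducers: plain double loops over elements and samples.
oracle_csdm <- function(history, threshold = 0.15) {
  qual <- 0
  for (j in seq_len(ncol(history$strain))) {
    peak <- -Inf
    for (k in seq_len(nrow(history$strain))) {
      peak <- max(peak, history$strain[k, j])
    }
    if (peak >= threshold) qual <- qual + history$volumes[j]
  }
  qual / sum(history$volumes)
}

oracle_mps <- function(history) {
  best <- list(value = -Inf, element = NA, time = NA)
  for (k in seq_len(nrow(history$strain))) {      # time-major: earliest first
    for (j in seq_len(ncol(history$strain))) {    # then lowest element id
      if (history$strain[k, j] > best$value) {
        best <- list(value = unname(history$strain[k, j]), element = j,
                     time = history$time[k])
      }
    }
  }
  best
}

# Random strain history (not via the generator) for reducer equivalence.
random_history <- function(n_time = 40, n_elements = 8) {
  time <- seq(0, by = 0.002, length.out = n_time)
  strain <- matrix(runif(n_time * n_elements, -0.05, 0.35), n_time, n_elements)
  strain_history(time, strain, volumes = runif(n_elements, 0.5, 2),
                 regions = sample(letters[1:3], n_elements, replace = TRUE))
}
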