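test_that("motion generation is deterministic and respects the null pulse", {
  cfg <- quick_config()
  m1 <- generate_motion(cfg, 4)
  m2 <- generate_motion(cfg, 4)
  expect_identical(m1, m2)
  m3 <- generate_motion(quick_config(seed = 102), 4)
  expect_false(isTRUE(all.equal(m1$alpha, m3$alpha)))

  null <- generate_motion(quick_config(amplitude_scale = 0), 2)
  expect_true(all(null$a_cm == 0))
  expect_true(all(null$alpha == 0))
  expect_true(all(null$omega == 0))
})

test_that("angular velocity is the running integral of angular acceleration", {
  cfg <- quick_config()
  for (i in c(1, 5, 9)) {
    m <- generate_motion(cfg, i)
    peak <- max(abs(m$omega))
    for (ax in 1:3) {
      num <- integrate_velocity(m$alpha[, ax], m$time, 0)
      # analytic integral vs trapezoid: agreement to within quadrature error
      expect_lt(max(abs(m$omega[, ax] - num)), 1e-5 * peak)
    }
  }
})

test_that("haversine angular pulse integrates to amp * duration / 2", {
  # analytic integral of A sin^2(pi t / T) over [0, T] is A T / 2; checked
  # against numeric quadrature at the generator's own sampling rate
  t <- seq(0, 0.02, by = 1e-5)
  A <- 3000; T <- 0.008
  pulse <- headkin:::haversine_pulse(t, A, 0.002, T)
  expect_equal(max(headkin:::haversine_integral(t, A, 0.002, T)), A * T / 2,
               tolerance = 1e-12)
  expect_equal(max(integrate_velocity(pulse, t, 0)), A * T / 2,
               tolerance = 1e-6)
})

test_that("simulated channels obey closed-form rigid-body cases", {
  geom <- nap_geometry(rho = c(0.05, 0.05, 0.05))
  t <- seq(0, 0.001, by = 1e-5)
  z <- matrix(0, length(t), 3)

  # pure translation: every channel reads the projection of a_cm
  trans <- manual_motion(t, a_cm = matrix(rep(c(0, 0, -100), each = length(t)),
                                          ncol = 3), alpha = z, omega = z)
  rec <- simulate_array(trans, geom)
  nz <- geom$sensors$nz
  for (i in 1:9) expect_equal(unname(rec$channels[, i]), rep(-100 * nz[i], length(t)))

  # constant spin about z: accelerometer at (rho_x, 0, 0) sensing x reads the
  # centripetal term -omega^2 rho_x
  spin <- manual_motion(t, a_cm = z, alpha = z,
                        omega = matrix(rep(c(0, 0, 10), each = length(t)), ncol = 3))
  rec2 <- simulate_array(spin, geom)
  ch_xy_arm <- which(geom$sensors$label == "xy")  # x-arm, senses y: no signal
  ch_yx_arm <- which(geom$sensors$label == "yx")  # y-arm, senses x: no signal
  expect_equal(unname(rec2$channels[, ch_xy_arm]), rep(0, length(t)))
  expect_equal(unname(rec2$channels[, ch_yx_arm]), rep(0, length(t)))
  # the centripetal reading appears on channels sensing along their own arm
  # only through the geometry here; verify against the oracle instead
  for (i in 1:9) {
    s <- geom$sensors[i, ]
    expect_equal(unname(rec2$channels[, i]),
                 oracle_channel(spin, c(s$px, s$py, s$pz), c(s$nx, s$ny, s$nz)),
                 tolerance = 1e-12)
  }
  # explicit value: a radial sensor at (rho, 0, 0) sensing x reads -w^2 rho
  radial <- oracle_channel(spin, c(0.05, 0, 0), c(1, 0, 0))
  expect_equal(radial, rep(-10^2 * 0.05, length(t)))

  # general pulse: channels equal the independent pointwise oracle
  cfg <- quick_config()
  m <- generate_motion(cfg, 6)
  rec3 <- simulate_array(m, geom, noise_sd = 0)
  for (i in c(1, 4, 7, 9)) {
    s <- geom$sensors[i, ]
    ora <- oracle_channel(m, c(s$px, s$py, s$pz), c(s$nx, s$ny, s$nz))
    expect_equal(unname(rec3$channels[, i]), ora,
                 tolerance = 1e-9 * max(abs(ora)))
  }
})

test_that("strain surrogate follows its stated links", {
  cfg <- quick_config(csdm_noise_sd = 0, mps_noise_sd = 0,
                      mps_intercept = 0.05, mps_slope = 0.005)
  at_mu <- generate_strain_surrogate(cfg$csdm_mu, cfg)
  expect_equal(at_mu$csdm15, 0.5)
  at_20 <- generate_strain_surrogate(20, cfg)
  expect_equal(at_20$mps, 0.15)
  expect_error(generate_strain_surrogate(-1, cfg), "nonnegative")

  # Monte-Carlo: sample mean within 3 standard errors of noise-free value
  noisy <- quick_config()
  dw <- rep(35, 1000)
  draws <- generate_strain_surrogate(dw, noisy, seed = 5)
  clean <- generate_strain_surrogate(35, quick_config(csdm_noise_sd = 0,
                                                      mps_noise_sd = 0))
  se <- noisy$csdm_noise_sd / sqrt(1000)
  expect_lt(abs(mean(draws$csdm15) - clean$csdm15), 3 * se)
  se_m <- noisy$mps_noise_sd / sqrt(1000)
  expect_lt(abs(mean(draws$mps) - clean$mps), 3 * se_m)
})

test_that("constructed strain histories round-trip through the reducers", {
  h <- generate_strain_history(0.5, 0.3, n_elements = 2, seed = 1)
  peaks <- apply(h$strain, 2, max)
  expect_identical(sum(peaks >= 0.15), 1L)

  expect_equal(mps(generate_strain_history(0.5, 0.30, n_elements = 10,
                                           seed = 2))$value, 0.30,
               tolerance = 1e-9)

  set.seed(33)
  for (rep in 1:100) {
    n_el <- sample(4:40, 1)
    target_c <- sample(0:n_el, 1) / n_el
    target_m <- if (target_c > 0) runif(1, 0.15, 0.6) else runif(1, 0.01, 0.14)
    h <- generate_strain_history(target_c, target_m, n_elements = n_el,
                                 seed = rep)
    expect_equal(csdm(h), target_c, tolerance = 1e-12)
    expect_equal(mps(h)$value, target_m, tolerance = 1e-12)
  }
})

test_that("unrepresentable and inconsistent strain targets are rejected", {
  expect_error(generate_strain_history(0.333, 0.3, n_elements = 2),
               "nearest representable value is 0.5")
  expect_error(generate_strain_history(0.5, 0.10, n_elements = 4),
               "requires mps >= 0.15")
  expect_error(generate_strain_history(0, 0.20, n_elements = 4),
               "forces csdm15 > 0")
  expect_error(generate_strain_history(0.5, 0.3, n_elements = 1), "at least 2")
})

test_that("study generation reproduces the configured location quota and bands", {
  st <- generate_study(synth_config(n = 267, seed = 7))
  expect_identical(nrow(st$impacts), 267L)
  counts <- table(st$impacts$location)
  expect_identical(as.integer(counts[c("front", "back", "side")]),
                   c(105L, 88L, 74L))
  expect_true(all(st$impacts$v_i >= 1.2 & st$impacts$v_i <= 5.8))
  expect_true(all(st$impacts$csdm15 >= 0 & st$impacts$csdm15 <= 1))
  expect_true(all(st$impacts$mps >= 0))
  # resultant excursion is exactly the norm of the directional excursions
  expect_equal(st$impacts$dw_r,
               sqrt(st$impacts$dw_x^2 + st$impacts$dw_y^2 + st$impacts$dw_z^2),
               tolerance = 1e-12)
})

test_that("peak-g / angular-velocity coupling behaves as configured", {
  st <- generate_study(synth_config(n = 200, seed = 11))
  back <- st$impacts[st$impacts$location == "back", ]
  expect_gt(cor(back$peak_g, back$dw_r), 0.9)

  dec <- synth_config(n = 200, seed = 11,
                      kappa = c(front = 0, back = 0, side = 0))
  st0 <- generate_study(dec)
  expect_lt(abs(cor(st0$impacts$peak_g, st0$impacts$dw_r)), 0.25)
})

test_that("identical config and seed give identical datasets", {
  a <- generate_study(quick_config(n = 15, seed = 3))
  b <- generate_study(quick_config(n = 15, seed = 3))
  expect_identical(a$impacts, b$impacts)
  expect_error(generate_study(quick_config(n = 0)), "n must be at least 1")
})

test_that("recording CSV round trip preserves channels and metadata", {
  cfg <- quick_config()
  rec <- simulate_array(generate_motion(cfg, 1), nap_geometry(),
                        noise_sd = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$channels, rec$channels, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$location, rec$location)
  expect_equal(back$v_i, rec$v_i, tolerance = 1e-12)
})
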