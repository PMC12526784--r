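# Helper: synthesize a consistent gyro/accel pair for a given angle series.
angle_to_sensors <- function(theta_deg, fs) {
  th <- theta_deg * pi / 180
  omega <- c(0, diff(theta_deg)) * fs
  list(gyro = omega, accel = cbind(9.81 * sin(th), 9.81 * cos(th)))
}

test_that("complementary filter limits reduce to integration and inclination", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  theta <- ifelse(t < 3, 0, 20 * sin(2 * pi * 1 * (t - 3)))
  s <- angle_to_sensors(theta, fs)

  # alpha = 1: pure trapezoidal integration of the gyro from the calibration angle
  o1 <- complementary_filter(s$gyro, s$accel, fs, alpha = 1)
  trapz <- cumsum(c(0, (s$gyro[-1] + s$gyro[-length(s$gyro)]) / 2)) / fs
  expect_equal(o1$angle, trapz + o1$angle[1], tolerance = 1e-8)

  # alpha = 0: per-sample accelerometer inclination
  o0 <- complementary_filter(s$gyro, s$accel, fs, alpha = 0)
  incl <- atan2(s$accel[, 1], s$accel[, 2]) * 180 / pi
  expect_equal(o0$angle, incl, tolerance = 1e-9)
})

test_that("complementary filter is exact for consistent sensors and quiet at rest", {
  fs <- 100
  t <- seq(0, 12, by = 1 / fs)
  theta <- ifelse(t < 3, 0, 12.5 * (1 - cos(2 * pi * 0.9 * (t - 3))))
  s <- angle_to_sensors(theta, fs)
  # analytic angular rate so gyro and accel describe the same smooth motion
  s$gyro <- ifelse(t < 3, 0, 12.5 * 2 * pi * 0.9 * sin(2 * pi * 0.9 * (t - 3)))
  o <- complementary_filter(s$gyro, s$accel, fs, alpha = 0.98)
  expect_lt(max(abs(o$angle - theta)), 0.1)
  # static standing: angle stays at zero for any alpha
  stat <- angle_to_sensors(rep(0, 500), fs)
  for (a in c(0, 0.5, 0.98, 1)) {
    os <- complementary_filter(stat$gyro, stat$accel, fs, alpha = a)
    expect_lt(max(abs(os$angle)), 1e-9)
  }
})

test_that("gyro bias error stays within the analytic steady-state bound", {
  fs <- 100
  bias <- 3 # deg/s
  n <- 3000
  stat <- angle_to_sensors(rep(0, n), fs)
  for (alpha in c(0.9, 0.98)) {
    o <- complementary_filter(stat$gyro + bias, stat$accel, fs, alpha = alpha)
    bound <- bias * (1 / fs) * alpha / (1 - alpha)
    steady <- abs(o$angle[n])
    expect_lte(steady, bound * 1.01)
    # and the bound is approached, not just satisfied trivially
    expect_gt(steady, bound * 0.9)
  }
})

test_that("zero-norm accelerometer samples fall back to pure integration", {
  fs <- 100
  stat <- angle_to_sensors(rep(0, 400), fs)
  acc <- stat$accel
  acc[350, ] <- 0
  o <- complementary_filter(stat$gyro, acc, fs, alpha = 0.98)
  expect_equal(o$n_zero_norm, 1L)
  expect_lt(max(abs(o$angle)), 1e-9)
})

test_that("joint angles are calibrated differences of segment orientations", {
  t <- seq(0, 5, by = 0.01)
  prox <- 10 * sin(2 * pi * t)
  expect_equal(joint_angles(prox, prox, t), rep(0, length(t)))
  # constant offset removed by static calibration
  expect_equal(joint_angles(prox + 7, prox, t), rep(0, length(t)),
               tolerance = 1e-9)
  expect_error(joint_angles(prox, prox, t, calibration_window = c(0.2, 0.5)),
               "0.5 s")
})

test_that("per-cycle ROM matches closed forms and a brute-force oracle", {
  t <- seq(0, 10, by = 0.01)
  cycles <- make_cycles(start_hs = c(1, 2.2), toe_off = c(1.7, 2.9),
                        end_hs = c(2.2, 3.4))
  expect_equal(rom_per_cycle(rep(3.5, length(t)), t, cycles)$mean_rom, 0)

  # sinusoid of amplitude A over a full cycle: ROM = 2A
  A <- 12
  x <- A * sin(2 * pi * (t - 1) / 1.2)
  r <- rom_per_cycle(x, t, make_cycles(1, 1.7, 2.2))
  expect_equal(r$mean_rom, 2 * A, tolerance = 0.01)

  # exhaustive scan oracle on random series
  set.seed(99)
  for (rep in 1:100) {
    x <- cumsum(rnorm(length(t)))
    st <- runif(1, 0.5, 4)
    cyc <- make_cycles(st, st + 0.6, st + runif(1, 0.8, 2))
    r <- rom_per_cycle(x, t, cyc)
    idx <- which(t >= cyc$start_hs & t < cyc$end_hs)
    expect_identical(r$per_cycle$rom, max(x[idx]) - min(x[idx]))
  }

  # ROM is invariant to constant offsets and never negative
  x <- cumsum(rnorm(length(t)))
  cyc <- make_cycles(2, 2.6, 3.4)
  expect_equal(rom_per_cycle(x + 100, t, cyc)$mean_rom,
               rom_per_cycle(x, t, cyc)$mean_rom)
  expect_gte(rom_per_cycle(x, t, cyc)$mean_rom, 0)

  # cycles outside the sampled span are skipped and counted
  r2 <- rom_per_cycle(x, t, make_cycles(c(2, 9.8), c(2.6, 10.4), c(3.4, 11)))
  expect_equal(r2$n_skipped, 1L)
  expect_equal(nrow(r2$per_cycle), 1L)
})

test_that("pendulum step length follows the closed form", {
  t <- seq(0, 3, by = 0.01)
  cyc <- make_cycles(0.5, 1.2, 1.9)
  # constant shank angle: zero sweep, zero step length
  expect_equal(estimate_step_length(rep(4, length(t)), t, cyc, 0.9)$step_length, 0)
  # sweep of 0.7 rad with leg 0.9 m: 2*0.9*sin(0.35)
  sweep_deg <- 0.7 * 180 / pi
  x <- ifelse(t >= 0.5 & t < 1.9,
              sweep_deg / 2 * sin(2 * pi * (t - 0.5) / 1.4), 0)
  sl <- estimate_step_length(x, t, cyc, 0.9)
  expect_equal(sl$step_length, 2 * 0.9 * sin(0.35), tolerance = 1e-3)
  expect_error(estimate_step_length(x * 600, t, cyc, 0.9), "non-physical")
  expect_error(estimate_step_length(x, t, cyc, -1), "leg_length")
})
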