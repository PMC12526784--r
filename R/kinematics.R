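# Sagittal segment orientation by complementary filtering, joint angles
# against a static calibration, per-cycle range of motion, and the
# inverted-pendulum step-length estimator.

#' Complementary-filter sagittal orientation estimate
#'
#' First-order fusion of integrated gyroscope rate and accelerometer gravity
#' inclination:
#' \deqn{\theta_t = \alpha(\theta_{t-1} + \bar\omega_t \Delta t) + (1-\alpha)\,\theta^{acc}_t}
#' where \eqn{\bar\omega_t} is the trapezoidal mean of consecutive gyro
#' samples and \eqn{\theta^{acc}_t = \mathrm{atan2}(a_x, a_y)} is the
#' inclination from the accelerometer (x anterior, y vertical). The initial
#' angle is the mean accelerometer inclination over the calibration window.
#' At `alpha = 1` the output reduces to the initial angle plus the
#' cumulative trapezoidal gyro integral; at `alpha = 0` it is the per-sample
#' accelerometer inclination.
#'
#' Accelerometer samples with near-zero norm cannot define an inclination;
#' those samples fall back to pure gyro integration and are counted in the
#' result.
#'
#' @param gyro_sagittal Sagittal angular velocity, deg/s.
#' @param accel n x 2 or n x 3 accelerometer matrix (m/s^2); columns x, y
#'   (, z).
#' @param sampling_rate Sampling rate, Hz.
#' @param alpha Fusion coefficient in \[0, 1\] (default 0.98 at 100 Hz).
#' @param calibration_window Two times (s) inside the static standing period.
#' @return List of class `orientation_series`: `angle` (deg), `time` (s),
#'   `alpha`, `n_zero_norm`.
#' @export
complementary_filter <- function(gyro_sagittal, accel, sampling_rate,
                                 alpha = 0.98,
                                 calibration_window = c(0.25, 2.25)) {
  if (alpha < 0 || alpha > 1) stop("parameter error: alpha must be in [0, 1]")
  n <- length(gyro_sagittal)
  if (is.vector(accel)) accel <- matrix(accel, ncol = 1)
  if (nrow(accel) != n) stop("data error: gyro and accel lengths differ")
  ax <- accel[, 1]
  ay <- accel[, 2]
  dt <- 1 / sampling_rate
  tt <- (seq_len(n) - 1) * dt

  norm2 <- ax^2 + ay^2
  zero_norm <- norm2 < 1e-12
  theta_acc <- rad2deg(atan2(ax, ay))
  theta_acc[zero_norm] <- NA_real_

  calib <- tt >= calibration_window[1] & tt <= calibration_window[2]
  if (!any(calib & !zero_norm)) {
    theta0 <- 0
  } else {
    theta0 <- mean(theta_acc[calib], na.rm = TRUE)
  }

  omega_bar <- c(0, (gyro_sagittal[-1] + gyro_sagittal[-n]) / 2)
  if (!any(zero_norm)) {
    x <- alpha * omega_bar * dt + (1 - alpha) * theta_acc
    theta <- numeric(n)
    theta[1] <- alpha * theta0 + (1 - alpha) * theta_acc[1]
    if (n > 1) {
      theta[2:n] <- as.numeric(stats::filter(x[2:n], alpha,
                                             method = "recursive",
                                             init = theta[1]))
    }
  } else {
    theta <- numeric(n)
    theta[1] <- if (zero_norm[1]) theta0 else alpha * theta0 + (1 - alpha) * theta_acc[1]
    for (i in seq_len(n)[-1]) {
      if (zero_norm[i]) {
        theta[i] <- theta[i - 1] + omega_bar[i] * dt
      } else {
        theta[i] <- alpha * (theta[i - 1] + omega_bar[i] * dt) +
          (1 - alpha) * theta_acc[i]
      }
    }
  }
  structure(list(angle = theta, time = tt, alpha = alpha,
                 n_zero_norm = sum(zero_norm)),
            class = "orientation_series")
}

#' Joint angle from two segment orientations
#'
#' The joint angle is the proximal-minus-distal orientation difference,
#' referenced to the mean difference over the static calibration window
#' (anatomical zero). Hip uses pelvis-thigh, knee thigh-shank, ankle
#' shank-foot; flexion is positive for hip and knee, dorsiflexion positive
#' for the ankle.
#'
#' @param proximal,distal `orientation_series` (or numeric angle vectors on
#'   a common time base).
#' @param time Time vector (s); taken from `proximal` when it is an
#'   `orientation_series`.
#' @param calibration_window Two times (s); must span at least 0.5 s.
#' @return Numeric joint-angle series (deg).
#' @export
joint_angles <- function(proximal, distal, time = NULL,
                         calibration_window = c(0.25, 2.25)) {
  if (inherits(proximal, "orientation_series")) {
    time <- time %||% proximal$time
    proximal <- proximal$angle
  }
  if (inherits(distal, "orientation_series")) distal <- distal$angle
  if (is.null(time)) stop("data error: time base required")
  if (length(proximal) != length(distal)) {
    stop("data error: proximal and distal series lengths differ")
  }
  if (diff(calibration_window) < 0.5) {
    stop("configuration error: calibration window must span at least 0.5 s")
  }
  d <- proximal - distal
  calib <- time >= calibration_window[1] & time <= calibration_window[2]
  if (!any(calib)) stop("configuration error: calibration window outside series")
  d - mean(d[calib])
}

#' Per-cycle range of motion
#'
#' For each gait cycle, the maximum and minimum of the joint angle within
#' \[start_hs, end_hs) and their difference (ROM); the subject-level value
#' is the mean over cycles. Cycles extending beyond the sampled span are
#' skipped and counted.
#'
#' @param angle_series Numeric joint-angle series (deg).
#' @param time Time vector (s).
#' @param cycles A `gait_cycles` data frame.
#' @return List of class `joint_angle_summary`: `per_cycle` (side, max
#'   flexion, max extension, rom), `mean_rom`, `mean_max_flexion`,
#'   `n_skipped`.
#' @export
rom_per_cycle <- function(angle_series, time, cycles) {
  if (nrow(cycles) == 0) stop("data error: no cycles supplied")
  n <- length(time)
  # sample index ranges [lo, hi] covering time >= start & time < end
  lo <- findInterval(cycles$start_hs - 1e-12, time) + 1L
  hi <- findInterval(cycles$end_hs - 1e-12, time)
  ok <- cycles$start_hs >= time[1] - 1e-9 & cycles$end_hs <= time[n] + 1e-9 &
    lo <= hi
  skipped <- sum(!ok)
  kk <- which(ok)
  mx <- vapply(kk, function(k) max(angle_series[lo[k]:hi[k]]), numeric(1))
  mn <- vapply(kk, function(k) min(angle_series[lo[k]:hi[k]]), numeric(1))
  per_cycle <- data.frame(side = cycles$side[kk], max_flexion = mx,
                          max_extension = mn, rom = mx - mn)
  structure(list(per_cycle = per_cycle,
                 mean_rom = if (nrow(per_cycle) > 0) mean(per_cycle$rom) else NA_real_,
                 mean_max_flexion = if (nrow(per_cycle) > 0) mean(per_cycle$max_flexion) else NA_real_,
                 n_skipped = skipped),
            class = "joint_angle_summary")
}

#' Inverted-pendulum step-length estimate from shank sweep
#'
#' Models the stance leg as an inverted pendulum of length `leg_length`:
#' each step covers \eqn{2 L \sin(\Delta\theta / 2)} where
#' \eqn{\Delta\theta} is the shank sagittal sweep (max minus min, radians)
#' during the cycle. Returns the per-cycle estimates and their mean.
#'
#' @param shank_angle_series Shank sagittal angle (deg).
#' @param time Time vector (s).
#' @param cycles A `gait_cycles` data frame.
#' @param leg_length Leg length, m.
#' @return List: `step_length` (mean, m), `per_cycle` (m).
#' @export
estimate_step_length <- function(shank_angle_series, time, cycles, leg_length) {
  if (leg_length <= 0) stop("parameter error: leg_length must be positive")
  if (nrow(cycles) == 0) stop("data error: no cycles supplied")
  lo <- findInterval(cycles$start_hs - 1e-12, time) + 1L
  hi <- findInterval(cycles$end_hs - 1e-12, time)
  kk <- which(lo <= hi)
  sweeps <- deg2rad(vapply(kk, function(k) {
    seg <- shank_angle_series[lo[k]:hi[k]]
    max(seg) - min(seg)
  }, numeric(1)))
  if (any(sweeps >= pi)) {
    stop("data error: non-physical shank sweep (",
         signif(rad2deg(max(sweeps)), 4), " deg)")
  }
  per <- 2 * leg_length * sin(sweeps / 2)
  list(step_length = if (length(per) > 0) mean(per) else NA_real_, per_cycle = per)
}
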