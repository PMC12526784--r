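# IMU trial synthesis. Each subject's segment-angle curves are built so the
# full extraction pipeline (filter -> events -> cycles -> complementary
# filter -> joint angles -> spatiotemporal formulas) inverts to the
# subject's ground-truth parameters exactly in the noiseless limit:
#   * right/left heel strikes and toe-offs are laid out periodically from
#     cycle time, stance fraction and the left/right phase offset;
#   * the foot sagittal gyro carries one positive Gaussian pulse per heel
#     strike and one negative pulse per toe-off (the detector's signature);
#   * thigh = shank + knee-curve, so the knee angle is an exact sinusoid
#     with range knee_rom and hip (pelvis - thigh) has range hip_rom;
#   * the shank amplitude is asin(step_length / (2 leg_length)), so the
#     inverted-pendulum estimator recovers step length exactly;
#   * the foot angle integrates the event pulses (a smoothed square wave)
#     plus a shank-aligned component scaled so the ankle angle
#     (shank - foot) has range ankle_rom (1-D numeric solve).

GRAVITY <- 9.81

SEGMENTS <- c("pelvis", "thigh_L", "thigh_R", "shank_L", "shank_R",
              "foot_L", "foot_R")

# Smoothed square wave stepping +1 at each `up` time and -1 at each `down`
# time, with Gaussian transition width sigma; and its time derivative.
# Transitions are evaluated only within +/- 8 sigma of each event (the
# Gaussian tail beyond is numerically zero), with the step carried forward.
pulse_square <- function(t, up, down, sigma) {
  n <- length(t)
  fs <- 1 / (t[2] - t[1])
  v <- numeric(n)
  add <- function(e, sign) {
    lo <- max(1L, as.integer(floor((e - 8 * sigma) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((e + 8 * sigma) * fs)) + 1L)
    if (lo <= hi) v[lo:hi] <<- v[lo:hi] + sign * stats::pnorm((t[lo:hi] - e) / sigma)
    if (hi < n) v[(hi + 1L):n] <<- v[(hi + 1L):n] + sign
  }
  for (e in up) add(e, 1)
  for (e in down) add(e, -1)
  v
}

pulse_train <- function(t, up, down, sigma) {
  n <- length(t)
  fs <- 1 / (t[2] - t[1])
  v <- numeric(n)
  add <- function(e, sign) {
    lo <- max(1L, as.integer(floor((e - 8 * sigma) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((e + 8 * sigma) * fs)) + 1L)
    if (lo <= hi) {
      v[lo:hi] <<- v[lo:hi] + sign * stats::dnorm((t[lo:hi] - e) / sigma) / sigma
    }
  }
  for (e in up) add(e, 1)
  for (e in down) add(e, -1)
  v
}

# Per-subject deterministic gait template; consumes the subject RNG stream.
build_subject_template <- function(profile, config) {
  fs <- config$sampling_rate
  cyc <- profile$gait_cycle_time
  st <- profile$stance_pct / 100
  sl <- profile$step_length
  L <- profile$leg_length_m

  if (sl >= config$walkway_length / 4) {
    stop("simulation error: step length ", signif(sl, 3),
         " m leaves fewer than 2 strides on the ", config$walkway_length,
         " m walkway (subject ", profile$subject_id, ")")
  }
  n_str <- max(2L, as.integer(floor(config$walkway_length / (2 * sl))))

  phi <- 0.5
  if (config$phase_asym_sd > 0) {
    phi <- min(max(stats::rnorm(1, 0.5, config$phase_asym_sd), 0.4), 0.6)
  }
  pulse_amp <- stats::runif(1, config$pulse_amp_range[1], config$pulse_amp_range[2])
  pulse_sd <- stats::runif(1, config$pulse_width_range[1], config$pulse_width_range[2])
  h <- pulse_amp * pulse_sd * sqrt(2 * pi)       # foot-angle step per event, deg

  # segment-curve parameters (deg); clamped solves are counted, not fatal
  warnings <- character(0)
  A_sh <- rad2deg(asin(sl / (2 * L)))            # shank amplitude (half sweep)
  b_kn <- profile$knee_rom / 2
  a_hp <- profile$hip_rom / 2
  cos_psi <- (a_hp^2 - A_sh^2 - b_kn^2) / (2 * A_sh * b_kn)
  if (cos_psi < -1 || cos_psi > 1) {
    warnings <- c(warnings, "knee/hip/step-length geometry clamped")
    cos_psi <- min(max(cos_psi, -1), 1)
  }
  psi <- acos(cos_psi)

  # Gait onset sits at the mid-stance phase (in right-foot cycle
  # coordinates): that is a zero of the foot's warp angular velocity for
  # both feet (the left foot, half a cycle out of phase, is at its
  # mid-swing zero), so the foot gyro starts continuously from rest and
  # the detector sees no onset artefact.
  t_g0 <- config$standing_duration
  t_hs0 <- t_g0 + (1 - st / 2) * cyc
  hs_R <- t_hs0 + (0:n_str) * cyc
  to_R <- t_hs0 + ((-1):(n_str - 1) + st) * cyc
  hs_L <- t_hs0 + ((-1):(n_str - 1) + phi) * cyc
  to_L <- t_hs0 + ((-1):(n_str - 2) + phi + st) * cyc
  t_g1 <- hs_R[length(hs_R)] + (st / 2) * cyc  # also a warp zero phase
  t_end <- t_g1 + 0.5
  tt <- seq(0, t_end, by = 1 / fs)
  n <- length(tt)

  u <- (tt - t_hs0) / cyc
  u0 <- (t_g0 - t_hs0) / cyc
  u1 <- (t_g1 - t_hs0) / cyc
  uw <- pmin(pmax(u, u0), u1)
  in_win <- u > u0 & u < u1

  shank_f <- function(v) A_sh * cos(2 * pi * (v - 0.3))
  knee_f <- function(v) b_kn * cos(2 * pi * (v - 0.3) + psi)
  dshank_f <- function(v) -A_sh * 2 * pi * sin(2 * pi * (v - 0.3))
  dknee_f <- function(v) -b_kn * 2 * pi * sin(2 * pi * (v - 0.3) + psi)

  # Stance-warped cosine: the foot's smooth angular velocity runs from +m
  # at heel strike monotonically to -m at toe-off and back, so its only
  # extremes coincide with the event pulses -- it can never contribute a
  # separate super-threshold peak, whatever m is. Its integral (the foot
  # angle component) peaks at mid-stance/mid-swing, mirroring the shank
  # curve, which makes the ankle angle (shank - foot) tunable by m.
  warp_deriv <- function(v) {
    uf <- v - floor(v)
    ifelse(uf <= st, cos(pi * uf / st), -cos(pi * (uf - st) / (1 - st)))
  }
  warp_angle <- function(v) {
    uf <- v - floor(v)
    cyc * ifelse(uf <= st,
                 (st / pi) * sin(pi * uf / st),
                 -((1 - st) / pi) * sin(pi * (uf - st) / (1 - st)))
  }

  side_curves <- function(shift, hs, to) {
    v <- uw - shift
    v0 <- u0 - shift
    shank <- shank_f(v) - shank_f(v0)
    knee <- knee_f(v) - knee_f(v0)
    warp <- warp_angle(v) - warp_angle(v0)
    q <- h * pulse_square(tt, hs, to, pulse_sd)
    list(
      shank = shank, thigh = shank + knee, warp = warp, q = q,
      dshank = dshank_f(v) / cyc * in_win,
      dthigh = (dshank_f(v) + dknee_f(v)) / cyc * in_win,
      dwarp = warp_deriv(v) * in_win,
      dq = h * pulse_train(tt, hs, to, pulse_sd)
    )
  }
  right <- side_curves(0, hs_R, to_R)
  left <- side_curves(phi, hs_L, to_L)

  # Solve the warp magnitude m (deg/s) so the right ankle angle
  # (shank - foot) spans exactly ankle_rom over a mid-walk cycle.
  mid <- max(1L, as.integer(floor(n_str / 2)))
  idx <- which(tt >= hs_R[mid + 1] & tt < hs_R[mid + 1] + cyc)
  ank_rom_of <- function(m) {
    val <- right$shank[idx] - m * right$warp[idx] - right$q[idx]
    diff(range(val))
  }
  target <- profile$ankle_rom
  # m >= 0 keeps the warp aligned with the pulses (adding to the event
  # peaks, never eroding them). ROM(m) is U-shaped: cancellation of the
  # shank curve on the left branch, warp dominance on the right, so any
  # reachable target has a crossing on one branch.
  grid <- seq(0, 400, length.out = 401)
  roms <- vapply(grid, ank_rom_of, numeric(1))
  m_w <- grid[which.min(abs(roms - target))]
  down <- which(roms[-length(roms)] >= target & roms[-1] < target)
  up <- which(roms[-length(roms)] <= target & roms[-1] > target)
  i <- if (length(down) > 0) down[1] else if (length(up) > 0) up[length(up)] else NA
  if (!is.na(i)) {
    m_w <- stats::uniroot(function(m) ank_rom_of(m) - target,
                          c(grid[i], grid[i + 1]), tol = 1e-8)$root
  }
  if (abs(ank_rom_of(m_w) - target) > 0.5) {
    warnings <- c(warnings, "ankle ROM target outside achievable band; clamped")
  }

  foot_angle <- function(sc) m_w * sc$warp + sc$q
  foot_gyro <- function(sc) m_w * sc$dwarp + sc$dq

  angles <- list(
    pelvis = numeric(n),
    thigh_L = left$thigh, thigh_R = right$thigh,
    shank_L = left$shank, shank_R = right$shank,
    foot_L = foot_angle(left), foot_R = foot_angle(right)
  )
  gyros <- list(
    pelvis = numeric(n),
    thigh_L = left$dthigh, thigh_R = right$dthigh,
    shank_L = left$dshank, shank_R = right$dshank,
    foot_L = foot_gyro(left), foot_R = foot_gyro(right)
  )

  events <- rbind(
    data.frame(time = hs_R, side = "R", type = "heel_strike"),
    data.frame(time = to_R, side = "R", type = "toe_off"),
    data.frame(time = hs_L, side = "L", type = "heel_strike"),
    data.frame(time = to_L, side = "L", type = "toe_off")
  )
  events <- events[order(events$time), ]
  rownames(events) <- NULL

  list(time = tt, angles = angles, gyros = gyros, events = events,
       n_strides = n_str, warnings = warnings, phi = phi,
       pulse_amp = pulse_amp, pulse_sd = pulse_sd, warp_magnitude = m_w)
}

#' Synthesize a multi-trial IMU recording for one subject
#'
#' Builds the subject's deterministic walking template (event layout, segment
#' angle curves, event pulses) from the ground-truth gait parameters, then
#' realizes `n_trials` trials that differ only by fresh sensor noise. Each
#' trial starts with a static standing period for calibration. The sagittal
#' angular velocity is the gyroscope z-axis; the accelerometer reports the
#' gravity projection of the true segment angle (x anterior, y vertical).
#'
#' @param profile A single-row subset of a `gait_cohort` (or an equivalent
#'   list with the same fields).
#' @param config The [cohort_config()] used for the cohort.
#' @param seed Master seed; the subject's stream is derived from it and the
#'   subject id, so cohorts can be synthesized subject-by-subject in any
#'   order.
#' @return An `imu_recording`: list with `subject_id`, `sampling_rate`,
#'   `time`, `trials` (each a named list of segments, each with `gyro` and
#'   `accel` n x 3 matrices), `ground_truth` (per-trial event table),
#'   `n_strides`, `leg_length_m`.
#' @export
#' @examples
#' cfg <- cohort_config(group_sizes = c(healthy_control = 1, mci = 1,
#'                                      mild_dementia = 1, moderate_dementia = 1),
#'                      n_trials = 2)
#' cohort <- sample_cohort(cfg, seed = 1)
#' rec <- synthesize_recording(cohort[1, ], cfg, seed = 1)
#' names(rec$trials[[1]])
synthesize_recording <- function(profile, config = cohort_config(), seed = 1L) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1L)
    profile <- as.list(profile)
  }
  validate_config(config)
  with_seed(derive_seed(seed, "recording", profile$subject_id), {
    tpl <- build_subject_template(profile, config)
    n <- length(tpl$time)
    trials <- vector("list", config$n_trials)
    for (tr in seq_len(config$n_trials)) {
      segs <- vector("list", length(SEGMENTS))
      names(segs) <- SEGMENTS
      for (seg in SEGMENTS) {
        ang <- tpl$angles[[seg]]
        gyro <- cbind(
          x = stats::rnorm(n, 0, config$gyro_noise_sd),
          y = stats::rnorm(n, 0, config$gyro_noise_sd),
          z = tpl$gyros[[seg]] + stats::rnorm(n, 0, config$gyro_noise_sd)
        )
        th <- deg2rad(ang)
        accel <- cbind(
          x = GRAVITY * sin(th) + stats::rnorm(n, 0, config$accel_noise_sd),
          y = GRAVITY * cos(th) + stats::rnorm(n, 0, config$accel_noise_sd),
          z = stats::rnorm(n, 0, config$accel_noise_sd)
        )
        segs[[seg]] <- list(gyro = gyro, accel = accel)
      }
      trials[[tr]] <- segs
    }
    gt <- do.call(rbind, lapply(seq_len(config$n_trials), function(tr) {
      cbind(trial = tr, tpl$events)
    }))
    rec <- list(
      subject_id = profile$subject_id,
      sampling_rate = config$sampling_rate,
      time = tpl$time,
      trials = trials,
      ground_truth = gt,
      n_strides = tpl$n_strides,
      leg_length_m = profile$leg_length_m,
      template_warnings = tpl$warnings
    )
    class(rec) <- "imu_recording"
    rec
  })
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording %s: %d trials, %d samples @ %g Hz, %d strides/side\n",
              x$subject_id, length(x$trials), length(x$time),
              x$sampling_rate, x$n_strides))
  invisible(x)
}

#' Write / read a recording as long-format CSV
#'
#' Columns: time_s, trial, segment, side, gyro_x_dps, gyro_y_dps, gyro_z_dps,
#' acc_x_mps2, acc_y_mps2, acc_z_mps2. The z gyro axis is the sagittal
#' angular velocity. Ground-truth events are written to a JSON sidecar by
#' [run_pipeline()] when recordings are exported.
#'
#' @param recording An `imu_recording`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  n <- length(recording$time)
  rows <- list()
  for (tr in seq_along(recording$trials)) {
    for (seg in names(recording$trials[[tr]])) {
      s <- recording$trials[[tr]][[seg]]
      side <- if (seg == "pelvis") "C" else sub("^.*_", "", seg)
      base <- sub("_[LR]$", "", seg)
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = recording$time, trial = tr, segment = base, side = side,
        gyro_x_dps = s$gyro[, 1], gyro_y_dps = s$gyro[, 2], gyro_z_dps = s$gyro[, 3],
        acc_x_mps2 = s$accel[, 1], acc_y_mps2 = s$accel[, 2], acc_z_mps2 = s$accel[, 3]
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param subject_id Subject identifier to attach to the recording.
#' @param sampling_rate Sampling rate of the stored series (Hz).
#' @param leg_length_m Optional subject leg length (m), needed for step-length
#'   estimation downstream.
#' @export
read_recording_csv <- function(path, subject_id = NA_character_,
                               sampling_rate = 100, leg_length_m = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "trial", "segment", "side", "gyro_x_dps", "gyro_y_dps",
            "gyro_z_dps", "acc_x_mps2", "acc_y_mps2", "acc_z_mps2")
  if (!all(need %in% names(df))) {
    stop("recording CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  trials <- list()
  tt <- NULL
  for (tr in sort(unique(df$trial))) {
    dtr <- df[df$trial == tr, ]
    segs <- list()
    for (seg in SEGMENTS) {
      base <- sub("_[LR]$", "", seg)
      side <- if (seg == "pelvis") "C" else sub("^.*_", "", seg)
      dseg <- dtr[dtr$segment == base & dtr$side == side, ]
      dseg <- dseg[order(dseg$time_s), ]
      if (nrow(dseg) == 0) next
      tt <- dseg$time_s
      segs[[seg]] <- list(
        gyro = cbind(x = dseg$gyro_x_dps, y = dseg$gyro_y_dps, z = dseg$gyro_z_dps),
        accel = cbind(x = dseg$acc_x_mps2, y = dseg$acc_y_mps2, z = dseg$acc_z_mps2)
      )
    }
    trials[[length(trials) + 1L]] <- segs
  }
  rec <- list(subject_id = subject_id, sampling_rate = sampling_rate,
              time = tt, trials = trials, ground_truth = NULL,
              n_strides = NA_integer_, leg_length_m = leg_length_m,
              template_warnings = character(0))
  class(rec) <- "imu_recording"
  rec
}
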