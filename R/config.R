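# Cohort/simulation configuration: every numeric default of the study design
# (group sizes, trial structure, filter, detector threshold) and the
# group-conditional parameter distributions lives here.

# Per-group generating distributions for the gait parameters and
# demographics. Summaries printed as median (Q1-Q3) become normal draws with
# mean = median and sd = IQR/1.349; mean +/- SD rows are used directly.
# Group order: healthy_control, mci, mild_dementia, moderate_dementia.
default_parameter_specs <- function() {
  med <- function(loc, q1, q3, lower, upper) {
    list(location = loc, scale = iqr_to_sd(q1, q3), lower = lower, upper = upper)
  }
  msd <- function(loc, sd, lower, upper) {
    list(location = loc, scale = sd, lower = lower, upper = upper)
  }
  g <- function(hc, mci, mild, mod) {
    out <- list(hc, mci, mild, mod)
    names(out) <- GAIT_GROUPS
    list(
      location = vapply(out, `[[`, numeric(1), "location"),
      scale = vapply(out, `[[`, numeric(1), "scale"),
      lower = vapply(out, `[[`, numeric(1), "lower"),
      upper = vapply(out, `[[`, numeric(1), "upper")
    )
  }
  list(
    cadence = g(msd(110.4, 6.1, 70, 135), msd(99.2, 4.6, 70, 135),
                msd(89.8, 7.9, 62, 130), msd(83.8, 9.1, 62, 130)),
    velocity = g(med(1.2, 1.2, 1.3, 0.35, 1.8), med(1.0, 0.9, 1.1, 0.35, 1.8),
                 med(0.7, 0.6, 0.8, 0.3, 1.6), med(0.6, 0.4, 0.6, 0.3, 1.6)),
    stance_pct = g(med(61.8, 60.8, 62.9, 53, 72), med(63.7, 60.9, 65.7, 53, 72),
                   med(60.6, 58.0, 63.9, 53, 72), med(63.9, 61.4, 67.5, 53, 72)),
    hip_rom = g(med(47.8, 45.0, 51.1, 15, 70), med(42.4, 38.1, 44.8, 15, 70),
                med(33.3, 27.3, 36.7, 12, 60), med(28.6, 26.0, 35.2, 12, 60)),
    knee_rom = g(med(53.9, 51.5, 56.6, 20, 80), med(48.1, 44.6, 54.4, 20, 80),
                 med(39.4, 35.6, 40.3, 18, 70), med(38.9, 35.4, 39.9, 18, 70)),
    ankle_rom = g(msd(32.1, 3.7, 10, 50), msd(23.8, 4.2, 10, 50),
                  msd(23.9, 5.6, 10, 50), msd(23.5, 9.3, 10, 50)),
    age = g(med(74.0, 72.0, 75.0, 60, 95), med(75.5, 72.0, 82.0, 60, 95),
            med(84.0, 77.0, 86.0, 60, 97), med(86.0, 76.0, 89.0, 60, 97)),
    height = g(med(158.5, 153.0, 165.0, 138, 185), med(159.0, 152.0, 165.0, 138, 185),
               med(150.0, 147.0, 158.0, 135, 182), med(155.0, 147.0, 170.0, 135, 185)),
    weight = g(msd(60.6, 9.8, 35, 95), msd(62.6, 9.8, 35, 95),
               msd(54.3, 7.8, 33, 90), msd(54.1, 10.8, 33, 90))
  )
}

#' Build a cohort/simulation configuration
#'
#' Collects every tunable of the synthetic four-group gait study in one
#' object: group sizes, trial structure (8 trials over an 8 m walkway at
#' 100 Hz), the group-conditional generating distributions for the eleven
#' gait parameters and demographics, IMU noise levels, event-pulse shaping,
#' and the downstream processing constants (4th-order 20 Hz Butterworth
#' low-pass, 50 deg/s event threshold, complementary-filter coefficient).
#'
#' Parameters printed in the source tables as median (Q1-Q3) are drawn from a
#' normal with mean equal to the printed median and sd = IQR/1.349; rows
#' printed as mean +/- SD use those moments directly. Draws are truncated to
#' physical bounds wide enough not to shift the medians.
#'
#' @param group_sizes Named integer vector of subjects per group; default
#'   c(54, 34, 25, 26) for healthy control, MCI, mild and moderate dementia.
#' @param n_trials Walking trials per subject (default 8).
#' @param walkway_length Walkway length in metres (default 8).
#' @param sampling_rate IMU sampling rate in Hz (default 100).
#' @param leg_length_fraction Leg length as a fraction of body height
#'   (default 0.53, a standard anthropometric ratio).
#' @param parameters Per-parameter, per-group generating distributions; see
#'   Details. Override entries to move group separations.
#' @param male_fraction Per-group probability of male sex; defaults match the
#'   study cohort counts (20/54, 15/34, 4/25, 10/26).
#' @param gyro_noise_sd Gyroscope white-noise SD in deg/s (default 5).
#' @param accel_noise_sd Accelerometer white-noise SD in m/s^2 (default 0.2).
#' @param phase_asym_sd SD of the left-right phase asymmetry, as a fraction
#'   of the gait cycle (default 0.005; contralateral heel strike at 50 % of
#'   the cycle plus this draw).
#' @param pulse_amp_range Foot-gyro event pulse amplitude band in deg/s
#'   (default 80-150).
#' @param pulse_width_range Event pulse SD band in seconds (default 30-50 ms).
#' @param event_threshold Detector peak threshold in deg/s (default 50).
#' @param min_separation Minimum same-type event separation in s (default 0.25).
#' @param filter_order,filter_cutoff Butterworth low-pass order and cutoff Hz.
#' @param alpha Complementary-filter fusion coefficient (default 0.98).
#' @param standing_duration Static standing lead-in per trial, s (default 2.5;
#'   the calibration window sits inside it).
#' @param calibration_window Two times (s) delimiting the static calibration
#'   window used for orientation baselines.
#' @param seed Optional default master seed carried with the configuration.
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config()
#' cfg$group_sizes
cohort_config <- function(group_sizes = c(healthy_control = 54L, mci = 34L,
                                          mild_dementia = 25L, moderate_dementia = 26L),
                          n_trials = 8L,
                          walkway_length = 8,
                          sampling_rate = 100,
                          leg_length_fraction = 0.53,
                          parameters = default_parameter_specs(),
                          male_fraction = c(healthy_control = 20 / 54, mci = 15 / 34,
                                            mild_dementia = 4 / 25, moderate_dementia = 10 / 26),
                          gyro_noise_sd = 5,
                          accel_noise_sd = 0.2,
                          phase_asym_sd = 0.005,
                          pulse_amp_range = c(80, 150),
                          pulse_width_range = c(0.03, 0.05),
                          event_threshold = 50,
                          min_separation = 0.25,
                          filter_order = 4L,
                          filter_cutoff = 20,
                          alpha = 0.98,
                          standing_duration = 2.5,
                          calibration_window = c(0.25, 2.25),
                          seed = NULL) {
  cfg <- list(
    group_sizes = group_sizes, n_trials = as.integer(n_trials),
    walkway_length = walkway_length, sampling_rate = sampling_rate,
    leg_length_fraction = leg_length_fraction, parameters = parameters,
    male_fraction = male_fraction,
    gyro_noise_sd = gyro_noise_sd, accel_noise_sd = accel_noise_sd,
    phase_asym_sd = phase_asym_sd,
    pulse_amp_range = pulse_amp_range, pulse_width_range = pulse_width_range,
    event_threshold = event_threshold, min_separation = min_separation,
    filter_order = as.integer(filter_order), filter_cutoff = filter_cutoff,
    alpha = alpha, standing_duration = standing_duration,
    calibration_window = calibration_window, seed = seed
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks group sizes, distribution parameters, sampling constraints
#' (filter cutoff below Nyquist) and trial structure, failing with an error
#' that names the offending field.
#'
#' @param config A `cohort_config` object.
#' @return The configuration, invisibly, if valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$group_sizes
  if (length(gs) != 4L || !all(names(gs) == GAIT_GROUPS)) {
    stop("config error: group_sizes must be named for the four groups ",
         paste(GAIT_GROUPS, collapse = ", "))
  }
  if (any(!is.finite(gs)) || any(gs < 1)) {
    stop("config error: group_sizes must be finite and >= 1")
  }
  if (!is.finite(config$n_trials) || config$n_trials < 1) {
    stop("config error: n_trials must be >= 1")
  }
  if (config$walkway_length <= 0) stop("config error: walkway_length must be positive")
  if (config$sampling_rate <= 0) stop("config error: sampling_rate must be positive")
  if (config$filter_cutoff >= config$sampling_rate / 2) {
    stop("config error: filter_cutoff must be below the Nyquist frequency")
  }
  if (config$alpha < 0 || config$alpha > 1) stop("config error: alpha must be in [0, 1]")
  for (pname in names(config$parameters)) {
    p <- config$parameters[[pname]]
    for (field in c("location", "scale")) {
      v <- p[[field]]
      if (length(v) != 4L || any(!is.finite(v))) {
        stop("config error: parameter '", pname, "' has non-finite ", field)
      }
    }
    if (any(p$scale < 0)) stop("config error: parameter '", pname, "' has negative scale")
    if (any(p$location <= 0)) stop("config error: parameter '", pname, "' has non-positive location")
  }
  if (any(config$male_fraction < 0 | config$male_fraction > 1)) {
    stop("config error: male_fraction must be in [0, 1]")
  }
  noise <- c(gyro_noise_sd = config$gyro_noise_sd, accel_noise_sd = config$accel_noise_sd,
             phase_asym_sd = config$phase_asym_sd)
  if (any(!is.finite(noise)) || any(noise < 0)) {
    stop("config error: noise SDs must be finite and >= 0")
  }
  if (diff(config$calibration_window) < 0.5) {
    stop("config error: calibration_window must span at least 0.5 s")
  }
  if (config$calibration_window[2] > config$standing_duration) {
    stop("config error: calibration_window must lie inside the standing period")
  }
  invisible(config)
}

#' Set all stochastic components of a configuration to zero
#'
#' Convenience for round-trip checks: zero sensor noise, zero left/right
#' phase asymmetry, and (optionally) zero spread in every generating
#' distribution so each subject realizes the group-level locations exactly.
#'
#' @param config A `cohort_config`.
#' @param parameter_scales If TRUE also zero the parameter/demographic
#'   distribution scales.
#' @return The modified configuration.
#' @export
noiseless_config <- function(config = cohort_config(), parameter_scales = FALSE) {
  config$gyro_noise_sd <- 0
  config$accel_noise_sd <- 0
  config$phase_asym_sd <- 0
  if (parameter_scales) {
    for (pname in names(config$parameters)) {
      config$parameters[[pname]]$scale <- rep(0, 4)
    }
  }
  validate_config(config)
  config
}

#' Write / read a configuration as YAML
#'
#' All defaults are embedded, so a dumped file is a complete, self-contained
#' record of the simulated study conditions.
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @return `write_config` returns the path invisibly; `read_config` returns a
#'   `cohort_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  # yaml drops names on scalars read back as lists; restore structure
  x$group_sizes <- stats::setNames(as.integer(unlist(x$group_sizes)), GAIT_GROUPS)
  x$male_fraction <- stats::setNames(as.numeric(unlist(x$male_fraction)), GAIT_GROUPS)
  x$parameters <- lapply(x$parameters, function(p) {
    lapply(p, function(v) stats::setNames(as.numeric(unlist(v)), GAIT_GROUPS))
  })
  for (f in c("pulse_amp_range", "pulse_width_range", "calibration_window")) {
    x[[f]] <- as.numeric(unlist(x[[f]]))
  }
  cfg <- c(x)
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  trials: %d x %g m walkway, %g Hz sampling\n",
              x$n_trials, x$walkway_length, x$sampling_rate))
  cat(sprintf("  noise: gyro %g deg/s, accel %g m/s^2, phase asym %g\n",
              x$gyro_noise_sd, x$accel_noise_sd, x$phase_asym_sd))
  cat(sprintf("  processing: Butterworth order %d @ %g Hz, threshold %g deg/s, alpha %g\n",
              x$filter_order, x$filter_cutoff, x$event_threshold, x$alpha))
  invisible(x)
}
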