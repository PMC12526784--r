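# The eleven-parameter gait feature set: spatiotemporal formulas from
# detected events plus sagittal joint ROMs, pooled over all trials.

#' Spatiotemporal gait parameters from segmented cycles
#'
#' Implements the event-based formulas: gait cycle time is the mean
#' same-side heel-strike interval; step time the mean interval between
#' alternating-side heel strikes; cadence = 60 / step time; walking
#' velocity = mean step length / step time; stance percentage is
#' (toe-off - heel-strike) / cycle time, swing its complement. Double
#' support comes from contralateral events: initial =
#' (contralateral toe-off - heel strike) / cycle time, terminal =
#' (toe-off - contralateral heel strike) / cycle time, single support =
#' stance - initial - terminal. Cycles with negative support intervals are
#' rejected and counted; cycles missing contralateral events contribute to
#' the temporal parameters only.
#'
#' @param cycles A `gait_cycles` data frame (both sides, possibly pooled
#'   across trials; all quantities are within-cycle differences).
#' @param step_lengths Per-step step-length estimates, m.
#' @param aggregate "mean" (default) or "median" across pooled cycles.
#' @return List with the eight temporal/spatial features (`gait_cycle_time`,
#'   `stance_pct`, `swing_pct`, `velocity`, `cadence`,
#'   `initial_double_support_pct`, `single_support_pct`,
#'   `terminal_double_support_pct`) and `diagnostics` (cycle counts).
#' @export
spatiotemporal_params <- function(cycles, step_lengths, aggregate = "mean") {
  if (nrow(cycles) == 0) stop("data error: no valid cycles")
  agg <- if (identical(aggregate, "median")) stats::median else mean

  dur <- cycles$duration
  stance_c <- (cycles$toe_off - cycles$start_hs) / dur * 100

  steps <- c(cycles$contra_hs - cycles$start_hs,
             cycles$end_hs - cycles$contra_hs)
  steps <- steps[!is.na(steps) & steps > 0]
  if (length(steps) == 0) stop("data error: no alternating heel strikes found")

  ids_c <- (cycles$contra_to - cycles$start_hs) / dur * 100
  tds_c <- (cycles$toe_off - cycles$contra_hs) / dur * 100
  bad_support <- (!is.na(ids_c) & ids_c < 0) | (!is.na(tds_c) & tds_c < 0)
  ids_c[bad_support] <- NA
  tds_c[bad_support] <- NA

  cycle_time <- agg(dur)
  step_time <- agg(steps)
  stance <- agg(stance_c)
  ids <- if (all(is.na(ids_c))) NA_real_ else agg(ids_c[!is.na(ids_c)])
  tds <- if (all(is.na(tds_c))) NA_real_ else agg(tds_c[!is.na(tds_c)])

  list(
    gait_cycle_time = cycle_time,
    stance_pct = stance,
    swing_pct = 100 - stance,
    velocity = agg(step_lengths) / step_time,
    cadence = 60 / step_time,
    initial_double_support_pct = ids,
    single_support_pct = stance - ids - tds,
    terminal_double_support_pct = tds,
    diagnostics = list(
      n_cycles = nrow(cycles),
      n_rejected_support = sum(bad_support),
      n_missing_contra = sum(is.na(cycles$contra_to) | is.na(cycles$contra_hs)),
      step_time = step_time
    )
  )
}

# Run the full single-subject extraction: filter, detect, segment, fuse,
# differentiate joints, and pool per-cycle quantities over all trials.
#' Extract the eleven gait features from one IMU recording
#'
#' Applies the full processing chain per trial -- zero-phase Butterworth
#' low-pass, gyroscope-peak event detection on both feet, cycle
#' segmentation, complementary-filter segment orientations, calibrated
#' hip/knee/ankle joint angles, inverted-pendulum step lengths -- then pools
#' valid cycles from all trials and aggregates.
#'
#' @param recording An `imu_recording`.
#' @param config A [cohort_config()] supplying the processing constants.
#' @param aggregate "mean" (default) or "median" cycle aggregation.
#' @return Named list: the 11 features ([gait_feature_names()]), plus
#'   `max_knee_flexion` (deg) and a `diagnostics` list (cycle counts,
#'   rejected cycles, events per trial).
#' @export
extract_gait_features <- function(recording, config = cohort_config(),
                                  aggregate = "mean") {
  fs <- recording$sampling_rate
  spec <- filter_spec(config$filter_order, config$filter_cutoff, fs)
  tt <- recording$time
  calib <- config$calibration_window

  all_cycles <- list()
  all_steps <- numeric(0)
  roms <- list(hip = numeric(0), knee = numeric(0), ankle = numeric(0))
  knee_flex <- numeric(0)
  n_skipped <- 0L

  for (tr in seq_along(recording$trials)) {
    segs <- recording$trials[[tr]]
    raw <- do.call(cbind, lapply(segs, function(s) {
      cbind(s$gyro[, 3], s$accel[, 1], s$accel[, 2])
    }))
    fm <- lowpass_filter_mat(raw, spec)
    filt <- stats::setNames(lapply(seq_along(segs), function(i) {
      j <- (i - 1) * 3
      list(gyro_z = fm[, j + 1], accel = fm[, j + 2:3])
    }), names(segs))
    ev_L <- detect_gait_events(filt$foot_L$gyro_z, fs, config$event_threshold,
                               config$min_separation, side = "L")
    ev_R <- detect_gait_events(filt$foot_R$gyro_z, fs, config$event_threshold,
                               config$min_separation, side = "R")
    cycles <- segment_cycles(ev_L, ev_R)
    if (nrow(cycles) == 0) next

    orient <- lapply(filt, function(f) {
      complementary_filter(f$gyro_z, f$accel, fs, config$alpha, calib)
    })
    for (side in c("L", "R")) {
      cyc_s <- cycles[cycles$side == side, ]
      if (nrow(cyc_s) == 0) next
      thigh <- orient[[paste0("thigh_", side)]]
      shank <- orient[[paste0("shank_", side)]]
      foot <- orient[[paste0("foot_", side)]]
      hip_a <- joint_angles(orient$pelvis, thigh, tt, calib)
      knee_a <- joint_angles(thigh, shank, tt, calib)
      ankle_a <- joint_angles(shank, foot, tt, calib)

      r_hip <- rom_per_cycle(hip_a, tt, cyc_s)
      r_knee <- rom_per_cycle(knee_a, tt, cyc_s)
      r_ankle <- rom_per_cycle(ankle_a, tt, cyc_s)
      roms$hip <- c(roms$hip, r_hip$per_cycle$rom)
      roms$knee <- c(roms$knee, r_knee$per_cycle$rom)
      roms$ankle <- c(roms$ankle, r_ankle$per_cycle$rom)
      knee_flex <- c(knee_flex, r_knee$per_cycle$max_flexion)
      n_skipped <- n_skipped + r_hip$n_skipped

      sl <- estimate_step_length(shank$angle, tt, cyc_s, recording$leg_length_m)
      all_steps <- c(all_steps, sl$per_cycle)
    }
    all_cycles[[length(all_cycles) + 1L]] <- cycles
  }

  if (length(all_cycles) == 0) {
    return(list(diagnostics = list(n_cycles = 0L,
                                   note = "no valid cycles in any trial")))
  }
  cycles <- do.call(rbind, all_cycles)
  sp <- spatiotemporal_params(cycles, all_steps, aggregate)
  agg <- if (identical(aggregate, "median")) stats::median else mean

  out <- sp[GAIT_FEATURES[GAIT_FEATURES %in% names(sp)]]
  out$hip_rom <- agg(roms$hip)
  out$knee_rom <- agg(roms$knee)
  out$ankle_rom <- agg(roms$ankle)
  out$max_knee_flexion <- agg(knee_flex)
  out$diagnostics <- c(sp$diagnostics, list(n_skipped_rom = n_skipped))
  out
}

#' Build the cohort feature table by running the extraction pipeline
#'
#' Synthesizes each subject's recording (from the master seed) and runs the
#' full extraction chain; subjects with zero valid cycles are excluded and
#' listed in the `excluded` attribute. Deterministic given `(cohort, config,
#' seed)`.
#'
#' @param cohort A `gait_cohort` from [sample_cohort()].
#' @param config The matching [cohort_config()].
#' @param seed Master seed (the same one used for recordings).
#' @param aggregate Cycle aggregation, "mean" or "median".
#' @return A `feature_table` data frame: `subject_id`, `group`, `cdr`, then
#'   the 11 features in canonical order.
#' @export
#' @examples
#' cfg <- cohort_config(group_sizes = c(healthy_control = 2, mci = 1,
#'                                      mild_dementia = 1, moderate_dementia = 1),
#'                      n_trials = 2)
#' cohort <- sample_cohort(cfg, seed = 7)
#' ft <- build_feature_table(cohort, cfg, seed = 7)
#' dim(ft)
build_feature_table <- function(cohort, config = attr(cohort, "config"),
                                seed = attr(cohort, "seed"),
                                aggregate = "mean") {
  stopifnot(inherits(cohort, "gait_cohort"))
  if (is.null(config)) config <- cohort_config()
  rows <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(cohort))) {
    rec <- synthesize_recording(cohort[i, ], config, seed)
    f <- extract_gait_features(rec, config, aggregate)
    if (is.null(f$gait_cycle_time) || !all(is.finite(unlist(f[GAIT_FEATURES])))) {
      excluded <- c(excluded, cohort$subject_id[i])
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject_id = cohort$subject_id[i],
                 group = cohort$group[i], cdr = cohort$cdr[i]),
      as.data.frame(f[GAIT_FEATURES])
    )
  }
  if (length(excluded) > 0) {
    message("excluded ", length(excluded), " subject(s) with no valid cycles: ",
            paste(excluded, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' Column order is subject_id, group, cdr, then the 11 features in canonical
#' order; values round-trip losslessly at double precision.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @return The path (write) or a `feature_table` (read).
#' @export
write_feature_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$group <- as.character(df$group)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = GAIT_GROUPS)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Gait feature table: %d subjects x %d features\n",
              nrow(x), sum(names(x) %in% GAIT_FEATURES)))
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
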