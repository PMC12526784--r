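# Cohort sampling: demographics and ground-truth gait parameter sets for the
# four severity groups.

#' Sample a synthetic four-group cohort
#'
#' Draws demographics (age, sex, height, weight) and a ground-truth gait
#' parameter set per subject from the configured group-conditional
#' distributions. Cadence is the primary temporal draw; cycle time
#' (120/cadence), step time (60/cadence) and step length
#' (velocity x step time) are derived so every subject's parameter set is
#' internally consistent. In steady-state periodic gait the side-averaged
#' double-support phases are tied to stance (initial = terminal =
#' stance - 50, single support = 100 - stance), so those fields are derived
#' from the drawn stance percentage rather than drawn independently.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return A data frame of class `gait_cohort`, one row per subject:
#'   demographics (`age`, `sex`, `height_cm`, `weight_kg`, `bmi`,
#'   `leg_length_m`), group labels (`group`, `cdr`) and the ground-truth gait
#'   parameters (the 11 canonical features plus `step_time` and
#'   `step_length`).
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_config(), seed = 1)
#' table(cohort$group)
sample_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_config(config)
  with_seed(derive_seed(seed, "cohort"), {
    rows <- lapply(seq_along(GAIT_GROUPS), function(gi) {
      grp <- GAIT_GROUPS[gi]
      n <- as.integer(config$group_sizes[[grp]])
      draw <- function(pname) {
        p <- config$parameters[[pname]]
        rtruncnorm(n, p$location[gi], p$scale[gi], p$lower[gi], p$upper[gi])
      }
      sex <- ifelse(stats::runif(n) < config$male_fraction[[grp]], "male", "female")
      age <- draw("age")
      height <- draw("height")
      weight <- draw("weight")
      cadence <- draw("cadence")
      velocity <- draw("velocity")
      stance <- draw("stance_pct")
      hip <- draw("hip_rom")
      knee <- draw("knee_rom")
      ankle <- draw("ankle_rom")
      cycle_time <- 120 / cadence
      step_time <- 60 / cadence
      step_length <- velocity * step_time
      data.frame(
        subject_id = sprintf("%s_%02d", GROUP_PREFIX[[grp]], seq_len(n)),
        group = grp, cdr = GROUP_CDR[[grp]],
        age = age, sex = sex, height_cm = height, weight_kg = weight,
        bmi = weight / (height / 100)^2,
        leg_length_m = config$leg_length_fraction * height / 100,
        cadence = cadence, gait_cycle_time = cycle_time,
        step_time = step_time, step_length = step_length,
        velocity = velocity, stance_pct = stance, swing_pct = 100 - stance,
        initial_double_support_pct = stance - 50,
        single_support_pct = 100 - stance,
        terminal_double_support_pct = stance - 50,
        hip_rom = hip, knee_rom = knee, ankle_rom = ankle,
        stringsAsFactors = FALSE
      )
    })
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    cohort$group <- factor(cohort$group, levels = GAIT_GROUPS)
    attr(cohort, "config") <- config
    attr(cohort, "seed") <- seed
    class(cohort) <- c("gait_cohort", "data.frame")
    cohort
  })
}

#' Ground-truth feature table of a cohort
#'
#' Returns the generator's own parameter draws as a feature table (subject id,
#' group, CDR, then the 11 canonical gait features). This is the noiseless
#' ground truth that the signal-extraction pipeline estimates; use
#' [build_feature_table()] to obtain the pipeline's estimates instead.
#'
#' @param cohort A `gait_cohort`.
#' @return A `feature_table` data frame.
#' @export
cohort_parameter_table <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  out <- cohort[, c("subject_id", "group", "cdr", GAIT_FEATURES)]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Demographic table of a cohort
#'
#' @param cohort A `gait_cohort`.
#' @return Data frame with subject_id, group, cdr, age, sex, height_cm,
#'   weight_kg, bmi.
#' @export
cohort_demographics <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  cohort[, c("subject_id", "group", "cdr", "age", "sex", "height_cm",
             "weight_kg", "bmi")]
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("Synthetic gait cohort: %d subjects\n", nrow(x)))
  print(table(x$group))
  invisible(x)
}
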