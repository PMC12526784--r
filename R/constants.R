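# Group coding and the fixed feature order used throughout the package.

GAIT_GROUPS <- c("healthy_control", "mci", "mild_dementia", "moderate_dementia")
GROUP_CDR <- c(healthy_control = 0, mci = 0.5, mild_dementia = 1, moderate_dementia = 2)
GROUP_PREFIX <- c(healthy_control = "hc", mci = "mci", mild_dementia = "mild",
                  moderate_dementia = "mod")

GAIT_FEATURES <- c(
  "gait_cycle_time", "stance_pct", "swing_pct", "velocity", "cadence",
  "initial_double_support_pct", "single_support_pct",
  "terminal_double_support_pct", "hip_rom", "knee_rom", "ankle_rom"
)

#' Severity group labels and their Clinical Dementia Rating codes
#'
#' The cohort is stratified into four severity groups keyed to the Clinical
#' Dementia Rating (CDR): healthy control (CDR 0), mild cognitive impairment
#' (CDR 0.5), mild dementia (CDR 1) and moderate dementia (CDR 2).
#'
#' @return Named numeric vector mapping group label to CDR.
#' @export
#' @examples
#' group_cdr_map()
group_cdr_map <- function() GROUP_CDR

#' The eleven gait parameters, in canonical table order
#'
#' Order is fixed and used for every exported feature table: gait cycle time
#' (s), stance and swing phase (% of cycle), walking velocity (m/s), cadence
#' (steps/min), initial double support, single support and terminal double
#' support (% of cycle), then sagittal hip, knee and ankle range of motion
#' (deg).
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' gait_feature_names()
gait_feature_names <- function() GAIT_FEATURES
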