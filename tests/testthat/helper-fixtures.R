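# Shared fixtures: a small cohort configuration for signal-level tests and
# fast ground-truth feature tables for statistical tests.

tiny_config <- function(n_trials = 2L, ...) {
  cohort_config(group_sizes = c(healthy_control = 8L, mci = 6L,
                                mild_dementia = 5L, moderate_dementia = 5L),
                n_trials = n_trials, ...)
}

# One representative subject per group from the default study conditions.
one_per_group <- function(seed = 42L) {
  cohort <- sample_cohort(cohort_config(), seed = seed)
  idx <- vapply(levels(cohort$group), function(g) which(cohort$group == g)[1],
                integer(1))
  cohort[idx, ]
}

# Ground-truth feature table of the default cohort (no signal synthesis).
truth_table <- function(seed) {
  cohort_parameter_table(sample_cohort(cohort_config(), seed = seed))
}

# Build synthetic gait cycles directly (for spatiotemporal unit tests).
make_cycles <- function(start_hs, toe_off, end_hs, side = "R",
                        contra_to = NA_real_, contra_hs = NA_real_) {
  df <- data.frame(side = side, start_hs = start_hs, toe_off = toe_off,
                   end_hs = end_hs, contra_to = contra_to,
                   contra_hs = contra_hs, duration = end_hs - start_hs)
  class(df) <- c("gait_cycles", "data.frame")
  df
}
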