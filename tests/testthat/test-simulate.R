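test_that("noiseless heel strikes are spaced exactly one cycle apart", {
  cfg <- noiseless_config(tiny_config())
  cohort <- sample_cohort(cfg, seed = 1)
  p <- cohort[1, ]
  rec <- synthesize_recording(p, cfg, seed = 1)
  gt <- rec$ground_truth[rec$ground_truth$trial == 1, ]
  for (side in c("L", "R")) {
    hs <- sort(gt$time[gt$side == side & gt$type == "heel_strike"])
    expect_equal(diff(hs), rep(p$gait_cycle_time, length(hs) - 1),
                 tolerance = 1e-9)
  }
})

test_that("recordings are deterministic in the seed and vary across seeds", {
  cfg <- tiny_config()
  cohort <- sample_cohort(cfg, seed = 4)
  a <- synthesize_recording(cohort[1, ], cfg, seed = 4)
  b <- synthesize_recording(cohort[1, ], cfg, seed = 4)
  cc <- synthesize_recording(cohort[1, ], cfg, seed = 5)
  expect_identical(a$trials[[1]]$foot_R$gyro, b$trials[[1]]$foot_R$gyro)
  expect_false(identical(a$trials[[1]]$foot_R$gyro, cc$trials[[1]]$foot_R$gyro))
  # trials within a recording differ only by noise realization
  expect_false(identical(a$trials[[1]]$foot_R$gyro, a$trials[[2]]$foot_R$gyro))
})

test_that("trial structure honours the standing period and series lengths", {
  cfg <- tiny_config()
  cohort <- sample_cohort(cfg, seed = 6)
  rec <- synthesize_recording(cohort[1, ], cfg, seed = 6)
  expect_equal(length(rec$trials), cfg$n_trials)
  n <- length(rec$time)
  for (seg in names(rec$trials[[1]])) {
    expect_equal(nrow(rec$trials[[1]][[seg]]$gyro), n)
    expect_equal(nrow(rec$trials[[1]][[seg]]$accel), n)
  }
  expect_equal(diff(rec$time)[1], 1 / cfg$sampling_rate)
  # all events happen after >= 2 s static standing
  expect_gte(min(rec$ground_truth$time), 2)
  # stride count respects the walkway length
  p <- cohort[1, ]
  expect_equal(rec$n_strides,
               max(2L, floor(cfg$walkway_length / (2 * p$step_length))))
})

test_that("step lengths too long for the walkway are rejected", {
  cfg <- tiny_config()
  cohort <- sample_cohort(cfg, seed = 2)
  p <- cohort[1, ]
  p$step_length <- cfg$walkway_length / 3
  expect_error(synthesize_recording(p, cfg, seed = 1), "strides")
})

test_that("full pipeline inverts the generator in the noiseless limit", {
  cfg0 <- noiseless_config(cohort_config())
  subjects <- one_per_group(seed = 42)
  for (i in seq_len(nrow(subjects))) {
    rec <- synthesize_recording(subjects[i, ], cfg0, seed = 42)
    f <- extract_gait_features(rec, cfg0)
    truth <- unlist(subjects[i, gait_feature_names()])
    est <- unlist(f[gait_feature_names()])
    expect_true(all(abs(est - truth) / truth < 0.01),
                label = paste("noiseless round trip for",
                              subjects$subject_id[i]))
  }
})

test_that("default-noise recordings keep the round trip within 5%", {
  cfg <- cohort_config()
  subjects <- one_per_group(seed = 31)
  for (i in seq_len(nrow(subjects))) {
    rec <- synthesize_recording(subjects[i, ], cfg, seed = 31)
    f <- extract_gait_features(rec, cfg)
    truth <- unlist(subjects[i, gait_feature_names()])
    est <- unlist(f[gait_feature_names()])
    expect_true(all(abs(est - truth) / truth < 0.05))
  }
})

test_that("the event detector recovers ground-truth events under default noise", {
  cfg <- cohort_config()
  subjects <- one_per_group(seed = 17)
  spec <- filter_spec(cfg$filter_order, cfg$filter_cutoff, cfg$sampling_rate)
  n_events <- 0L
  n_hit <- 0L
  for (i in seq_len(nrow(subjects))) {
    rec <- synthesize_recording(subjects[i, ], cfg, seed = 17)
    for (tr in seq_along(rec$trials)) {
      for (side in c("L", "R")) {
        x <- lowpass_filter(rec$trials[[tr]][[paste0("foot_", side)]]$gyro[, 3], spec)
        ev <- detect_gait_events(x, cfg$sampling_rate, cfg$event_threshold,
                                 cfg$min_separation, side = side)
        gt <- rec$ground_truth[rec$ground_truth$trial == tr &
                                 rec$ground_truth$side == side, ]
        for (k in seq_len(nrow(gt))) {
          n_events <- n_events + 1L
          d <- suppressWarnings(min(abs(ev$time[ev$type == gt$type[k]] - gt$time[k])))
          if (is.finite(d) && d <= 0.02) n_hit <- n_hit + 1L
        }
      }
    }
  }
  expect_gte(n_hit / n_events, 0.99)
})

test_that("recordings round-trip through long-format CSV", {
  cfg <- tiny_config(n_trials = 1L)
  cohort <- sample_cohort(cfg, seed = 9)
  rec <- synthesize_recording(cohort[1, ], cfg, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path, subject_id = rec$subject_id,
                             sampling_rate = cfg$sampling_rate,
                             leg_length_m = rec$leg_length_m)
  expect_equal(back$trials[[1]]$foot_R$gyro[, 3],
               unname(rec$trials[[1]]$foot_R$gyro[, 3]), tolerance = 1e-9)
  expect_equal(back$trials[[1]]$pelvis$accel[, 2],
               unname(rec$trials[[1]]$pelvis$accel[, 2]), tolerance = 1e-9)
})
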