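# gaitsev — gait-based dementia severity analysis from wearable IMU signals

Gait slows and stiffens as cognition declines: walking velocity and
cadence fall, gait cycles lengthen, and sagittal hip/knee/ankle excursions
shrink. `gaitsev` is an R package for studying how well inertial
measurement units (IMUs) can grade dementia severity from gait alone, in a
four-group design keyed to the Clinical Dementia Rating (CDR): healthy
control (CDR 0), mild cognitive impairment (CDR 0.5), mild dementia
(CDR 1) and moderate dementia (CDR 2).

It is aimed at researchers in digital gait biomarkers who want a fully
reproducible, end-to-end reference pipeline — from raw six-axis segment
signals to severity classification — together with a calibrated synthetic
cohort generator that stands in for clinical recordings that cannot be
shared.

## What the package computes

For each subject (8 walking trials over an 8 m walkway, 7 body-segment
IMUs at 100 Hz):

1. **Signal conditioning** — zero-phase 4th-order Butterworth low-pass at
   20 Hz on all gyroscope/accelerometer channels.
2. **Gait events** — heel strikes as local maxima of the foot sagittal
   angular velocity above +50 °/s, toe-offs as minima below −50 °/s, with
   alternation enforcement; cycles between consecutive same-side heel
   strikes.
3. **Spatiotemporal parameters** — cycle time; cadence = 60/step time;
   velocity = step length / step time (step length from an
   inverted-pendulum shank model, 2·L·sin(Δθ/2)); stance/swing and the
   double/single-support percentages from contralateral events.
4. **Kinematics** — sagittal segment orientations by complementary
   filtering, θ_t = α(θ_{t−1} + ω̄Δt) + (1−α)·atan2(a_x, a_y); joint
   angles as calibrated segment differences; per-cycle range of motion
   (ROM) for hip, knee, ankle.
5. **Feature ranking** — multiclass ReliefF (k = 10, Manhattan distance
   on range-normalized features, prior-weighted misses).
6. **Severity classification** — stratified 5-fold cross-validated RBF
   SVM over the selected features, with a 4×4 confusion matrix and macro
   one-vs-rest accuracy/PPV/sensitivity/specificity/F1/NPV/AUC.
7. **Statistics** — Kolmogorov–Smirnov (Lilliefors, Monte-Carlo
   calibrated) normality screening, Kruskal–Wallis with the six
   Bonferroni-corrected pairwise flags (threshold 0.05/6 = 0.0083),
   Fisher's exact test, and logistic regression (dementia vs healthy)
   with odds ratios, 95 % CIs and max-rescaled (Nagelkerke) R².

The synthetic cohort generator draws each subject's demographics and
ground-truth gait parameters from group-conditional distributions
calibrated to published four-group summaries (e.g. healthy velocity
1.2 m/s vs moderate dementia 0.6 m/s; knee ROM 53.9° vs 38.9°), then
synthesizes IMU trials whose signals embed those parameters exactly in
the noiseless limit — so every stage of the pipeline can be validated by
round trip. See the methods vignette
(`vignettes/gait-severity-methods.Rmd`) for the signal model and all
design decisions.

## A worked example

A reduced cohort for speed; defaults reproduce the full 139-subject
study conditions.

```r
library(gaitsev)

cfg <- cohort_config(group_sizes = c(healthy_control = 12, mci = 10,
                                     mild_dementia = 8, moderate_dementia = 8),
                     n_trials = 2)
cohort <- sample_cohort(cfg, seed = 7)
features <- build_feature_table(cohort, cfg, seed = 7)   # full signal pipeline
head(as.data.frame(features)[, c("subject_id", "group", "velocity", "knee_rom")])
#>   subject_id           group velocity knee_rom
#> 1      hc_01 healthy_control    1.196    54.59
#> 2      hc_02 healthy_control    1.248    50.91
#> 3      hc_03 healthy_control    1.212    55.96
#> 4      hc_04 healthy_control    1.270    48.01

w <- relieff_weights(features, seed = 7)
rank_and_select(w, 4)
#> [1] "velocity"        "gait_cycle_time" "knee_rom"        "hip_rom"

report <- train_eval_svm(features, rank_and_select(w, 4), folds = 3, seed = 7)
report$confusion
#>                    predicted
#> actual              healthy_control mci mild_dementia moderate_dementia
#>   healthy_control                 8   4             0                 0
#>   mci                             5   5             0                 0
#>   mild_dementia                   0   1             5                 2
#>   moderate_dementia               0   0             5                 3
round(report$accuracy, 1)
#> [1] 55.3
```

The extracted velocities and knee ROMs sit on their generating group
distributions (healthy controls near 1.2 m/s and 54°), velocity ranks
first, and the confusion matrix shows the characteristic pattern: healthy
vs dementia separates cleanly while adjacent severity stages (here with
only 8–12 subjects per group) blur into each other. At the full cohort
size the cross-validated 4-class accuracy is about 78–82 %, with errors
concentrated in the mild/moderate pair — see the vignette for why that
pair is intrinsically hard at the published group spreads.

An end-to-end run with artifacts (cohort CSV, feature table, ReliefF
ranks, SVM report, logistic fits, group-comparison table, reproducibility
manifest):

```r
run_pipeline(cohort_config(), seed = 1, out_dir = "gaitsev_run")
```

or from a shell, `Rscript inst/cli/gaitsev-pipeline.R --seed 1 --out gaitsev_run`.

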