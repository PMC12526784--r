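test_that("metric arithmetic matches hand calculation on a fixed confusion", {
  cm <- matrix(c(50, 4, 0, 0,
                 5, 27, 2, 0,
                 0, 3, 20, 2,
                 0, 0, 4, 22), nrow = 4, byrow = TRUE)
  m <- multiclass_metrics(cm)
  expect_equal(m$accuracy, 100 * 119 / 139, tolerance = 1e-10)
  expect_equal(round(m$accuracy, 2), 85.61)
  sens <- mean(c(50 / 54, 27 / 34, 20 / 25, 22 / 26)) * 100
  expect_equal(m$recall_sensitivity, sens, tolerance = 1e-10)
  expect_equal(round(sens, 2), 84.15)
  expect_equal(m$f1,
               2 * m$precision_ppv * m$recall_sensitivity /
                 (m$precision_ppv + m$recall_sensitivity))
})

test_that("degenerate confusion matrices behave as documented", {
  expect_equal(multiclass_metrics(diag(c(5, 7, 9)))$accuracy, 100)
  expect_equal(multiclass_metrics(diag(c(5, 7, 9)))$f1, 100)
  m2 <- multiclass_metrics(matrix(c(1, 1, 1, 1), 2))
  expect_equal(m2$accuracy, 50)
  expect_equal(m2$precision_ppv, 50)
  expect_equal(m2$recall_sensitivity, 50)
  # zero-denominator class contributes 0 with a warning
  expect_warning(m3 <- multiclass_metrics(matrix(c(2, 1, 0, 0), 2)), "zero")
  expect_equal(m3$per_class$ppv[2], 0)
  expect_error(multiclass_metrics(matrix(0, 2, 2)), "positive total")
})

test_that("perfectly separated clusters classify at 100% with AUC 1", {
  cfg <- noiseless_config(cohort_config(), parameter_scales = TRUE)
  tab <- cohort_parameter_table(sample_cohort(cfg, seed = 1))
  rep <- train_eval_svm(tab, folds = 5, seed = 1)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$auc, 1)
  expect_equal(sum(rep$confusion), 139)
  expect_equal(unname(rowSums(rep$confusion)), c(54, 34, 25, 26))
})

test_that("cross-validation is seed-deterministic and conserves the cohort", {
  tab <- truth_table(5)
  a <- train_eval_svm(tab, folds = 5, seed = 9)
  b <- train_eval_svm(tab, folds = 5, seed = 9)
  expect_identical(a$confusion, b$confusion)
  expect_equal(sum(a$confusion), nrow(tab))
  expect_error(train_eval_svm(tab, folds = 30, seed = 1), "stratification")
})

test_that("label permutation drives accuracy to the majority-class rate", {
  tab <- truth_table(2)
  accs <- vapply(1:50, function(s) {
    set.seed(s)
    perm <- tab
    perm$group <- sample(perm$group)
    suppressWarnings(train_eval_svm(perm, folds = 5, seed = s)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 * 54 / 139), 3 * sd(accs))
})

test_that("logistic regression reproduces the contingency-table odds ratio", {
  # binary predictor with outcome counts [[30,10],[10,30]] -> OR = 9
  df <- data.frame(
    group = rep(c("healthy_control", "mild_dementia"), each = 40),
    x = c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  )
  class(df) <- c("feature_table", "data.frame")
  fit <- fit_logistic(df, "x")
  expect_equal(fit$coefficients$odds_ratio, (30 * 30) / (10 * 10),
               tolerance = 1e-6)
  expect_equal(fit$n, 80)
})

test_that("Nagelkerke R-squared hits its analytic limits", {
  set.seed(3)
  df <- data.frame(
    group = rep(c("healthy_control", "moderate_dementia"), each = 30),
    flat = rnorm(60),
    perfect = c(rnorm(30, -4), rnorm(30, 4))
  )
  class(df) <- c("feature_table", "data.frame")
  # an uninformative predictor leaves the null model: R2 ~ 0
  fit0 <- fit_logistic(df, "flat")
  expect_lt(fit0$max_rescaled_r_square, 0.1)
  expect_gte(fit0$max_rescaled_r_square, 0)
  # a perfectly separating predictor approaches 1 and raises the flag
  fit1 <- suppressWarnings(fit_logistic(df, "perfect"))
  expect_gt(fit1$max_rescaled_r_square, 0.95)
  expect_true(fit1$separation)
  expect_equal(fit1$classification_accuracy, 100)
})

test_that("singular designs are rejected with the collinear predictor named", {
  tab <- truth_table(4)
  tab$dup <- tab$knee_rom
  expect_error(fit_logistic(tab, c("knee_rom", "dup")), "collinear")
})

test_that("ROM coefficients point the direction of lower angles in dementia", {
  signs <- vapply(1:20, function(s) {
    tab <- truth_table(600 + s)
    fit <- suppressWarnings(fit_logistic(tab, c("knee_rom", "hip_rom")))
    all(fit$coefficients$estimate < 0)
  }, logical(1))
  expect_gte(mean(signs), 0.9)
})

test_that("cross-validated logistic accuracy pools held-out folds", {
  tab <- truth_table(8)
  cv <- cv_logistic(tab, c("knee_rom", "hip_rom"), folds = 5, seed = 8)
  expect_equal(sum(cv$confusion), cv$n)
  expect_equal(cv$accuracy, 100 * sum(diag(cv$confusion)) / cv$n)
  expect_equal(cv$n, sum(tab$group %in% c("healthy_control", "mild_dementia",
                                          "moderate_dementia")))
})

test_that("the univariable/multivariable table reports one row per predictor", {
  tab <- truth_table(9)
  lt <- suppressWarnings(logistic_table(tab, c("knee_rom", "hip_rom")))
  expect_equal(lt$univariable$predictor, c("knee_rom", "hip_rom"))
  expect_equal(nrow(lt$multivariable$coefficients), 2L)
  expect_true(all(lt$univariable$ci_lower <= lt$univariable$ci_upper))
  expect_gte(lt$multivariable$max_rescaled_r_square, 0)
  expect_lte(lt$multivariable$max_rescaled_r_square, 1)
})
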