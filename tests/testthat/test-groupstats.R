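# Exhaustive two-sided Fisher oracle for 2x2 tables.
fisher_2x2_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Kruskal-Wallis matches the hand-ranked worked example", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-10)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  ident <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("Kruskal-Wallis p agrees with exact permutation enumeration, N <= 10", {
  groups <- list(c(1.2, 3.4, 2.2), c(5.1, 4.4, 6.0), c(0.5, 2.8))
  kw <- kruskal_wallis(groups)
  values <- unlist(groups)
  sizes <- lengths(groups)
  # enumerate permutations by repeated sampling without replacement is not
  # exhaustive; instead enumerate all assignments of ranks to groups
  idx <- seq_along(values)
  combs1 <- combn(idx, sizes[1])
  count <- 0L; total <- 0L
  h_of <- function(split1, split2, split3) {
    kruskal_wallis(list(values[split1], values[split2], values[split3]))$statistic
  }
  h_obs <- kw$statistic
  for (i in seq_len(ncol(combs1))) {
    g1 <- combs1[, i]
    rest <- setdiff(idx, g1)
    combs2 <- combn(rest, sizes[2])
    for (j in seq_len(ncol(combs2))) {
      g2 <- combs2[, j]
      g3 <- setdiff(rest, g2)
      total <- total + 1L
      if (h_of(g1, g2, g3) >= h_obs - 1e-12) count <- count + 1L
    }
  }
  exact_p <- count / total
  # chi-square approximation should sit near the exact permutation p
  expect_lt(abs(kw$p_value - exact_p), 0.05)
})

test_that("KW statistic is invariant under strictly monotone transforms", {
  set.seed(12)
  groups <- list(rnorm(10), rnorm(8, 1), rnorm(9, 2))
  h1 <- kruskal_wallis(groups)$statistic
  h2 <- kruskal_wallis(lapply(groups, function(g) exp(g)))$statistic
  h3 <- kruskal_wallis(lapply(groups, function(g) g^3 + 5))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("the Bonferroni threshold for 6 pairwise comparisons prints as 0.0083", {
  groups <- replicate(4, rnorm(10), simplify = FALSE)
  ph <- pairwise_posthoc(groups, family_alpha = 0.05)
  expect_equal(ph$threshold, 0.0083)
  expect_equal(nrow(ph$pairs), 6L)
  expect_equal(ph$pairs$label, letters[1:6])

  ident <- pairwise_posthoc(replicate(4, rep(1:5, 2), simplify = FALSE))
  expect_equal(length(ident$significant_pairs), 0L)

  bad <- list(hc = rnorm(5), mci = numeric(0), mild = rnorm(5), mod = rnorm(5))
  expect_error(pairwise_posthoc(bad), "mci")
})

test_that("velocity separates the severity groups pairwise", {
  # pairs a-e are decisively separated at the corrected level in nearly all
  # cohorts; the mild-vs-moderate pair (f: 0.7 vs 0.6 m/s at the printed
  # IQR spread) is power-limited, so it is only required in a minority
  hits_ae <- vapply(1:20, function(s) {
    tab <- truth_table(800 + s)
    ph <- pairwise_posthoc(split(tab$velocity, tab$group))
    all(letters[1:5] %in% ph$significant_pairs)
  }, logical(1))
  expect_gte(mean(hits_ae), 0.9)
})

test_that("Fisher 2x2 equals exhaustive hypergeometric enumeration", {
  m <- matrix(c(3, 1, 1, 3), 2)
  fx <- fisher_exact(m)
  expect_equal(fx$p_value, 34 / 70, tolerance = 1e-10)
  expect_equal(fx$p_value, fisher_2x2_oracle(m), tolerance = 1e-10)

  set.seed(21)
  for (rep in 1:50) {
    m <- matrix(rpois(4, 4), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0) || sum(m) > 40) next
    expect_equal(fisher_exact(m)$p_value, fisher_2x2_oracle(m),
                 tolerance = 1e-8, label = paste(m, collapse = ","))
  }

  expect_warning(fx0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(fx0$p_value, 1)
})

test_that("sex-by-group tables from a balanced configuration are null", {
  cfg <- cohort_config(male_fraction = c(healthy_control = 0.4, mci = 0.4,
                                         mild_dementia = 0.4,
                                         moderate_dementia = 0.4))
  ps <- vapply(1:20, function(s) {
    cohort <- sample_cohort(cfg, seed = 900 + s)
    tab <- table(cohort$sex, cohort$group)
    fisher_exact(unclass(tab), seed = s, B = 2e4)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("normality screen is calibrated and has power", {
  pass_norm <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    ks_normality(rnorm(500), n_mc = 1000, seed = 5)$pass
  }, logical(1))
  expect_gte(mean(pass_norm), 0.90)

  fail_exp <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    !ks_normality(rexp(500), n_mc = 1000, seed = 5)$pass
  }, logical(1))
  expect_gte(mean(fail_exp), 0.95)

  cst <- ks_normality(rep(3, 20))
  expect_false(cst$pass)
  expect_equal(cst$reason, "zero variance")
  expect_error(ks_normality(rnorm(5)), "at least 8")
})

test_that("normality screen agrees with an established Lilliefors implementation", {
  skip_if_not_installed("nortest")
  set.seed(14)
  for (rep in 1:10) {
    x <- if (rep %% 2) rnorm(60) else rlnorm(60)
    ours <- ks_normality(x, n_mc = 4000, seed = 3)
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    # decisions agree except in a narrow indifference band around 0.05
    if (ref$p.value < 0.02 || ref$p.value > 0.15) {
      expect_equal(ours$pass, ref$p.value > 0.05)
    }
  }
})

test_that("cohort summary emits ordered rows with pair flags", {
  cfg <- cohort_config()
  cohort <- sample_cohort(cfg, seed = 27)
  tab <- cohort_parameter_table(cohort)
  cmp <- summarize_cohort(tab, cohort_demographics(cohort), seed = 27,
                          n_mc = 500)
  expect_s3_class(cmp, "group_comparison")
  # demographics (4 rows + sex) followed by the 11 gait parameters in order
  expect_equal(cmp$parameter[1:5],
               c("age_years", "height_cm", "weight_kg", "bmi_kg_m2", "sex_male"))
  expect_equal(cmp$parameter[6:16], gait_feature_names())
  vel <- cmp[cmp$parameter == "velocity", ]
  expect_lt(vel$p_value, 0.0001)
  expect_gte(nchar(vel$significant_pairs), 1)
  lines <- format_group_table(cmp)
  expect_true(any(grepl("0.0083", lines)))

  one_group <- tab[tab$group == "mci", ]
  expect_error(summarize_cohort(one_group, NULL), "4 severity groups")
})

test_that("Dunn's z post hoc agrees with the rank-sum flags on separated data", {
  tab <- truth_table(901)
  groups <- split(tab$velocity, tab$group)
  rs <- pairwise_posthoc(groups, method = "ranksum")
  dn <- pairwise_posthoc(groups, method = "dunn")
  expect_equal(dn$threshold, rs$threshold)
  expect_true(all(is.finite(dn$pairs$p_value)))
  # the decisively separated pairs (a-e) flag under both statistics
  expect_true(all(letters[1:5] %in% dn$significant_pairs))
})
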