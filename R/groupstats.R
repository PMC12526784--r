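# The group-comparison statistical battery: Monte-Carlo-calibrated
# normality screening, Kruskal-Wallis omnibus, Bonferroni-corrected
# pairwise post hoc, Fisher's exact test, and the four-group summary table.

.null_cache <- new.env(parent = emptyenv())

# Lilliefors statistic: KS distance against a normal with estimated moments.
lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

# Null distribution of the statistic for sample size n, cached per (n, B).
lillie_null <- function(n, n_mc, seed) {
  key <- paste0("n", n, "_B", n_mc, "_s", seed)
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  d <- with_seed(derive_seed(seed, "lilliefors", n, n_mc), {
    vapply(seq_len(n_mc), function(i) lillie_stat(stats::rnorm(n)), numeric(1))
  })
  .null_cache[[key]] <- d
  d
}

#' Kolmogorov-Smirnov normality screen (Lilliefors, Monte-Carlo calibrated)
#'
#' One-sample KS distance of the data against a normal with estimated mean
#' and SD. Because the moments are estimated, the p-value is calibrated by
#' seeded Monte Carlo: the statistic is compared with its null distribution
#' over `n_mc` normal samples of the same size (cached per sample size).
#'
#' @param values Numeric sample (n >= 8).
#' @param alpha Decision level (default 0.05).
#' @param n_mc Monte-Carlo replicates (default 10000).
#' @param seed Seed for the null calibration.
#' @return List: `statistic`, `p_value`, `pass` (TRUE when p > alpha),
#'   `reason` (set when the screen fails structurally, e.g. zero variance).
#' @export
#' @examples
#' ks_normality(rnorm(100), seed = 1)$pass
ks_normality <- function(values, alpha = 0.05, n_mc = 10000L, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) stop("data error: need at least 8 values for the normality screen")
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p_value = 0, pass = FALSE,
                reason = "zero variance"))
  }
  d <- lillie_stat(values)
  null <- lillie_null(n, n_mc, seed)
  p <- (1 + sum(null >= d)) / (n_mc + 1)
  list(statistic = d, p_value = p, pass = p > alpha, reason = NULL)
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric omnibus comparison of two or more groups using midranks
#' with tie correction; the statistic is referred to a chi-square with
#' k - 1 degrees of freedom. Identical values across all groups give H = 0,
#' p = 1.
#'
#' @param groups List of numeric vectors (one per group).
#' @return List: `statistic` (H), `p_value`, `df`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic # 7.2
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 1) || sum(ns) < 3) stop("data error: too few observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  if (stats::sd(values) == 0) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

PAIR_LABELS <- data.frame(
  label = letters[1:6],
  i = c(1, 1, 1, 2, 2, 3),
  j = c(2, 3, 4, 3, 4, 4)
)

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' All six pairwise comparisons among the four severity groups, labelled
#' a-f in the conventional order (a: healthy vs MCI, b: healthy vs mild,
#' c: healthy vs moderate, d: MCI vs mild, e: MCI vs moderate, f: mild vs
#' moderate). Each pair is tested with a two-sided rank-sum test (or Dunn's
#' rank z-test); significance is declared at `family_alpha / 6`
#' (0.05 / 6 = 0.0083).
#'
#' @param groups List of exactly 4 numeric vectors in severity order.
#' @param family_alpha Family-wise level (default 0.05).
#' @param method "ranksum" (default, two-sided Wilcoxon) or "dunn".
#' @return List: `pairs` data frame (label, groups, p_value, significant),
#'   `threshold` (the corrected level), `significant_pairs` (labels).
#' @export
pairwise_posthoc <- function(groups, family_alpha = 0.05,
                             method = c("ranksum", "dunn")) {
  method <- match.arg(method)
  if (length(groups) != 4) stop("data error: exactly 4 groups required")
  empty <- lengths(groups) == 0
  if (any(empty)) {
    nm <- names(groups) %||% as.character(seq_along(groups))
    stop("data error: empty group: ", paste(nm[empty], collapse = ", "))
  }
  n_pairs <- nrow(PAIR_LABELS)
  threshold <- family_alpha / n_pairs

  if (method == "dunn") {
    values <- unlist(groups, use.names = FALSE)
    ns <- lengths(groups)
    g <- rep(seq_along(groups), ns)
    r <- rank(values)
    N <- length(values)
    rbar <- tapply(r, g, mean)
    ties <- table(values)
    tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
    s2 <- N * (N + 1) / 12 - tie_corr
  }
  p <- vapply(seq_len(n_pairs), function(k) {
    i <- PAIR_LABELS$i[k]; j <- PAIR_LABELS$j[k]
    if (method == "ranksum") {
      suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]],
                                          exact = FALSE, correct = TRUE)$p.value)
    } else {
      z <- (rbar[i] - rbar[j]) /
        sqrt(s2 * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
      2 * stats::pnorm(-abs(z))
    }
  }, numeric(1))

  pairs <- data.frame(
    label = PAIR_LABELS$label,
    group_i = GAIT_GROUPS[PAIR_LABELS$i],
    group_j = GAIT_GROUPS[PAIR_LABELS$j],
    p_value = p,
    significant = p < threshold
  )
  list(pairs = pairs, threshold = round(threshold, 4),
       significant_pairs = pairs$label[pairs$significant])
}

#' Fisher's exact test for contingency tables
#'
#' 2x2 tables are solved exactly (two-sided: sum of hypergeometric
#' probabilities not exceeding the observed table's). Larger tables use a
#' seeded Monte-Carlo over margin-preserving tables. A table with a zero
#' margin is degenerate and returns p = 1 with a warning.
#'
#' @param table_counts Matrix of non-negative integer counts.
#' @param seed Seed for the Monte-Carlo path.
#' @param B Monte-Carlo replicates when r x c > 4 (default 1e5).
#' @return List: `p_value`, `method`.
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value # 34/70
fisher_exact <- function(table_counts, seed = 1L, B = 1e5) {
  m <- as.matrix(table_counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("data error: counts must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate table with a zero margin; p = 1")
    return(list(p_value = 1, method = "degenerate"))
  }
  if (length(m) <= 4) {
    list(p_value = stats::fisher.test(m)$p.value, method = "exact")
  } else {
    p <- with_seed(derive_seed(seed, "fisher"), {
      stats::fisher.test(m, simulate.p.value = TRUE, B = as.integer(B))$p.value
    })
    list(p_value = p, method = sprintf("monte-carlo (B = %g)", B))
  }
}

fmt_summary <- function(x, normal) {
  if (normal) {
    sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
}

#' Four-group cohort summary with omnibus and post hoc testing
#'
#' Builds the demographic and gait-parameter comparison table: per
#' variable, a per-group normality screen decides the presentation
#' (mean +/- SD when every group passes, otherwise median (Q1-Q3)); the
#' Kruskal-Wallis omnibus p-value is computed and, when significant at
#' `family_alpha`, the six Bonferroni-corrected pairwise flags a-f are
#' attached. Sex is compared with Fisher's exact test on the 2 x 4 table.
#'
#' @param table A `feature_table` (gait parameters).
#' @param demographics Cohort demographics ([cohort_demographics()]); set
#'   NULL to summarize gait parameters only.
#' @param family_alpha Family-wise level for the post hoc flags.
#' @param seed Seed for Monte-Carlo components.
#' @param n_mc Normality-calibration replicates.
#' @return Data frame of class `group_comparison`: parameter, presentation,
#'   per-group summaries, statistic, p_value, significant_pairs.
#' @export
summarize_cohort <- function(table, demographics = NULL, family_alpha = 0.05,
                             seed = 1L, n_mc = 10000L) {
  df <- as.data.frame(table)
  if (length(unique(df$group)) != 4) {
    stop("data error: all 4 severity groups are required")
  }
  vars <- list()
  if (!is.null(demographics)) {
    dd <- as.data.frame(demographics)
    vars <- c(vars, list(
      list(name = "age_years", data = split(dd$age, dd$group)),
      list(name = "height_cm", data = split(dd$height_cm, dd$group)),
      list(name = "weight_kg", data = split(dd$weight_kg, dd$group)),
      list(name = "bmi_kg_m2", data = split(dd$bmi, dd$group))
    ))
  }
  for (f in intersect(GAIT_FEATURES, names(df))) {
    vars <- c(vars, list(list(name = f, data = split(df[[f]], df$group))))
  }

  rows <- lapply(vars, function(v) {
    groups <- v$data[GAIT_GROUPS]
    # groups below the normality screen's minimum n default to the robust
    # median (Q1-Q3) presentation
    normal <- all(vapply(groups, function(g) {
      if (length(g) < 8) return(FALSE)
      ks_normality(g, n_mc = n_mc, seed = seed)$pass
    }, logical(1)))
    kw <- kruskal_wallis(groups)
    flags <- ""
    if (is.finite(kw$p_value) && kw$p_value < family_alpha) {
      ph <- pairwise_posthoc(groups, family_alpha)
      flags <- paste(ph$significant_pairs, collapse = ",")
    }
    all_values <- unlist(groups, use.names = FALSE)
    out <- data.frame(
      parameter = v$name,
      presentation = if (normal) "mean_sd" else "median_iqr",
      total = fmt_summary(all_values, normal),
      stringsAsFactors = FALSE
    )
    for (g in GAIT_GROUPS) out[[g]] <- fmt_summary(groups[[g]], normal)
    out$statistic <- kw$statistic
    out$p_value <- kw$p_value
    out$significant_pairs <- flags
    out
  })
  out <- do.call(rbind, rows)

  if (!is.null(demographics)) {
    dd <- as.data.frame(demographics)
    sex_tab <- table(dd$sex, dd$group)
    fx <- fisher_exact(unclass(sex_tab), seed = seed)
    sex_row <- data.frame(
      parameter = "sex_male", presentation = "count_pct",
      total = sprintf("%d (%.1f%%)", sum(dd$sex == "male"),
                      100 * mean(dd$sex == "male")),
      stringsAsFactors = FALSE
    )
    for (g in GAIT_GROUPS) {
      idx <- dd$group == g
      sex_row[[g]] <- sprintf("%d (%.1f%%)", sum(dd$sex[idx] == "male"),
                              100 * mean(dd$sex[idx] == "male"))
    }
    sex_row$statistic <- NA_real_
    sex_row$p_value <- fx$p_value
    sex_row$significant_pairs <- ""
    out <- rbind(out[seq_len(min(4, nrow(out))), ], sex_row,
                 out[-seq_len(min(4, nrow(out))), ])
  }
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- round(family_alpha / 6, 4)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Format a group-comparison table as text
#'
#' @param comparison A `group_comparison` from [summarize_cohort()].
#' @return Character vector of report lines (invisibly printed).
#' @export
format_group_table <- function(comparison) {
  thr <- attr(comparison, "bonferroni_threshold") %||% 0.0083
  lines <- c(
    sprintf("%-30s %-20s %-20s %-20s %-20s %-9s %s",
            "parameter", GAIT_GROUPS[1], GAIT_GROUPS[2], GAIT_GROUPS[3],
            GAIT_GROUPS[4], "p", "pairs"),
    vapply(seq_len(nrow(comparison)), function(i) {
      r <- comparison[i, ]
      sprintf("%-30s %-20s %-20s %-20s %-20s %-9.4g %s",
              r$parameter, r$healthy_control, r$mci, r$mild_dementia,
              r$moderate_dementia, r$p_value,
              ifelse(nzchar(r$significant_pairs), r$significant_pairs, "-"))
    }, character(1)),
    sprintf("pair flags significant at Bonferroni-corrected p < %.4f", thr),
    "a: HC vs MCI; b: HC vs mild; c: HC vs moderate; d: MCI vs mild; e: MCI vs moderate; f: mild vs moderate"
  )
  lines
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(format_group_table(x), sep = "\n")
  invisible(x)
}
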