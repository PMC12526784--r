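# Severity classification (cross-validated SVM) and logistic-regression
# analysis with odds ratios and max-rescaled R-squared.

# Stratified fold assignment; errors if any class cannot reach every fold.
stratified_folds <- function(y, folds, seed) {
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts < folds)) {
    stop("stratification error: class counts (",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         ") too small for ", folds, " folds")
  }
  fold <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

# Rank-based (Mann-Whitney) AUC of score against binary truth.
rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metric panel from a multiclass confusion matrix
#'
#' One-vs-rest TP/FP/FN/TN per class, macro-averaged. Accuracy is
#' 100 x trace / total; the F1 score is the harmonic mean of the macro
#' precision and macro sensitivity. A class with a zero denominator for
#' some metric contributes 0 to the macro mean, with a warning.
#'
#' @param confusion Square count matrix, rows = actual, columns = predicted.
#' @return Named list (all in %): `accuracy`, `precision_ppv`,
#'   `recall_sensitivity`, `specificity`, `f1`, `npv`, plus the `per_class`
#'   data frame.
#' @export
#' @examples
#' cm <- matrix(c(50, 4, 0, 0, 5, 27, 2, 0, 0, 3, 20, 2, 0, 0, 4, 22),
#'              nrow = 4, byrow = TRUE)
#' multiclass_metrics(cm)$accuracy
multiclass_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0) || sum(confusion) == 0) {
    stop("confusion matrix must hold non-negative counts with positive total")
  }
  total <- sum(confusion)
  kc <- nrow(confusion)
  per <- data.frame(class = rownames(confusion) %||% as.character(seq_len(kc)),
                    ppv = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_, npv = NA_real_)
  zero_warned <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      if (!zero_warned) {
        warning("zero denominator in a per-class metric; contributing 0")
        zero_warned <<- TRUE
      }
      return(0)
    }
    num / den
  }
  for (i in seq_len(kc)) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, -i])
    fp <- sum(confusion[-i, i])
    tn <- total - tp - fn - fp
    per$ppv[i] <- safe_div(tp, tp + fp)
    per$sensitivity[i] <- safe_div(tp, tp + fn)
    per$specificity[i] <- safe_div(tn, tn + fp)
    per$npv[i] <- safe_div(tn, tn + fn)
  }
  ppv <- mean(per$ppv) * 100
  sens <- mean(per$sensitivity) * 100
  list(
    accuracy = 100 * sum(diag(confusion)) / total,
    precision_ppv = ppv,
    recall_sensitivity = sens,
    specificity = mean(per$specificity) * 100,
    f1 = if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0,
    npv = mean(per$npv) * 100,
    per_class = per
  )
}

#' Cross-validated SVM severity classification
#'
#' Stratified k-fold cross-validation of a soft-margin SVM (radial basis
#' function kernel by default, one-vs-one multiclass, box constraint 1).
#' Features are standardized inside each training fold and the fold
#' statistics applied to the held-out fold; the kernel scale uses the
#' median heuristic (gamma = 1 / (2 median^2) of pairwise training
#' distances) unless a numeric `gamma` is given. Out-of-fold predictions
#' are pooled into one confusion matrix; the AUC is the macro one-vs-rest
#' area computed from the SVM's class probability scores.
#'
#' @param table A `feature_table`.
#' @param selected_features Feature subset to use (default all 11 present).
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and the probability model.
#' @param kernel SVM kernel, "radial" (default), "linear", "polynomial" or
#'   "sigmoid".
#' @param cost Box constraint (default 1).
#' @param gamma "median" (default, the median heuristic) or a numeric value.
#' @return List of class `cv_report`: `confusion` (rows actual, class order
#'   healthy/MCI/mild/moderate), the [multiclass_metrics()] panel, `auc`,
#'   `fold_count`, `seed`, `kernel_spec`.
#' @export
train_eval_svm <- function(table, selected_features = NULL, folds = 5L,
                           seed = 1L, kernel = "radial", cost = 1,
                           gamma = "median") {
  df <- as.data.frame(table)
  feats <- selected_features %||% intersect(GAIT_FEATURES, names(df))
  y <- droplevels(factor(df$group, levels = levels(factor(df$group))))
  if (nlevels(y) < 2) stop("data error: need at least 2 classes")
  x <- as.matrix(df[, feats, drop = FALSE])
  if (any(!is.finite(x))) {
    bad <- df$subject_id[!stats::complete.cases(x)]
    stop("data error: non-finite features for subject(s) ",
         paste(bad, collapse = ", "))
  }
  if (folds < 2) stop("parameter error: folds must be >= 2")

  fold <- stratified_folds(y, folds, seed)
  classes <- levels(y)
  pred <- factor(rep(NA_character_, nrow(x)), levels = classes)
  prob <- matrix(NA_real_, nrow(x), length(classes),
                 dimnames = list(NULL, classes))
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    g <- gamma
    if (identical(gamma, "median")) {
      med <- stats::median(stats::dist(xtr))
      g <- if (is.finite(med) && med > 0) 1 / (2 * med^2) else 1 / ncol(xtr)
    }
    fit <- with_seed(derive_seed(seed, "svm", f), {
      e1071::svm(xtr, y[tr], kernel = kernel, cost = cost, gamma = g,
                 probability = TRUE, scale = FALSE)
    })
    p <- stats::predict(fit, xte, probability = TRUE)
    pred[!tr] <- p
    pr <- attr(p, "probabilities")
    prob[!tr, colnames(pr)] <- pr
  }

  confusion <- table(actual = y, predicted = pred)
  confusion <- unclass(confusion)[classes, classes]
  metrics <- multiclass_metrics(confusion)
  aucs <- vapply(classes, function(cl) rank_auc(prob[, cl], y == cl), numeric(1))
  out <- c(list(confusion = confusion), metrics[setdiff(names(metrics), "per_class")],
           list(per_class = metrics$per_class,
                auc = mean(aucs, na.rm = TRUE), auc_per_class = aucs,
                fold_count = folds, seed = seed,
                kernel_spec = list(kernel = kernel, cost = cost, gamma = gamma)))
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("SVM cross-validation (%d-fold, %s kernel)\n",
              x$fold_count, x$kernel_spec$kernel))
  print(x$confusion)
  cat(sprintf("accuracy %.2f%% | PPV %.2f%% | sensitivity %.2f%% | specificity %.2f%%\n",
              x$accuracy, x$precision_ppv, x$recall_sensitivity, x$specificity))
  cat(sprintf("F1 %.2f%% | NPV %.2f%% | AUC %.3f\n", x$f1, x$npv, x$auc))
  invisible(x)
}

# Binary outcome used in the logistic analyses: dementia (CDR >= 1, i.e.
# mild + moderate) vs healthy control; MCI excluded unless requested.
logistic_outcome <- function(df, include_mci = FALSE) {
  pos <- c("mild_dementia", "moderate_dementia")
  if (include_mci) pos <- c("mci", pos)
  keep <- df$group %in% c("healthy_control", pos)
  list(df = df[keep, , drop = FALSE],
       y = as.integer(df$group[keep] %in% pos))
}

#' Logistic regression with odds ratios and max-rescaled R-squared
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of dementia
#' (CDR >= 1) versus healthy control on the given predictors. Reports Wald
#' 95% confidence intervals (exp(b +/- 1.96 SE)), Cox-Snell
#' R^2 = 1 - exp((2/n)(LL0 - LL1)) and its max-rescaled (Nagelkerke) form
#' R^2 / (1 - exp(2 LL0 / n)), and the in-sample classification accuracy at
#' probability threshold 0.5. Perfect separation is flagged rather than
#' silently reported.
#'
#' @param table A `feature_table`.
#' @param predictors Feature names to include jointly (multivariable) —
#'   fit one at a time for univariable results.
#' @param include_mci Count MCI in the dementia group (default FALSE).
#' @return List of class `logistic_fit`: `coefficients` data frame
#'   (estimate, SE, OR, CI bounds, p), `r_square` (Cox-Snell),
#'   `max_rescaled_r_square`, `classification_accuracy` (%), `n`,
#'   `separation` flag.
#' @export
fit_logistic <- function(table, predictors, include_mci = FALSE) {
  df <- as.data.frame(table)
  oc <- logistic_outcome(df, include_mci)
  n <- nrow(oc$df)
  if (n <= length(predictors) + 1) {
    stop("data error: need more observations than predictors")
  }
  x <- oc$df[, predictors, drop = FALSE]
  qrx <- qr(cbind(1, as.matrix(x)))
  if (qrx$rank < ncol(x) + 1) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    drop_idx <- setdiff(seq_len(ncol(x) + 1), keep) - 1L
    stop("data error: singular design; collinear predictor(s): ",
         paste(predictors[drop_idx], collapse = ", "))
  }
  dat <- cbind(data.frame(.y = oc$y), x)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  separation <- sep_warn && any(abs(stats::coef(fit)[-1]) > 10)
  if (separation) {
    warning("possible complete separation: coefficient estimates diverged")
  }
  est <- sm[-1, "Estimate"]
  se <- sm[-1, "Std. Error"]
  coefs <- data.frame(
    predictor = predictors,
    estimate = est, se = se,
    odds_ratio = exp(est),
    ci_lower = exp(est - 1.96 * se),
    ci_upper = exp(est + 1.96 * se),
    p_value = sm[-1, "Pr(>|z|)"],
    row.names = NULL
  )
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(.y ~ 1, data = dat,
                                             family = stats::binomial())))
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll1))
  max_rescaled <- if (ll0 == 0) 0 else cox_snell / (1 - exp(2 * ll0 / n))
  acc <- 100 * mean((stats::fitted(fit) >= 0.5) == (oc$y == 1))
  structure(list(coefficients = coefs, r_square = cox_snell,
                 max_rescaled_r_square = max_rescaled,
                 classification_accuracy = acc, n = n,
                 intercept = sm[1, "Estimate"], separation = separation,
                 include_mci = include_mci, model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression, dementia vs healthy (n = %d)\n", x$n))
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-20s OR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                cf$predictor[i], cf$odds_ratio[i], cf$ci_lower[i],
                cf$ci_upper[i], cf$p_value[i]))
  }
  cat(sprintf("  R2 %.4f | max-rescaled R2 %.4f | accuracy %.1f%%\n",
              x$r_square, x$max_rescaled_r_square, x$classification_accuracy))
  if (x$separation) cat("  WARNING: possible complete separation\n")
  invisible(x)
}

#' Univariable and multivariable logistic table
#'
#' Convenience analogue of the classical reporting layout: one univariable
#' fit per predictor plus the joint multivariable fit, with the
#' multivariable model's R-squared measures and accuracy.
#'
#' @inheritParams fit_logistic
#' @return List: `univariable` (data frame), `multivariable`
#'   (`logistic_fit`).
#' @export
logistic_table <- function(table, predictors, include_mci = FALSE) {
  uni <- do.call(rbind, lapply(predictors, function(p) {
    fit_logistic(table, p, include_mci)$coefficients
  }))
  multi <- fit_logistic(table, predictors, include_mci)
  list(univariable = uni, multivariable = multi)
}

#' Cross-validated accuracy of a logistic model
#'
#' Stratified k-fold cross-validation of the dementia-vs-healthy logistic
#' model: per fold, fit on the training part and classify the held-out part
#' at probability threshold 0.5; pooled accuracy over all held-out
#' predictions.
#'
#' @inheritParams fit_logistic
#' @param folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List: `accuracy` (%), `confusion` (2x2), `fold_count`, `n`.
#' @export
cv_logistic <- function(table, predictors, folds = 5L, seed = 1L,
                        include_mci = FALSE) {
  df <- as.data.frame(table)
  oc <- logistic_outcome(df, include_mci)
  x <- oc$df[, predictors, drop = FALSE]
  y <- oc$y
  fold <- stratified_folds(factor(y), folds, seed)
  pred <- integer(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    dat <- cbind(data.frame(.y = y[tr]), x[tr, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                       family = stats::binomial()))
    p <- stats::predict(fit, newdata = x[!tr, , drop = FALSE],
                        type = "response")
    pred[!tr] <- as.integer(p >= 0.5)
  }
  confusion <- table(actual = y, predicted = factor(pred, levels = 0:1))
  list(accuracy = 100 * mean(pred == y), confusion = unclass(confusion),
       fold_count = folds, n = length(y))
}

#' Export a cross-validation report as JSON
#'
#' @param report A `cv_report`.
#' @param path Output .json path.
#' @return The path, invisibly.
#' @export
write_cv_report <- function(report, path) {
  out <- list(
    confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)),
    class_order = rownames(report$confusion),
    accuracy = report$accuracy, precision_ppv = report$precision_ppv,
    recall_sensitivity = report$recall_sensitivity,
    specificity = report$specificity, f1 = report$f1, npv = report$npv,
    auc = report$auc, fold_count = report$fold_count, seed = report$seed,
    kernel = report$kernel_spec
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
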