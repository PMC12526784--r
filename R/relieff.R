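# Multiclass ReliefF feature weighting (Kononenko's formulation) and
# rank-based selection.

#' ReliefF feature weights
#'
#' Instance-based relevance scoring: for each sampled instance, find its k
#' nearest same-class neighbours (hits) and, for every other class, its k
#' nearest neighbours from that class (misses); features whose values
#' separate misses but not hits gain weight:
#' \deqn{W_f \leftarrow W_f - \frac{diff(f, x, hit)}{mk}
#'   + \sum_{C \ne class(x)} \frac{P(C)}{1 - P(class(x))}
#'     \frac{diff(f, x, miss_C)}{mk}}
#' with `diff` the absolute difference after range normalization to
#' \[0, 1\] and distances Manhattan on the range-normalized features. With
#' range-normalized diffs the weights lie in \[-1, 1\]. Two-class ReliefF
#' with k = 1 and all instances sampled reduces to classic Relief.
#'
#' A feature constant across all instances has zero range; its diff is
#' defined as 0 (with a warning) and its weight is exactly 0. If a class
#' holds fewer than k + 1 members, k is reduced for that class with a
#' warning.
#'
#' @param table A `feature_table` (or data frame with a `group` column and
#'   numeric feature columns).
#' @param k Neighbours per class (default 10).
#' @param n_sampled Number of instances to sample (default all).
#' @param seed Seed for the instance sample (unused when all instances are
#'   used).
#' @param features Feature columns to score (default the canonical 11 that
#'   are present).
#' @return List of class `relieff_weights`: `weights` (named), `ranks`
#'   (feature names in descending weight, ties broken lexicographically),
#'   `k`, `n_sampled`, `seed`.
#' @export
#' @examples
#' df <- data.frame(group = rep(c("a", "b"), each = 2),
#'                  f = c(0, 0.1, 0.9, 1.0))
#' relieff_weights(df, k = 1, features = "f")$weights
relieff_weights <- function(table, k = 10L, n_sampled = NULL, seed = 1L,
                            features = NULL) {
  df <- as.data.frame(table)
  if (is.null(features)) {
    features <- intersect(GAIT_FEATURES, names(df))
    if (length(features) == 0) {
      features <- names(df)[vapply(df, is.numeric, logical(1)) &
                              !names(df) %in% c("cdr")]
    }
  }
  y <- droplevels(as.factor(df$group))
  x <- as.matrix(df[, features, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("data error: non-finite feature values")
  n <- nrow(x)
  classes <- levels(y)
  if (length(classes) < 2) stop("data error: ReliefF needs at least 2 classes")

  rng <- apply(x, 2, function(col) diff(range(col)))
  zero_rng <- rng <= 0
  if (any(zero_rng)) {
    warning("constant feature(s) with zero range: ",
            paste(features[zero_rng], collapse = ", "), "; diff set to 0")
    rng[zero_rng] <- 1  # diffs on these columns are identically 0 anyway
  }
  xn <- sweep(x, 2, apply(x, 2, min), "-")
  xn <- sweep(xn, 2, rng, "/")
  xn[, zero_rng] <- 0

  # Manhattan distances on range-normalized features
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  priors <- table(y) / n

  if (is.null(n_sampled) || n_sampled >= n) {
    sampled <- seq_len(n)
  } else {
    sampled <- with_seed(derive_seed(seed, "relieff"),
                         sort(sample.int(n, n_sampled)))
  }
  m <- length(sampled)

  k_eff <- stats::setNames(integer(length(classes)), classes)
  for (cl in classes) {
    size <- sum(y == cl)
    k_eff[cl] <- min(k, size - 1L)
    if (k_eff[cl] < k) {
      warning("class '", cl, "' has ", size,
              " members; k reduced to ", k_eff[cl], " for that class")
    }
  }
  if (any(k_eff < 1)) stop("data error: every class needs at least 2 members")

  w <- stats::setNames(numeric(length(features)), features)
  for (i in sampled) {
    cl <- as.character(y[i])
    # hits: k nearest same-class neighbours (stable order on ties)
    same <- which(y == cl & seq_len(n) != i)
    hits <- same[order(d[i, same])][seq_len(k_eff[cl])]
    hit_diff <- colMeans(abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ], "-")))
    w <- w - hit_diff / m
    for (co in setdiff(classes, cl)) {
      others <- which(y == co)
      kk <- min(k_eff[cl], length(others))
      miss <- others[order(d[i, others])][seq_len(kk)]
      miss_diff <- colMeans(abs(sweep(xn[miss, , drop = FALSE], 2, xn[i, ], "-")))
      w <- w + as.numeric(priors[co] / (1 - priors[cl])) * miss_diff / m
    }
  }
  w[zero_rng] <- 0

  ord <- order(-w, features)
  structure(list(weights = w, ranks = features[ord], k = k,
                 n_sampled = m, seed = seed),
            class = "relieff_weights")
}

#' Select the top-ranked features
#'
#' @param weights A `relieff_weights` object.
#' @param n_keep Number of features to keep (1..n_features).
#' @return Character vector: the top `n_keep` features in descending weight
#'   order (ties broken lexicographically by name).
#' @export
rank_and_select <- function(weights, n_keep) {
  stopifnot(inherits(weights, "relieff_weights"))
  nf <- length(weights$weights)
  if (n_keep < 1 || n_keep > nf) {
    stop("parameter error: n_keep must be in 1..", nf)
  }
  weights$ranks[seq_len(n_keep)]
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat(sprintf("ReliefF weights (k = %d, %d instances)\n", x$k, x$n_sampled))
  w <- sort(x$weights, decreasing = TRUE)
  for (i in seq_along(w)) {
    cat(sprintf("  %2d. %-28s %8.4f\n", i, names(w)[i], w[i]))
  }
  invisible(x)
}

#' Export ReliefF weights as CSV / JSON
#'
#' @param weights A `relieff_weights`.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return The path, invisibly.
#' @export
write_relieff <- function(weights, path) {
  df <- data.frame(feature = names(weights$weights),
                   weight = as.numeric(weights$weights))
  df <- df[order(-df$weight, df$feature), ]
  df$rank <- seq_len(nrow(df))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
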