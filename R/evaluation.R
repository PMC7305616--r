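# Predictive power of selected feature subsets.
#
# The end test of an attribution method: retrain a predictor on increasing
# prefixes of the reported (significant) features and compare the held-out
# metric with models trained on random subsets of the same size. A good
# method's curve rises fast and saturates early.

# logistic classifier + held-out metric; base glm is adequate for the small
# reference tasks (separable fits only affect coefficients, not ranking)
fit_and_score <- function(Xtr, ytr, Xte, yte, metric = c("auc", "accuracy")) {
  metric <- match.arg(metric)
  df_tr <- data.frame(y = ytr, Xtr)
  df_te <- data.frame(Xte)
  names(df_tr) <- c("y", paste0("V", seq_len(ncol(Xtr))))
  names(df_te) <- paste0("V", seq_len(ncol(Xte)))
  fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
  sc <- suppressWarnings(stats::predict(fit, newdata = df_te, type = "link"))
  if (metric == "accuracy") return(mean((sc > 0) == (yte == 1)))
  rank_auc(sc, yte)
}

# rank-based AUC (Mann-Whitney); ties handled by midranks
rank_auc <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("degenerate single-class split")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Held-out binary classification with a feature subset
#'
#' Trains a logistic classifier distinguishing two classes using only the
#' given features and reports held-out accuracy and AUC-ROC.
#'
#' @param features n x p matrix with column names.
#' @param labels class label per row.
#' @param class_a,class_b the two classes.
#' @param features_subset character vector of feature names (non-empty).
#' @param split fraction of rows used for training (default 0.8).
#' @param seed integer seed for the split.
#' @return list with `accuracy` and `auc`.
#' @export
holdout_binary_task <- function(features, labels, class_a, class_b,
                                features_subset, split = 0.8, seed = 1) {
  if (length(features_subset) == 0) stop("empty feature subset")
  X <- as.matrix(features)
  keep <- labels %in% c(class_a, class_b)
  X <- X[keep, features_subset, drop = FALSE]
  y <- as.numeric(labels[keep] == class_b)
  set.seed(seed)
  idx <- sample.int(nrow(X), floor(split * nrow(X)))
  if (length(unique(y[idx])) < 2 || length(unique(y[-idx])) < 2)
    stop("degenerate single-class split")
  list(accuracy = fit_and_score(X[idx, , drop = FALSE], y[idx],
                                X[-idx, , drop = FALSE], y[-idx], "accuracy"),
       auc = fit_and_score(X[idx, , drop = FALSE], y[idx],
                           X[-idx, , drop = FALSE], y[-idx], "auc"))
}

#' Feature-subset predictive-power curve
#'
#' For each subset size s, trains a fresh classifier on the top-s ranked
#' features and on `repeats` random subsets of size s, evaluating each on a
#' fixed held-out split. Meta-feature names are expanded to their member
#' features before training when a map is supplied.
#'
#' @param features n x p matrix with column names.
#' @param labels class label per row (binary task between `class_a` and
#'   `class_b`).
#' @param class_a,class_b classes to distinguish.
#' @param ranked_features character vector, best first (feature or
#'   meta-feature names).
#' @param sizes strictly increasing subset sizes.
#' @param metric `"auc"` or `"accuracy"`.
#' @param repeats random-arm repetitions per size (default 20).
#' @param split train fraction (default 0.8).
#' @param seed integer seed (split and random draws).
#' @param map optional `meta_feature_map` for expanding meta-features.
#' @return object of class `subset_curve`: data.frame with `size`,
#'   `metric_significant`, `metric_random` (mean over repeats).
#' @export
feature_subset_curve <- function(features, labels, class_a, class_b,
                                 ranked_features, sizes,
                                 metric = c("auc", "accuracy"), repeats = 20,
                                 split = 0.8, seed = 1, map = NULL) {
  metric <- match.arg(metric)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  expand <- function(nm) {
    if (is.null(map)) return(nm)
    unlist(map$groups[nm], use.names = FALSE)
  }
  universe <- if (is.null(map)) colnames(X) else names(map$groups)
  if (any(sizes > length(universe)))
    stop("subset size exceeds the number of available features")
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be strictly increasing")
  keep <- labels %in% c(class_a, class_b)
  Xk <- X[keep, , drop = FALSE]
  y <- as.numeric(labels[keep] == class_b)
  set.seed(seed)
  idx <- sample.int(nrow(Xk), floor(split * nrow(Xk)))
  score <- function(feats) {
    feats <- intersect(feats, colnames(Xk))
    fit_and_score(Xk[idx, feats, drop = FALSE], y[idx],
                  Xk[-idx, feats, drop = FALSE], y[-idx], metric)
  }
  sig <- numeric(length(sizes))
  rnd <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    sig[i] <- score(expand(ranked_features[seq_len(s)]))
    reps <- vapply(seq_len(repeats), function(r) {
      set.seed(seed * 1000 + i * 100 + r)
      score(expand(sample(universe, s)))
    }, numeric(1))
    rnd[i] <- mean(reps)
  }
  out <- data.frame(size = sizes, metric_significant = sig,
                    metric_random = rnd)
  attr(out, "metric") <- metric
  attr(out, "repeats") <- repeats
  class(out) <- c("subset_curve", "data.frame")
  out
}

#' @export
print.subset_curve <- function(x, ...) {
  cat("Feature-subset curve (", attr(x, "metric"), ", ", attr(x, "repeats"),
      " random repeats per size):\n", sep = "")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.subset_curve <- function(x, ...) {
  graphics::matplot(x$size, cbind(x$metric_significant, x$metric_random),
                    type = "b", pch = c(19, 1), lty = 1,
                    col = c("firebrick", "grey50"),
                    xlab = "number of (meta-)features",
                    ylab = attr(x, "metric"), ...)
  graphics::legend("bottomright", c("significant", "random"),
                   col = c("firebrick", "grey50"), pch = c(19, 1), lty = 1)
  invisible(x)
}
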