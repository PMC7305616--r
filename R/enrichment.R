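# Hypergeometric enrichment against a known feature set.

#' Upper-tail hypergeometric probability
#'
#' P\[X >= overlap\] where X counts known-set members in a uniform draw of
#' `selected` items from a universe containing `known` members.
#'
#' @param overlap observed overlap (<= min(selected, known)).
#' @param selected number of reported features.
#' @param known size of the known set.
#' @param universe total number of features.
#' @export
hypergeom_p <- function(overlap, selected, known, universe) {
  if (overlap > min(selected, known) || selected > universe ||
      known > universe || overlap < 0)
    stop("inconsistent counts for the hypergeometric test")
  stats::phyper(overlap - 1, known, universe - known, selected,
                lower.tail = FALSE)
}

# two-sided hypergeometric p for a presence/absence 2x2 split:
# 2 * min(enrichment tail, depletion tail), capped at 1
hyper_two_sided <- function(x, n_pos, K, N) {
  up <- stats::phyper(x - 1, K, N - K, n_pos, lower.tail = FALSE)
  lo <- stats::phyper(x, K, N - K, n_pos, lower.tail = TRUE)
  min(1, 2 * min(up, lo))
}

#' Construct the known (gold-standard) feature set
#'
#' For every feature, presence (value > 0) is compared between a positive and
#' a negative class with a two-sided hypergeometric test for enrichment or
#' depletion. Features passing a highly conservative threshold
#' (-log10 p > `threshold`, default 20) form the known set. When a
#' meta-feature map is given, each meta-feature inherits the minimum p-value
#' of its members and membership is decided at the meta level.
#'
#' @param features n x p matrix (binary or binarisable; non-binary columns
#'   are binarised at > 0 with a warning).
#' @param labels class label per row.
#' @param positive_class,negative_class the two classes to contrast.
#' @param threshold -log10(p) cutoff; default 20.
#' @param map optional `meta_feature_map`.
#' @param log_base base for the threshold transform (default 10).
#' @return object of class `known_feature_set`: `members`, `table`
#'   (feature/meta-feature, p, minus_log_p), `threshold`.
#' @export
known_feature_set <- function(features, labels, positive_class,
                              negative_class, threshold = 20, map = NULL,
                              log_base = 10) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  pos <- labels == positive_class
  neg <- labels == negative_class
  if (!any(pos) || !any(neg)) stop("both classes must be non-empty")
  keep <- pos | neg
  X <- X[keep, , drop = FALSE]
  pos <- pos[keep]
  if (any(X != 0 & X != 1)) {
    warning("non-binary feature values binarised at > 0")
    X <- (X > 0) * 1
  }
  N <- nrow(X)
  n_pos <- sum(pos)
  pv <- vapply(seq_len(ncol(X)), function(j) {
    K <- sum(X[, j])
    x <- sum(X[pos, j])
    hyper_two_sided(x, n_pos, K, N)
  }, numeric(1))
  names(pv) <- colnames(X)
  if (!is.null(map)) {
    pv <- vapply(map$groups, function(g) min(pv[g]), numeric(1))
  }
  mlp <- -log(pv, base = log_base)
  tab <- data.frame(feature = names(pv), p = unname(pv),
                    minus_log_p = unname(mlp))
  structure(list(members = names(pv)[mlp > threshold], table = tab,
                 threshold = threshold, log_base = log_base),
            class = "known_feature_set")
}

#' @export
print.known_feature_set <- function(x, ...) {
  cat("Known feature set: ", length(x$members), " of ", nrow(x$table),
      " features at -log", x$log_base, "(p) > ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Ranked enrichment curve
#'
#' Walks down a ranked feature list and, at every prefix size s, computes the
#' upper-tail hypergeometric p-value of the overlap between the top-s
#' features and the known set, reported as -log10(p). The prefix of size 0
#' is defined to have p = 1.
#'
#' @param ranked character vector of feature names ordered by relative
#'   attribution (no duplicates).
#' @param known a `known_feature_set` or character vector of member names.
#' @param universe total number of features in the universe.
#' @return data.frame: `subset_size`, `overlap`, `minus_log10_p`.
#' @export
enrichment_curve <- function(ranked, known, universe) {
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates")
  if (length(ranked) > universe)
    stop("ranked items exceed the stated universe")
  members <- if (inherits(known, "known_feature_set")) known$members else known
  if (length(members) > universe) stop("known set larger than universe")
  ov <- cumsum(ranked %in% members)
  s <- seq_along(ranked)
  p <- vapply(s, function(i) hypergeom_p(ov[i], i, length(members), universe),
              numeric(1))
  data.frame(subset_size = c(0, s), overlap = c(0, ov),
             minus_log10_p = c(0, -log10(p)))
}

#' Relative attribution ranking of meta-features
#'
#' Orders meta-features by mean absolute attribution across the class
#' samples, normalised by the total (a scale-free "relative attribution").
#'
#' @param meta_attrs samples x meta-features matrix.
#' @return data.frame with `meta_feature` and `relative_attr`, ordered
#'   decreasingly.
#' @export
rank_by_attribution <- function(meta_attrs) {
  m <- colMeans(abs(as.matrix(meta_attrs)))
  rel <- m / sum(m)
  ord <- order(rel, decreasing = TRUE)
  data.frame(meta_feature = colnames(meta_attrs)[ord] %||%
               paste0("MF", ord),
             relative_attr = rel[ord], row.names = NULL)
}
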