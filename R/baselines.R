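# Baseline (reference point) construction.
#
# Attributions explain F(x) - F(x') for a baseline x'. Group-agnostic
# baselines (zero, encoded-zero) need no class information; group-specific
# baselines (random, kmeans, median, close) are picked from a designated
# baseline class in the original feature space.

new_baseline_set <- function(points, strategy, params = list(),
                             per_sample = FALSE) {
  points <- as_row_matrix(points, ncol(as.matrix(points)))
  stopifnot(nrow(points) >= 1)
  structure(list(points = points, strategy = strategy, params = params,
                 per_sample = per_sample), class = "baseline_set")
}

#' @export
print.baseline_set <- function(x, ...) {
  cat("Baseline set: ", nrow(x$points), " point(s), strategy '",
      x$strategy, "'", if (x$per_sample) " (per-sample)", "\n", sep = "")
  invisible(x)
}

#' All-zero baseline
#'
#' The classic no-signal reference of integrated gradients.
#' @param p feature-space dimensionality.
#' @return a `baseline_set` with one all-zero point.
#' @export
zero_baseline <- function(p) {
  if (p < 1) stop("p must be >= 1")
  new_baseline_set(matrix(0, 1, p), "zero")
}

#' Encoded-zero baseline
#'
#' Decodes the all-zero latent vector. For an autoencoder trained on centred
#' data this point sits near the mean of the training data, making it a
#' group-agnostic reference that captures deviation-from-average rather than
#' deviation-from-nothing.
#' @param codec a trained `eig_codec`.
#' @export
encoded_zero_baseline <- function(codec) {
  pt <- decode(codec, matrix(0, 1, codec$q))
  new_baseline_set(pt, "encoded_zero", params = list(q = codec$q))
}

#' Random baseline points from the baseline class
#'
#' @param class_points n x p matrix of baseline-class points.
#' @param m number of points to draw (without replacement).
#' @param seed integer seed.
#' @export
random_baseline <- function(class_points, m = 3, seed = 1) {
  X <- as.matrix(class_points)
  if (m < 1 || m > nrow(X)) stop("m must satisfy 1 <= m <= nrow(class_points)")
  set.seed(seed)
  idx <- sample.int(nrow(X), m)
  new_baseline_set(X[idx, , drop = FALSE], "random",
                   params = list(m = m, seed = seed, idx = idx))
}

#' k-means centroid baseline
#'
#' Cluster centroids summarise subgroups within the baseline class. Three to
#' five clusters are typically sufficient; default k = 3.
#' @param class_points n x p matrix.
#' @param k number of clusters (1 <= k <= n).
#' @param seed integer seed.
#' @export
kmeans_baseline <- function(class_points, k = 3, seed = 1) {
  X <- as.matrix(class_points)
  if (k < 1 || k > nrow(X)) stop("k must satisfy 1 <= k <= nrow(class_points)")
  if (k == nrow(X))  # every point its own centroid
    return(new_baseline_set(X, "kmeans", params = list(k = k, seed = seed)))
  run <- function(s) {
    set.seed(s)
    stats::kmeans(X, centers = k, nstart = 5, iter.max = 50)
  }
  km <- tryCatch(run(seed), error = function(e) {
    tryCatch(run(seed + 1),
             error = function(e2) stop("k-means failed twice (empty cluster): ",
                                       conditionMessage(e2)))
  })
  new_baseline_set(km$centers, "kmeans", params = list(k = k, seed = seed))
}

#' Median-proximal baseline
#'
#' Computes the coordinate-wise median of the baseline class and returns the
#' `m` class points closest to it (Euclidean distance, ties broken by input
#' order). Using actual class points near the median guards the reference
#' against outliers.
#' @param class_points n x p matrix.
#' @param m number of points (default 3).
#' @export
median_baseline <- function(class_points, m = 3) {
  X <- as.matrix(class_points)
  if (m < 1 || m > nrow(X)) stop("m must satisfy 1 <= m <= nrow(class_points)")
  med <- apply(X, 2, stats::median)
  d <- sqrt(colSums((t(X) - med)^2))
  idx <- order(d)[seq_len(m)]
  new_baseline_set(X[idx, , drop = FALSE], "median",
                   params = list(m = m, idx = idx))
}

#' Close baseline (per-sample)
#'
#' Ranks baseline-class points by distance to the sample, discards the single
#' closest (an outlier guard) and returns the next `m`. Being near the sample,
#' these references emphasise a minimal set of distinguishing features.
#' @param class_points n x p matrix (needs `n >= m + 1`).
#' @param sample the p-vector being explained.
#' @param m number of points (default 3).
#' @export
close_baseline <- function(class_points, sample, m = 3) {
  X <- as.matrix(class_points)
  if (nrow(X) <= m) stop("need more than m baseline-class points (m + 1)")
  d <- sqrt(colSums((t(X) - as.numeric(sample))^2))
  idx <- order(d)[1 + seq_len(m)]  # drop rank 1
  new_baseline_set(X[idx, , drop = FALSE], "close",
                   params = list(m = m, idx = idx), per_sample = TRUE)
}

#' Write / read a baseline set as TSV
#'
#' The header comment line records the strategy and its parameters, so
#' provenance round-trips through serialisation.
#' @param bs a `baseline_set`.
#' @param path file path.
#' @export
write_baselines <- function(bs, path) {
  par <- bs$params[setdiff(names(bs$params), "idx")]
  hdr <- paste0("# strategy=", bs$strategy,
                " per_sample=", tolower(bs$per_sample),
                if (length(par))
                  paste0(" ", paste(names(par), unlist(par), sep = "=",
                                    collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(bs$points, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_baselines
#' @export
read_baselines <- function(path) {
  hdr <- readLines(path, n = 1)
  fields <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  kv <- strsplit(fields, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  pts <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(pts) <- NULL
  par <- as.list(vals[setdiff(names(vals), c("strategy", "per_sample"))])
  par <- lapply(par, function(v) {
    n <- suppressWarnings(as.numeric(v)); if (is.na(n)) v else n
  })
  new_baseline_set(pts, vals[["strategy"]], params = par,
                   per_sample = identical(vals[["per_sample"]], "true"))
}
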