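# Meta-features and the class-level significance test.
#
# Highly correlated features (e.g., variants of one RNA-binding-protein
# motif) are grouped into meta-features so attribution is not diluted across
# near-duplicates. Significance for a class of interest is then assessed per
# meta-feature by comparing absolute attributions on the class set against a
# similarly sized random event set with a one-sided Welch t-test, Bonferroni
# corrected.

#' Group correlated features into meta-features
#'
#' Single-linkage grouping of features whose absolute Pearson correlation
#' meets `threshold`: features are merged whenever a chain of pairwise
#' correlations at or above the threshold connects them. Constant columns
#' cannot be correlated and are placed in singleton groups with a warning.
#'
#' @param features n x p numeric matrix with column names (n >= 3).
#' @param threshold absolute-correlation cutoff in (0, 1]; default 0.8.
#' @return object of class `meta_feature_map`: `groups` (named list of
#'   feature-name vectors), `feature_to_group` (named character), `linkage`.
#' @export
build_meta_features <- function(features, threshold = 0.8) {
  X <- as.matrix(features)
  if (nrow(X) < 3) stop("need at least 3 rows to estimate correlations")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const))
    warning(sum(const), " constant feature column(s) placed in singleton groups")
  cc <- suppressWarnings(abs(stats::cor(X)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "single")
  grp <- stats::cutree(hc, h = 1 - threshold)
  # name groups deterministically by first member in input order
  ids <- unique(grp[order(match(names(grp), colnames(X)))])
  groups <- lapply(ids, function(g) colnames(X)[grp == g])
  names(groups) <- paste0("MF", seq_along(groups))
  f2g <- stats::setNames(rep(names(groups), lengths(groups)),
                         unlist(groups))
  structure(list(groups = groups, feature_to_group = f2g,
                 linkage = list(threshold = threshold, method = "single")),
            class = "meta_feature_map")
}

#' @export
print.meta_feature_map <- function(x, ...) {
  cat("Meta-feature map: ", length(x$feature_to_group), " features in ",
      length(x$groups), " groups (|r| >= ", x$linkage$threshold,
      ", ", x$linkage$method, " linkage)\n", sep = "")
  invisible(x)
}

#' Read / write a meta-feature map as 2-column TSV (feature, group)
#' @param map a `meta_feature_map`.
#' @param file path.
#' @export
write_meta_features <- function(map, file) {
  df <- data.frame(feature = names(map$feature_to_group),
                   group = unname(map$feature_to_group))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_meta_features
#' @export
read_meta_features <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  groups <- split(df$feature, df$group)
  groups <- groups[unique(df$group)]
  structure(list(groups = groups,
                 feature_to_group = stats::setNames(df$group, df$feature),
                 linkage = list(threshold = NA, method = "external")),
            class = "meta_feature_map")
}

#' Aggregate feature attributions to meta-features
#'
#' The meta-feature attribution of a sample is the sum of the signed
#' attributions of its member features.
#'
#' @param attrs an `eig_attribution` or a plain samples x features matrix
#'   with column names.
#' @param map a `meta_feature_map` covering every column.
#' @return samples x meta-features matrix.
#' @export
meta_attributions <- function(attrs, map) {
  M <- if (inherits(attrs, "eig_attribution")) attrs$values else as.matrix(attrs)
  if (is.null(colnames(M))) colnames(M) <- paste0("f", seq_len(ncol(M)))
  unmapped <- setdiff(colnames(M), names(map$feature_to_group))
  if (length(unmapped) > 0)
    stop("features not covered by the meta-feature map: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  out <- vapply(map$groups,
                function(g) rowSums(M[, g, drop = FALSE]),
                numeric(nrow(M)))
  if (nrow(M) == 1) out <- matrix(out, 1, dimnames = list(NULL, names(map$groups)))
  out
}

#' Significance test for class-level (meta-)feature attribution
#'
#' For every meta-feature, compares the absolute attributions on the class
#' of interest (`G`) against those on a random event set (`R`) with a
#' one-sided Welch t-test for the positive tail (mean |attr| in G greater),
#' then applies Bonferroni correction over the number of meta-features.
#'
#' With `rank_transform = TRUE` the test is run on the ranks of the pooled
#' values instead of the raw absolute attributions. With
#' `abs_of_sum = FALSE` the input matrices are expected to hold per-feature
#' attributions already aggregated as sums of absolute values.
#'
#' @param G samples x meta-features attribution matrix for the class of
#'   interest (signed; absolute values are taken internally).
#' @param R samples x meta-features matrix for the random set (same columns).
#' @param fwer family-wise error rate for the Bonferroni flag; default 0.05.
#' @param rank_transform test on pooled ranks instead of absolute values.
#' @return data.frame of class `eig_significance`: one row per meta-feature
#'   with `mean_abs_G`, `mean_abs_R`, `t`, `p`, `p_adj`, `significant`.
#' @export
significance_test <- function(G, R, fwer = 0.05, rank_transform = FALSE) {
  G <- as.matrix(G); R <- as.matrix(R)
  if (!(fwer > 0 && fwer <= 1)) stop("fwer must be in (0, 1]")
  if (is.null(colnames(G))) colnames(G) <- paste0("MF", seq_len(ncol(G)))
  if (is.null(colnames(R))) colnames(R) <- colnames(G)
  if (!identical(colnames(G), colnames(R)))
    stop("G and R must share meta-feature columns")
  if (nrow(G) < 2 || nrow(R) < 2) stop("each set needs >= 2 rows")
  m <- ncol(G)
  res <- lapply(seq_len(m), function(j) {
    sg <- abs(G[, j]); sr <- abs(R[, j])
    if (rank_transform) {
      rk <- rank(c(sg, sr))
      sg <- rk[seq_along(sg)]; sr <- rk[-seq_along(sg)]
    }
    if (stats::sd(sg) < 1e-300 && stats::sd(sr) < 1e-300) {
      # no within-group variation: no evidence either way
      return(c(mean(sg), mean(sr), 0, 1))
    }
    tt <- tryCatch(stats::t.test(sg, sr, alternative = "greater",
                                 var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) return(c(mean(sg), mean(sr), 0, 1))
    c(mean(sg), mean(sr), unname(tt$statistic), tt$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(meta_feature = colnames(G),
                    mean_abs_G = res[, 1], mean_abs_R = res[, 2],
                    t = res[, 3], p = res[, 4],
                    p_adj = pmin(1, res[, 4] * m))
  out$significant <- out$p_adj <= fwer
  attr(out, "fwer") <- fwer
  attr(out, "n_tests") <- m
  class(out) <- c("eig_significance", "data.frame")
  out
}

#' @export
print.eig_significance <- function(x, ...) {
  cat("Significance over ", nrow(x), " meta-features (Bonferroni, FWER ",
      attr(x, "fwer"), "): ", sum(x$significant), " significant\n", sep = "")
  if (sum(x$significant) > 0) {
    top <- x[order(x$p_adj), ]
    print.data.frame(utils::head(top[top$significant, ], 10), digits = 3,
                     row.names = FALSE)
  }
  invisible(x)
}

#' Write a significance table as TSV sorted by adjusted p
#' @param tab an `eig_significance`.
#' @param file path.
#' @param extra named provenance values for the header.
#' @export
write_significance <- function(tab, file, extra = list()) {
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# fwer=", attr(tab, "fwer")), con)
  for (k in names(extra)) writeLines(paste0("# ", k, "=", extra[[k]]), con)
  utils::write.table(tab[order(tab$p_adj), ], con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Sample a random event set
#'
#' Draws a uniform sample of rows without replacement across all classes,
#' for use as the reference set of the significance test. By convention the
#' random set is the same size as the class of interest.
#'
#' @param n_total number of available events.
#' @param size sample size (<= n_total).
#' @param seed integer seed.
#' @return integer row indices.
#' @export
sample_random_set <- function(n_total, size, seed = 1) {
  if (size > n_total) stop("size must not exceed the number of events")
  set.seed(seed)
  sample.int(n_total, size)
}
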