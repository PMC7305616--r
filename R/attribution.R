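# Gradient integration along paths.
#
# The attribution of feature j is the line integral of dF/dx_j along the
# path. For a discretised path it is realised as a per-segment trapezoid in
# feature space: the gradient dotted with the coordinate increments,
#   attr_j = sum_i 1/2 (g_j(p_i) + g_j(p_{i+1})) (p_{i+1,j} - p_{i,j}),
# which absorbs the d(gamma_j)/d(alpha) term and is exact for piecewise
# linear paths with constant gradients. Two diagnostics accompany every
# attribution: the completeness gap |sum_j attr_j - (F(x) - F(x'))| and,
# when refinement is requested, the change under step halving.

#' Integrate gradients along a path
#'
#' @param F a prediction function (`eig_predfun` or `eig_model`).
#' @param path an `eig_path` from baseline to sample.
#' @return list of class `eig_attr` with `values` (p-vector),
#'   `completeness_gap`, `refinement_delta` (NA here; see [refine_until()]),
#'   `n_steps`, and the endpoint predictions `f_x`, `f_x_prime`.
#' @export
path_attributions <- function(F, path) {
  P <- path$points
  n <- nrow(P)
  fx <- pf_eval(F, P[c(1, n), , drop = FALSE])
  if (any(!is.finite(fx)))
    stop("non-finite prediction at path endpoint")
  G <- pf_grad_matrix(F, P)
  bad <- which(rowSums(!is.finite(G)) > 0)
  if (length(bad) > 0)
    stop("non-finite gradient at path step ", bad[1])
  dP <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  vals <- colSums(0.5 * (G[-n, , drop = FALSE] + G[-1, , drop = FALSE]) * dP)
  gap <- abs(sum(vals) - (fx[2] - fx[1]))
  structure(list(values = vals, completeness_gap = gap,
                 refinement_delta = NA_real_, n_steps = n,
                 f_x = fx[2], f_x_prime = fx[1]),
            class = "eig_attr")
}

#' @export
print.eig_attr <- function(x, ...) {
  cat("Attribution over ", length(x$values), " features (", x$n_steps,
      " steps): sum = ", signif(sum(x$values), 5),
      ", completeness gap = ", signif(x$completeness_gap, 3), "\n", sep = "")
  invisible(x)
}

#' Refine path resolution until attribution converges
#'
#' Doubles the number of path points, starting at 50, until both the
#' completeness gap is below `tol * max(|F(x) - F(x')|, 1e-8)` and the
#' maximum per-feature change under step halving is below
#' `tol * max_j |attr_j|`. If `max_steps` is exceeded the best attribution
#' is returned with `converged = FALSE` and a warning.
#'
#' @param F a prediction function.
#' @param path_builder function(n) returning an `eig_path` with n points.
#' @param tol relative tolerance (> 0).
#' @param max_steps resolution ceiling.
#' @param n0 starting resolution.
#' @return an `eig_attr` with `refinement_delta` and `converged` filled in.
#' @export
refine_until <- function(F, path_builder, tol = 0.01, max_steps = 10000,
                         n0 = 50) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  n <- n0
  prev <- path_attributions(F, path_builder(n))
  repeat {
    n2 <- 2 * n
    cur <- path_attributions(F, path_builder(n2))
    delta <- max(abs(cur$values - prev$values))
    cur$refinement_delta <- delta
    dF <- abs(cur$f_x - cur$f_x_prime)
    ok_gap <- cur$completeness_gap <= tol * max(dF, 1e-8)
    ok_delta <- delta <= tol * max(max(abs(cur$values)), 1e-300)
    if (ok_gap && ok_delta) {
      cur$converged <- TRUE
      return(cur)
    }
    if (n2 > max_steps) {
      warning("attribution did not converge within max_steps = ", max_steps)
      cur$converged <- FALSE
      return(cur)
    }
    prev <- cur
    n <- n2
  }
}

#' Class-level attributions over samples and baselines
#'
#' The main batch entry point: for every sample an attribution vector is
#' computed against each baseline point and the vectors are averaged
#' element-wise (for the `close` strategy, baselines are re-selected per
#' sample). Returns a per-sample x per-feature matrix with integration
#' diagnostics and full provenance.
#'
#' @param F a prediction function.
#' @param samples n x p matrix of points to explain (rows named or not).
#' @param baselines a `baseline_set`, or (for per-sample strategies) a
#'   function(sample) returning one.
#' @param path_config list: `kind` ("O-L", "H-L", "O-N", "H-N"),
#'   `n_steps` (default 250), and `codec` / `graph` as the kind requires.
#' @return object of class `eig_attribution`: `values` (n x p matrix),
#'   `completeness_gap` (worst per-sample gap across baselines), `provenance`.
#' @examples
#' F <- prediction_function(function(x) sum(x^2), p = 3)
#' A <- class_attributions(F, matrix(rnorm(15), 5), zero_baseline(3),
#'                         list(kind = "O-L", n_steps = 100))
#' summary(A)
#' @export
class_attributions <- function(F, samples, baselines,
                               path_config = list(kind = "O-L")) {
  samples <- as.matrix(samples)
  p <- pf_dim(F)
  if (ncol(samples) != p)
    stop("samples have ", ncol(samples), " columns but the model expects ", p)
  cfg <- utils::modifyList(list(kind = "O-L", n_steps = 250,
                                codec = NULL, graph = NULL), path_config)
  get_bs <- if (is.function(baselines)) baselines else function(s) baselines
  if (!is.function(baselines) && ncol(baselines$points) != p)
    stop("baseline dimensionality (", ncol(baselines$points),
         ") does not match the model (", p, ")")
  n <- nrow(samples)
  vals <- matrix(NA_real_, n, p)
  gaps <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    x <- samples[i, ]
    res <- tryCatch({
      bs <- get_bs(x)
      per <- apply(bs$points, 1, function(b) {
        a <- path_attributions(
          F, build_path(cfg$kind, b, x, cfg$n_steps, cfg$codec, cfg$graph))
        c(a$values, a$completeness_gap)
      })
      per <- matrix(per, nrow = p + 1)
      list(v = rowMeans(per[seq_len(p), , drop = FALSE]),
           g = max(per[p + 1, ]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
    } else {
      vals[i, ] <- res$v
      gaps[i] <- res$g
    }
  }
  if (length(failed) == n)
    stop("attribution failed for every sample")
  if (length(failed) > 0)
    warning("attribution failed for ", length(failed), " sample(s): ",
            paste(utils::head(failed, 5), collapse = ", "))
  colnames(vals) <- colnames(samples)
  rownames(vals) <- rownames(samples)
  strategy <- if (is.function(baselines)) "per-sample" else baselines$strategy
  structure(list(values = vals, completeness_gap = gaps, failed = failed,
                 provenance = list(path = cfg$kind, n_steps = cfg$n_steps,
                                   baseline = strategy,
                                   target = if (inherits(F, "eig_model"))
                                     F$target else "F")),
            class = "eig_attribution")
}

#' @export
print.eig_attribution <- function(x, ...) {
  cat("Attributions: ", nrow(x$values), " samples x ", ncol(x$values),
      " features [path ", x$provenance$path, ", baseline ",
      x$provenance$baseline, "]\n", sep = "")
  cat("  worst completeness gap: ",
      signif(max(x$completeness_gap, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.eig_attribution <- function(object, ...) {
  m <- colMeans(abs(object$values))
  ord <- order(m, decreasing = TRUE)
  out <- data.frame(feature = colnames(object$values)[ord] %||%
                      paste0("f", ord),
                    mean_abs_attr = m[ord], row.names = NULL)
  cat("Top features by mean |attribution| (path ", object$provenance$path,
      ", baseline ", object$provenance$baseline, "):\n", sep = "")
  print(utils::head(out, 10))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.matrix.eig_attribution <- function(x, ...) x$values

#' @export
plot.eig_attribution <- function(x, top = 20, ...) {
  m <- sort(colMeans(abs(x$values)), decreasing = TRUE)
  m <- utils::head(m, top)
  graphics::barplot(rev(m), horiz = TRUE, las = 1,
                    xlab = "mean |attribution|",
                    main = paste0(x$provenance$path, " / ",
                                  x$provenance$baseline), ...)
  invisible(x)
}

#' Write attributions to TSV with provenance header
#' @param attrs an `eig_attribution`.
#' @param file output path.
#' @param extra named list appended to the provenance header.
#' @export
write_attributions <- function(attrs, file, extra = list()) {
  pv <- c(attrs$provenance, extra)
  con <- base::file(file, "w")
  on.exit(close(con))
  for (k in names(pv)) writeLines(paste0("# ", k, "=", pv[[k]]), con)
  df <- data.frame(sample = rownames(attrs$values) %||%
                     seq_len(nrow(attrs$values)),
                   attrs$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
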