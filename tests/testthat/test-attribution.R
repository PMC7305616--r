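# Gradient integration: closed forms, refinement, batching.

test_that("linear models give exact path-independent attributions", {
  x0 <- c(1, -1, 0, 2); x1 <- c(3, 0, -2, 1)
  want <- lin_w * (x1 - x0)
  for (n in c(2, 50, 1000)) {
    a <- path_attributions(lin_f, linear_path(x0, x1, n))
    expect_equal(a$values, want, tolerance = 1e-12)
    expect_lt(a$completeness_gap, 1e-10)
  }
  # exactness holds on any polyline, not only the straight line
  g <- knn_graph(matrix(stats::rnorm(40), 10, 4), k = 3)
  a_n <- tryCatch(path_attributions(lin_f, neighbor_path(x0, x1, g, 120)),
                  error = function(e) NULL)
  if (!is.null(a_n)) expect_equal(a_n$values, want, tolerance = 1e-10)
})

test_that("bilinear closed form: attributions split the product evenly", {
  f <- prediction_function(function(x) x[1] * x[2], p = 2,
                           grad = function(x) c(x[2], x[1]))
  for (ab in list(c(2, 3), c(-1, 4), c(0.5, 0.5))) {
    a <- path_attributions(f, linear_path(c(0, 0), ab, 250))
    expect_equal(a$values, rep(prod(ab) / 2, 2),
                 tolerance = 1e-6 * abs(prod(ab) / 2))
  }
})

test_that("zero-length paths give zero attributions and zero gap", {
  a <- path_attributions(smooth_f, linear_path(c(1, 2, 3), c(1, 2, 3), 10))
  expect_equal(a$values, c(0, 0, 0))
  expect_equal(a$completeness_gap, 0)
})

test_that("non-finite model output names the failing step", {
  f <- prediction_function(function(x) if (x[1] > 0.5) NaN else x[1], p = 1)
  expect_error(path_attributions(f, linear_path(0, 1, 10)), "step|endpoint")
})

test_that("refinement converges to the dense-quadrature oracle", {
  f <- prediction_function(function(x) sin(5 * x[1]) + x[2], p = 2,
                           grad = function(x) c(5 * cos(5 * x[1]), 1))
  builder <- function(n) linear_path(c(0, 0), c(2, 1), n)
  res <- refine_until(f, builder, tol = 1e-6)
  expect_true(res$converged)
  dF <- abs(res$f_x - res$f_x_prime)
  expect_lte(res$completeness_gap, 1e-6 * max(dF, 1e-8))
  oracle <- path_attributions(f, builder(1e5))
  expect_equal(res$values, oracle$values, tolerance = 1e-6)

  # linear model converges immediately (gap identically ~0)
  lin <- refine_until(lin_f, function(n) linear_path(rep(0, 4), rep(1, 4), n),
                      tol = 1e-10)
  expect_true(lin$converged)
  expect_equal(lin$n_steps, 100)  # first halving check at 2 * n0

  expect_error(refine_until(lin_f, builder, tol = 0), "tol")
  expect_warning(
    hard <- refine_until(f, builder, tol = 1e-14, max_steps = 200),
    "did not converge")
  expect_false(hard$converged)
})

test_that("class attributions average per-baseline results", {
  set.seed(5)
  X <- matrix(stats::rnorm(12), 3, 4)
  b1 <- matrix(stats::rnorm(4), 1)
  # single baseline == per-row path_attributions
  A1 <- class_attributions(lin_f, X, eigrad:::new_baseline_set(b1, "random"),
                           list(kind = "O-L", n_steps = 50))
  for (i in 1:3) {
    want <- path_attributions(lin_f, linear_path(b1, X[i, ], 50))$values
    expect_equal(A1$values[i, ], want, tolerance = 1e-12)
  }
  # duplicated baseline equals the single-baseline result
  A2 <- class_attributions(lin_f, X,
                           eigrad:::new_baseline_set(rbind(b1, b1), "random"),
                           list(kind = "O-L", n_steps = 50))
  expect_equal(A2$values, A1$values, tolerance = 1e-12)
  # linear model, 3 baselines: attribution = w_j (x_j - mean b_j)
  B <- matrix(stats::rnorm(12), 3, 4)
  A3 <- class_attributions(lin_f, X, eigrad:::new_baseline_set(B, "random"),
                           list(kind = "O-L", n_steps = 50))
  want3 <- sweep(X, 2, colMeans(B)) * rep(lin_w, each = 3)
  expect_equal(A3$values, want3, tolerance = 1e-10)
})

test_that("sensitivity: a lone differing feature receives nonzero attribution", {
  f <- prediction_function(function(x) tanh(x[2]), p = 3,
                           grad = function(x) c(0, 1 - tanh(x[2])^2, 0))
  x0 <- c(1, 0, 2); x1 <- c(1, 1.5, 2)
  a <- path_attributions(f, linear_path(x0, x1, 100))
  expect_gt(abs(a$values[2]), 0)
  expect_equal(a$values[c(1, 3)], c(0, 0))
})

test_that("per-sample failures are skipped with a warning, all-failure errors", {
  f <- prediction_function(function(x) if (abs(x[1] - 2) < 0.5) NaN else x[1],
                           p = 1)
  X <- matrix(c(0.5, 2, 1), 3, 1)
  expect_warning(
    A <- class_attributions(f, X, zero_baseline(1),
                            list(kind = "O-L", n_steps = 20)),
    "failed for 1")
  expect_equal(A$failed, 2L)
  expect_true(all(is.na(A$values[2, ])))
  Xbad <- matrix(c(2, 2.1), 2, 1)
  expect_error(suppressWarnings(
    class_attributions(f, Xbad, zero_baseline(1),
                       list(kind = "O-L", n_steps = 20))),
    "every sample")
})

test_that("H-L with a perfectly reconstructing codec reproduces O-L", {
  cd <- codec_affine(diag(3) * 0.5, diag(3) * 2)  # D(E(x)) = x
  set.seed(8)
  x0 <- stats::rnorm(3); x1 <- stats::rnorm(3)
  a_ol <- path_attributions(smooth_f, linear_path(x0, x1, 400))
  a_hl <- path_attributions(smooth_f, latent_linear_path(x0, x1, cd, 400))
  expect_equal(a_hl$values, a_ol$values, tolerance = 1e-4)
})

test_that("attribution TSV round-trips values and provenance", {
  A <- class_attributions(lin_f, matrix(stats::rnorm(8), 2, 4),
                          zero_baseline(4), list(kind = "O-L", n_steps = 20))
  f <- tempfile(fileext = ".tsv")
  write_attributions(A, f, extra = list(seed = 1))
  lines <- readLines(f)
  expect_true(any(grepl("path=O-L", lines)))
  expect_true(any(grepl("baseline=zero", lines)))
  df <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(unname(as.matrix(df[, -1])), unname(A$values),
               tolerance = 1e-10)
  unlink(f)
})
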