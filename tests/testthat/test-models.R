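# Prediction-function contracts, reference training, stability, targets.

test_that("analytic and finite-difference gradients agree with calculus", {
  f_lin <- prediction_function(function(x) 3 * x[1] + 2 * x[2], p = 2)
  expect_equal(gradient(f_lin, c(5, 7)), c(3, 2), tolerance = 1e-8)

  f_prod <- prediction_function(function(x) x[1] * x[2], p = 2)
  expect_equal(gradient(f_prod, c(2, 3)), c(3, 2), tolerance = 1e-8)

  f_mix <- prediction_function(function(x) sin(x[1]) + x[2]^2, p = 2)
  expect_equal(gradient(f_mix, c(0.3, 1.1)), c(cos(0.3), 2.2),
               tolerance = 1e-6)

  # fallback matches analytic gradients on polynomials to 1e-5 relative
  f_poly <- prediction_function(function(x) x[1]^3 - 2 * x[2]^2 + x[1] * x[3],
                                p = 3)
  for (i in 1:5) {
    x <- stats::rnorm(3, sd = 2)
    want <- c(3 * x[1]^2 + x[3], -4 * x[2], x[1])
    expect_equal(gradient(f_poly, x), want,
                 tolerance = 1e-5 * max(1, max(abs(want))))
  }
})

test_that("gradient rejects non-finite inputs and outputs with coordinates", {
  f_bad <- prediction_function(function(x) x[1], p = 2,
                               grad = function(x) c(1, NaN))
  expect_error(gradient(f_bad, c(1, 2)), "coordinate 2")
  f <- prediction_function(function(x) x[1], p = 2)
  expect_error(gradient(f, c(1, NA)), "non-finite")
})

test_that("network input gradients match finite differences", {
  net <- nn_init(c(4, 6, 1), c("tanh", "sigmoid"), seed = 3)
  fun <- function(x) drop(nn_output(net, matrix(x, 1)))
  for (i in 1:3) {
    x <- stats::rnorm(4)
    expect_equal(drop(nn_input_grad(net, matrix(x, 1))),
                 eigrad:::fd_gradient(fun, x), tolerance = 1e-6)
  }
})

test_that("reference training separates separable classes and is deterministic", {
  d <- synth_tabular(n = 200, p = 12, n_informative = 4, effect_size = 5,
                     block_size = 3, block_r = 0.3, seed = 9)
  idx <- seq_len(150)
  m1 <- train_reference_models(d$features[idx, ], d$labels[idx],
                               config = list(q = 4, epochs_ae = 150,
                                             epochs_head = 250), seed = 5)
  held <- predict(m1$model, d$features[-idx, ], type = "response")
  acc <- mean((held > 0.5) == (d$labels[-idx] == "B"))
  expect_gt(acc, 0.9)

  m2 <- train_reference_models(d$features[idx, ], d$labels[idx],
                               config = list(q = 4, epochs_ae = 150,
                                             epochs_head = 250), seed = 5)
  expect_identical(m1$model$net$W, m2$model$net$W)
  expect_identical(pf_eval(m1$model, d$features), pf_eval(m2$model, d$features))

  expect_error(train_reference_models(d$features, d$labels,
                                      config = list(q = 12), seed = 1),
               "smaller than p")
  expect_error(train_reference_models(d$features, rep("A", 200)),
               "2 classes")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  tmp <- tempfile(fileext = ".rds")
  models <- list(codec = ref_fixture$codec, model = ref_fixture$model)
  save_reference_models(models, tmp)
  expect_true(file.exists(paste0(tmp, ".json")))
  side <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(side$p, models$model$p)
  expect_equal(side$q, models$codec$q)
  back <- load_reference_models(tmp)
  x <- matrix(stats::rnorm(2 * models$model$p), 2)
  expect_identical(pf_eval(back$model, x), pf_eval(models$model, x))
  unlink(c(tmp, paste0(tmp, ".json")))
})

test_that("latent stability is 1 for identical and rescaled codecs", {
  set.seed(2)
  pts <- matrix(stats::rnorm(30), 10, 3)
  cd <- codec_pca(pts, q = 2)
  # scaling all latent coordinates preserves distance ranks
  enc2 <- cd$enc
  enc2$W[[1]] <- enc2$W[[1]] * 2
  enc2$b[[1]] <- enc2$b[[1]] * 2
  cd2 <- structure(list(enc = enc2, dec = cd$dec, p = 3, q = 2,
                        kind = "scaled"), class = "eig_codec")
  m <- latent_stability(list(cd, cd, cd2), pts)
  expect_equal(m, matrix(1, 3, 3))
  expect_true(isSymmetric(m))
})

test_that("latent stability matches a hand-computed 3-point Spearman", {
  pts <- matrix(c(0, 0, 1, 0, 0, 3), 3, 2, byrow = TRUE)
  A <- codec_affine(diag(2), diag(2))
  # swap axes and stretch one: distances reorder
  B <- codec_affine(matrix(c(0, 5, 1, 0), 2), diag(2))
  dA <- as.numeric(dist(encode(A, pts)))
  dB <- as.numeric(dist(encode(B, pts)))
  want <- stats::cor(rank(dA), rank(dB))
  m <- latent_stability(list(A, B), pts)
  expect_equal(m[1, 2], want)
  expect_true(all(abs(m) <= 1))
})

test_that("degenerate embeddings give missing correlations with a warning", {
  pts <- matrix(1, 4, 2)  # identical points
  A <- codec_identity(2)
  expect_warning(m <- latent_stability(list(A, A), pts), "constant")
  expect_true(is.na(m[1, 2]))
  expect_equal(diag(m), c(1, 1))
})

test_that("splicing targets follow the max/min epsilon formulas", {
  t1 <- splicing_targets(0.7, 0.5, epsilon = 0.02)
  expect_equal(t1$t_dpsi_inc, 0.5)
  expect_equal(t1$t_dpsi_exc, 0.02)
  expect_equal(t1$t_psi, 0.7)

  t2 <- splicing_targets(0.5, -0.3, epsilon = 0.02)
  expect_equal(t2$t_dpsi_inc, 0.02)
  expect_equal(t2$t_dpsi_exc, 0.3)

  # non-changing event: epsilon floors the inclusion target; the exclusion
  # target |min(eps, 0)| is exactly zero
  t3 <- splicing_targets(0.5, 0, epsilon = 0.015)
  expect_equal(t3$t_dpsi_inc, 0.015)
  expect_equal(t3$t_dpsi_exc, 0)

  # epsilon drawn from the seeded RNG stays in range; the smaller
  # differential target can never exceed the epsilon ceiling
  for (s in 1:20) {
    tt <- splicing_targets(runif(1), runif(1, -1, 1), seed = s)
    expect_gte(tt$epsilon, 0.01)
    expect_lte(tt$epsilon, 0.03)
    expect_lte(min(tt$t_dpsi_inc, tt$t_dpsi_exc), 0.03)
    expect_gte(tt$t_dpsi_inc, 0)
    expect_gte(tt$t_dpsi_exc, 0)
  }
  expect_error(splicing_targets(1.5, 0), "0, 1")
  expect_error(splicing_targets(0.5, 0, epsilon = 0.5), "0.01")
})

test_that("codec reconstruction error is finite and small on training data", {
  err <- reconstruction_error(ref_fixture$codec, ref_fixture$data$features)
  expect_true(all(is.finite(err)))
  # autoencoder must beat the trivial all-mean reconstruction
  X <- ref_fixture$data$features
  base <- sqrt(rowSums(sweep(X, 2, colMeans(X))^2))
  expect_lt(mean(err), mean(base))
})
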