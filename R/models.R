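# Prediction-function and encoder/decoder contracts, reference models.

#' Wrap a scalar function of a p-vector as a prediction function
#'
#' A prediction function is any real-valued, (sub)differentiable map
#' \eqn{F:\mathbb{R}^p \to \mathbb{R}}. Attribution only needs two
#' capabilities: evaluating \eqn{F} and evaluating its gradient. If no
#' analytic gradient is supplied, a central finite-difference fallback with
#' step \eqn{h_j = 10^{-5}\max(1, |x_j|)} is used.
#'
#' @param fun function taking a numeric p-vector, returning a scalar.
#' @param p input dimensionality.
#' @param grad optional gradient function (p-vector in, p-vector out).
#' @param name label used in provenance records.
#' @return an object of class `eig_predfun`.
#' @examples
#' F <- prediction_function(function(x) x[1] * x[2], p = 2)
#' gradient(F, c(2, 3))  # (3, 2)
#' @export
prediction_function <- function(fun, p, grad = NULL, name = "F") {
  stopifnot(is.function(fun), p >= 1)
  structure(list(fun = fun, p = p, grad = grad, name = name),
            class = "eig_predfun")
}

#' @export
print.eig_predfun <- function(x, ...) {
  cat("Prediction function '", x$name, "' on R^", x$p,
      if (is.null(x$grad)) " (finite-difference gradients)" else
        " (analytic gradients)", "\n", sep = "")
  invisible(x)
}

# ---- evaluation / gradient generics -----------------------------------------

pf_dim <- function(F) {
  if (inherits(F, "eig_model")) F$p else F$p
}

#' Evaluate a prediction function on one or more points
#'
#' @param F a prediction function (`eig_predfun` or `eig_model`).
#' @param X a p-vector or an n x p matrix of row-points.
#' @return a numeric vector of length n.
#' @export
pf_eval <- function(F, X) UseMethod("pf_eval")

#' @export
pf_eval.eig_predfun <- function(F, X) {
  X <- as_row_matrix(X, F$p)
  apply(X, 1, F$fun)
}

#' @export
pf_eval.eig_model <- function(F, X) {
  drop(nn_output(F$net, as_row_matrix(X, F$p)))
}

#' Gradient of a prediction function
#'
#' Returns \eqn{\partial F/\partial x_j} for all j, using analytic gradients
#' where the backend provides them and central finite differences otherwise.
#'
#' @inheritParams pf_eval
#' @return an n x p matrix (or a p-vector when `X` is a single point).
#' @export
gradient <- function(F, X) {
  p <- pf_dim(F)
  single <- is.null(dim(X))
  X <- as_row_matrix(X, p)
  if (any(!is.finite(X))) stop("non-finite input to gradient()")
  G <- pf_grad_matrix(F, X)
  bad <- which(!is.finite(G), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite gradient at coordinate ", bad[1, 2],
         " (point ", bad[1, 1], ")")
  if (single) drop(G) else G
}

pf_grad_matrix <- function(F, X) UseMethod("pf_grad_matrix")

#' @export
pf_grad_matrix.eig_model <- function(F, X) nn_input_grad(F$net, X)

#' @export
pf_grad_matrix.eig_predfun <- function(F, X) {
  g <- if (!is.null(F$grad)) apply(X, 1, F$grad)
       else apply(X, 1, function(x) fd_gradient(F$fun, x))
  # apply drops to a vector when p == 1
  if (is.null(dim(g))) matrix(g, ncol = 1) else t(g)
}

# central finite differences, h = 1e-5 * max(1, |x_j|)
fd_gradient <- function(fun, x) {
  p <- length(x)
  g <- numeric(p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    g[j] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  g
}

# ---- encoder/decoder codecs -------------------------------------------------

new_codec <- function(enc, dec, p, q, kind = "custom", meta = list()) {
  stopifnot(q >= 1)
  structure(list(enc = enc, dec = dec, p = p, q = q, kind = kind, meta = meta),
            class = "eig_codec")
}

#' Encode points into latent space
#' @param codec an `eig_codec`.
#' @param X p-vector or n x p matrix.
#' @return n x q matrix of latent coordinates.
#' @export
encode <- function(codec, X) {
  stopifnot(inherits(codec, "eig_codec"))
  nn_output(codec$enc, as_row_matrix(X, codec$p))
}

#' Decode latent points back to feature space
#' @param codec an `eig_codec`.
#' @param Z q-vector or n x q matrix.
#' @return n x p matrix.
#' @export
decode <- function(codec, Z) {
  stopifnot(inherits(codec, "eig_codec"))
  out <- nn_output(codec$dec, as_row_matrix(Z, codec$q))
  if (any(!is.finite(out))) stop("decoder produced non-finite output")
  out
}

#' Per-point reconstruction error of a codec
#' @param codec an `eig_codec`.
#' @param X n x p matrix.
#' @return numeric vector of Euclidean reconstruction errors.
#' @export
reconstruction_error <- function(codec, X) {
  X <- as_row_matrix(X, codec$p)
  R <- decode(codec, encode(codec, X))
  sqrt(rowSums((R - X)^2))
}

#' @export
print.eig_codec <- function(x, ...) {
  cat("Codec (", x$kind, "): R^", x$p, " <-> R^", x$q, "\n", sep = "")
  invisible(x)
}

#' Identity codec (latent space equals feature space)
#' @param p dimensionality.
#' @export
codec_identity <- function(p) {
  I <- diag(p)
  new_codec(nn_affine(I), nn_affine(I), p, p, kind = "identity")
}

#' Affine codec from explicit encode/decode maps
#'
#' `encode(x) = x %*% A_enc + b_enc`, `decode(z) = z %*% A_dec + b_dec`.
#' Useful for constructing codecs with known closed-form behaviour.
#' @param A_enc,b_enc encoder matrix/offset.
#' @param A_dec,b_dec decoder matrix/offset.
#' @export
codec_affine <- function(A_enc, A_dec, b_enc = NULL, b_dec = NULL) {
  A_enc <- as.matrix(A_enc); A_dec <- as.matrix(A_dec)
  stopifnot(ncol(A_enc) == nrow(A_dec), nrow(A_enc) == ncol(A_dec))
  new_codec(nn_affine(A_enc, b_enc), nn_affine(A_dec, b_dec),
            nrow(A_enc), ncol(A_enc), kind = "affine")
}

#' Linear (principal-component) codec
#'
#' Encoder projects centred data onto the top `q` principal axes; decoder
#' maps back. The optimal linear autoencoder under squared error.
#'
#' @param X n x p training matrix.
#' @param q latent dimensionality (`q <= p`).
#' @export
codec_pca <- function(X, q) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(q >= 1, q <= p)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  V <- pc$rotation[, seq_len(q), drop = FALSE]
  enc <- nn_affine(V, b = -as.numeric(pc$center %*% V))
  dec <- nn_affine(t(V), b = pc$center)
  new_codec(enc, dec, p, q, kind = "pca")
}

#' Nonlinear autoencoder codec
#'
#' A tanh autoencoder `p -> hidden -> q -> hidden -> p` trained for mean
#' squared reconstruction error with full-batch Adam. Inputs are standardised
#' internally; the standardisation is folded back into the first/last layers
#' so `encode`/`decode` operate on raw coordinates.
#'
#' @param X n x p training matrix.
#' @param q latent dimensionality (must satisfy `q < p`).
#' @param hidden hidden-layer width.
#' @param epochs,lr training budget.
#' @param seed integer seed fixing the weight initialisation.
#' @export
codec_autoencoder <- function(X, q, hidden = max(16, 2 * q), epochs = 300,
                              lr = 0.01, seed = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (q >= p) stop("latent dimensionality q must be smaller than p")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  net <- nn_init(c(p, hidden, q, hidden, p),
                 c("tanh", "identity", "tanh", "identity"), seed = seed)
  net <- nn_train(net, Xs, Xs, loss = "mse", epochs = epochs, lr = lr)
  enc <- structure(list(sizes = net$sizes[1:3], acts = net$acts[1:2],
                        W = net$W[1:2], b = net$b[1:2]), class = "eig_nn")
  dec <- structure(list(sizes = net$sizes[3:5], acts = net$acts[3:4],
                        W = net$W[3:4], b = net$b[3:4]), class = "eig_nn")
  enc <- nn_fold_input(enc, center, scale)
  dec <- nn_fold_output(dec, center, scale)
  new_codec(enc, dec, p, q, kind = "autoencoder",
            meta = list(hidden = hidden, epochs = epochs, lr = lr, seed = seed,
                        final_loss = attr(net, "loss")))
}

# ---- reference models -------------------------------------------------------

#' Train reference codec and predictor on labelled data
#'
#' Trains an autoencoder codec for reconstruction, then a small classifier
#' head on the (frozen) latent representation; the returned predictor is the
#' composition encoder + head, so attribution paths can be built in either
#' the original or the latent space of the same model.
#'
#' @param features n x p numeric matrix.
#' @param labels vector of class labels (>= 2 classes; the first level in
#'   sort order is coded 0). For binary tasks the predictor outputs
#'   P(class == positive).
#' @param config list of hyperparameters: `q` (latent dim), `hidden`,
#'   `head_hidden`, `epochs_ae`, `epochs_head`, `lr`.
#' @param seed integer seed fixing all stochastic initialisation.
#' @return list with elements `codec` (an `eig_codec`) and `model`
#'   (an `eig_model` prediction function).
#' @export
train_reference_models <- function(features, labels, config = list(), seed = 1) {
  X <- as.matrix(features)
  p <- ncol(X)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  # default latent size ~ sqrt(p): the narrow bottleneck doubles as a
  # regularizer, keeping the predictor from loading on idiosyncratic noise
  # directions (a wide latent head overfits and spreads attribution onto
  # uninformative features)
  cfg <- utils::modifyList(list(q = max(2, min(p - 1, ceiling(sqrt(p)))),
                                hidden = NULL,
                                head_hidden = 16, epochs_ae = 400,
                                epochs_head = 400, lr = 0.01), config)
  if (is.null(cfg$hidden)) cfg$hidden <- max(32, 2 * cfg$q)
  if (cfg$q >= p) stop("latent dimensionality q must be smaller than p")
  codec <- codec_autoencoder(X, q = cfg$q, hidden = cfg$hidden,
                             epochs = cfg$epochs_ae, lr = cfg$lr, seed = seed)
  Z <- encode(codec, X)
  y <- as.numeric(labels == levels(labels)[nlevels(labels)])
  head <- nn_init(c(cfg$q, cfg$head_hidden, 1), c("tanh", "sigmoid"),
                  seed = seed + 1)
  # standardise latent inputs for stable training, then fold back
  zc <- colMeans(Z); zs <- apply(Z, 2, stats::sd); zs[zs < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, zc), 2, zs, "/")
  head <- nn_train(head, Zs, y, loss = "logloss",
                   epochs = cfg$epochs_head, lr = cfg$lr)
  head <- nn_fold_input(head, zc, zs)
  # the attribution surface is the pre-sigmoid score: probability-scale
  # gradients are inflated wherever a path crosses the steep part of the
  # sigmoid and vanish in its tails, which skews |attribution| between
  # samples near and far from the decision boundary; the logit has no such
  # saturation asymmetry
  net <- nn_stack(codec$enc, head)
  net$acts[length(net$acts)] <- "identity"
  model <- structure(list(net = net, p = p,
                          target = paste0("logit P(",
                                          levels(labels)[nlevels(labels)], ")"),
                          classes = levels(labels), config = cfg, seed = seed),
                     class = c("eig_model"))
  list(codec = codec, model = model)
}

#' @export
print.eig_model <- function(x, ...) {
  cat("Reference model on R^", x$p, ", target ", x$target,
      " (layers: ", paste(x$net$sizes, collapse = "-"), ")\n", sep = "")
  invisible(x)
}

#' @export
predict.eig_model <- function(object, newdata,
                              type = c("response", "logit"), ...) {
  type <- match.arg(type)
  sc <- pf_eval(object, newdata)
  if (type == "response") 1 / (1 + exp(-sc)) else sc
}

# ---- model persistence ------------------------------------------------------

#' Save / load a reference model pair
#'
#' Weights are stored in R's native serialisation; a JSON sidecar records
#' dimensionality, seed and a hash of the configuration for provenance.
#' @param models list as returned by [train_reference_models()].
#' @param path file path for the checkpoint (`.rds`); the sidecar is
#'   `paste0(path, ".json")`.
#' @export
save_reference_models <- function(models, path) {
  saveRDS(models, path)
  side <- list(p = models$model$p, q = models$codec$q,
               seed = models$model$seed,
               config_hash = config_hash(models$model$config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_reference_models
#' @export
load_reference_models <- function(path) readRDS(path)

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  # small rolling hash; provenance only, not cryptographic
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

# ---- latent stability -------------------------------------------------------

#' Latent-space stability across codecs
#'
#' Embedding robustness is measured through neighbourhood structure: for each
#' codec, the \eqn{n(n-1)/2} pairwise Euclidean distances among the encoded
#' points are computed, and entry (a, b) of the returned matrix is the
#' Spearman rank correlation between the distance vectors of codecs a and b.
#' Stable embeddings preserve relative distances and give correlations near 1.
#'
#' @param codecs list of `eig_codec` objects (length >= 2); an element may
#'   also be a precomputed n x q embedding matrix of the same points.
#' @param points n x p matrix of evaluation points (n >= 3).
#' @return symmetric correlation matrix with unit diagonal; entries are `NA`
#'   (with a warning) when a codec collapses all points to one distance.
#' @export
latent_stability <- function(codecs, points) {
  stopifnot(length(codecs) >= 2)
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  dvec <- lapply(codecs, function(cd) {
    emb <- if (is.matrix(cd)) {
      stopifnot(nrow(cd) == nrow(points))
      cd
    } else encode(cd, points)
    as.numeric(stats::dist(emb))
  })
  m <- length(codecs)
  out <- diag(1, m)
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    if (stats::sd(dvec[[a]]) < 1e-15 || stats::sd(dvec[[b]]) < 1e-15) {
      warning("constant distance vector for codec ", a, " or ", b,
              "; correlation undefined")
      out[a, b] <- out[b, a] <- NA_real_
    } else {
      out[a, b] <- out[b, a] <- stats::cor(dvec[[a]], dvec[[b]],
                                           method = "spearman")
    }
  }
  out
}

# ---- splicing-code target transforms ---------------------------------------

#' Splicing-code prediction targets from expected inclusion levels
#'
#' The splicing-code formulation predicts three quantities per cassette event
#' and condition pair: the expected inclusion level \eqn{T_\Psi = E[\Psi]},
#' and two non-negative differential targets
#' \eqn{T_{\Delta\Psi,inc} = |\max(\epsilon, E[\Delta\Psi])|} and
#' \eqn{T_{\Delta\Psi,exc} = |\min(\epsilon, E[\Delta\Psi])|}. The small
#' \eqn{\epsilon}, drawn uniformly in [0.01, 0.03], gives non-changing events
#' small symmetric targets instead of exact zeros; at most one of the two
#' differential targets can exceed \eqn{\epsilon} for one event/condition
#' pair.
#'
#' @param e_psi expected inclusion level in \[0, 1\].
#' @param e_dpsi expected differential inclusion in \[-1, 1\].
#' @param epsilon value in \[0.01, 0.03\]; drawn from the seeded RNG when NULL.
#' @param seed integer seed used when `epsilon` is drawn.
#' @return list of class `splicing_targets` with `t_psi`, `t_dpsi_inc`,
#'   `t_dpsi_exc`, `epsilon`.
#' @export
splicing_targets <- function(e_psi, e_dpsi, epsilon = NULL, seed = NULL) {
  if (!is.finite(e_psi) || e_psi < 0 || e_psi > 1)
    stop("e_psi must be in [0, 1]")
  if (!is.finite(e_dpsi) || e_dpsi < -1 || e_dpsi > 1)
    stop("e_dpsi must be in [-1, 1]")
  if (is.null(epsilon)) {
    if (!is.null(seed)) set.seed(seed)
    epsilon <- stats::runif(1, 0.01, 0.03)
  }
  if (epsilon < 0.01 || epsilon > 0.03)
    stop("epsilon must be in [0.01, 0.03]")
  structure(list(t_psi = e_psi,
                 t_dpsi_inc = abs(max(epsilon, e_dpsi)),
                 t_dpsi_exc = abs(min(epsilon, e_dpsi)),
                 epsilon = epsilon),
            class = "splicing_targets")
}
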