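# Minimal dense feed-forward networks with analytic input gradients.
#
# These back the reference prediction functions and autoencoder codecs.
# Everything is full-batch and matrix-based; the networks involved are small
# (tens of units), so plain BLAS-backed R is adequate.

act_fun <- function(z, act) {
  switch(act,
    identity = z,
    tanh     = tanh(z),
    sigmoid  = 1 / (1 + exp(-z)),
    stop("unknown activation: ", act)
  )
}

# derivative expressed through the activation *output* a
act_deriv <- function(a, act) {
  switch(act,
    identity = array(1, dim(a)),
    tanh     = 1 - a^2,
    sigmoid  = a * (1 - a),
    stop("unknown activation: ", act)
  )
}

#' Initialise a dense feed-forward network
#'
#' @param sizes integer vector of layer widths, input first.
#' @param acts character vector of activations, one per weight layer
#'   (`"identity"`, `"tanh"` or `"sigmoid"`).
#' @param seed optional integer seed for the weight draw.
#' @return an object of class `eig_nn`.
#' @keywords internal
nn_init <- function(sizes, acts, seed = NULL) {
  stopifnot(length(sizes) >= 2, length(acts) == length(sizes) - 1)
  if (!is.null(seed)) set.seed(seed)
  W <- vector("list", length(acts))
  b <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(1 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(sizes = sizes, acts = acts, W = W, b = b), class = "eig_nn")
}

as_row_matrix <- function(X, p) {
  if (is.null(dim(X))) {
    stopifnot(length(X) %% p == 0)
    X <- matrix(X, ncol = p, byrow = TRUE)
  }
  stopifnot(ncol(X) == p)
  X
}

# forward pass caching all layer activations (A[[1]] is the input)
nn_forward <- function(net, X) {
  X <- as_row_matrix(X, net$sizes[1])
  A <- vector("list", length(net$acts) + 1)
  A[[1]] <- X
  for (l in seq_along(net$acts)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- act_fun(Z, net$acts[l])
  }
  A
}

nn_output <- function(net, X) {
  A <- nn_forward(net, X)
  A[[length(A)]]
}

# gradient of the (scalar) output w.r.t. each input row; returns n x p
nn_input_grad <- function(net, X) {
  A <- nn_forward(net, X)
  L <- length(net$acts)
  if (ncol(A[[L + 1]]) != 1)
    stop("input gradient requires a scalar-output network")
  delta <- act_deriv(A[[L + 1]], net$acts[L])  # dOut/dZ_L, n x 1
  for (l in L:1) {
    back <- delta %*% t(net$W[[l]])
    if (l > 1) {
      delta <- back * act_deriv(A[[l]], net$acts[l - 1])
    } else {
      return(back)
    }
  }
}

# full-batch parameter gradients for one loss evaluation
nn_backprop <- function(net, X, Y, loss) {
  A <- nn_forward(net, X)
  L <- length(net$acts)
  n <- nrow(A[[1]])
  out <- A[[L + 1]]
  Y <- as_row_matrix(Y, ncol(out))
  if (loss == "mse") {
    err <- out - Y
    lval <- mean(err^2)
    dZ <- (2 / length(err)) * err * act_deriv(out, net$acts[L])
  } else if (loss == "logloss") {
    # canonical link: assumes sigmoid output activation
    eps <- 1e-12
    lval <- -mean(Y * log(out + eps) + (1 - Y) * log(1 - out + eps))
    dZ <- (out - Y) / n
  } else stop("unknown loss: ", loss)
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in L:1) {
    dW[[l]] <- crossprod(A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1) dZ <- (dZ %*% t(net$W[[l]])) * act_deriv(A[[l]], net$acts[l - 1])
  }
  list(dW = dW, db = db, loss = lval)
}

#' Train a network with full-batch Adam
#'
#' @param net an `eig_nn` network.
#' @param X,Y training inputs / targets (rows are samples).
#' @param loss `"mse"` or `"logloss"`.
#' @param epochs,lr optimisation budget and step size.
#' @param weight_decay decoupled L2 penalty on the weights (AdamW style);
#'   keeps unused units in their near-linear regime.
#' @return the trained network with a `loss` attribute (final loss).
#' @keywords internal
nn_train <- function(net, X, Y, loss = "mse", epochs = 300, lr = 0.01,
                     weight_decay = 0) {
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  lval <- NA_real_
  for (t in seq_len(epochs)) {
    g <- nn_backprop(net, X, Y, loss)
    lval <- g$loss
    if (!is.finite(lval))
      stop("network training diverged (non-finite loss at epoch ", t, ")")
    for (l in seq_along(net$W)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$dW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$dW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$db[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$db[[l]]^2
      mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
      mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
      net$W[[l]] <- net$W[[l]] - lr * (mhW / (sqrt(vhW) + eps) +
                                       weight_decay * net$W[[l]])
      net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  attr(net, "loss") <- lval
  net
}

# fold an input affine transform (X - center)/scale into the first layer,
# so the network accepts unstandardised inputs
nn_fold_input <- function(net, center, scale) {
  net$b[[1]] <- net$b[[1]] - as.numeric((center / scale) %*% net$W[[1]])
  net$W[[1]] <- net$W[[1]] / scale
  net
}

# fold an output affine transform out*scale + center into the last layer
nn_fold_output <- function(net, center, scale) {
  L <- length(net$W)
  stopifnot(net$acts[L] == "identity")
  net$W[[L]] <- sweep(net$W[[L]], 2, scale, "*")
  net$b[[L]] <- net$b[[L]] * scale + center
  net
}

# concatenate two networks (output of a feeds input of b)
nn_stack <- function(a, b) {
  stopifnot(a$sizes[length(a$sizes)] == b$sizes[1])
  structure(list(
    sizes = c(a$sizes, b$sizes[-1]),
    acts  = c(a$acts, b$acts),
    W     = c(a$W, b$W),
    b     = c(a$b, b$b)
  ), class = "eig_nn")
}

# a bare affine layer z = X %*% W + b as a network
nn_affine <- function(W, b = NULL) {
  W <- as.matrix(W)
  if (is.null(b)) b <- numeric(ncol(W))
  structure(list(sizes = c(nrow(W), ncol(W)), acts = "identity",
                 W = list(W), b = list(b)), class = "eig_nn")
}
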