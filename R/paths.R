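# Discretised attribution paths.
#
# A path is an ordered point sequence from the baseline x' to the sample x.
# Four kinds: O-L (straight line in feature space), H-L (straight line in
# latent space, decoded), O-N / H-N (k-NN-graph shortest path in feature /
# latent space). Nonlinear paths exist to keep the trajectory near the data
# manifold, where the model's gradients are meaningful.

new_path <- function(points, kind, bridge_info = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  total <- sum(seg)
  if (total < 1e-300) {
    # degenerate path (x == x'): keep a uniform grid
    alphas <- seq(0, 1, length.out = n)
  } else {
    keep <- c(TRUE, seg > 0)  # drop zero-length steps so alpha is strictly increasing
    points <- points[keep, , drop = FALSE]
    n <- nrow(points)
    seg <- seg[seg > 0]
    alphas <- c(0, cumsum(seg) / total)
    alphas[n] <- 1
  }
  structure(list(points = points, alphas = alphas, kind = kind,
                 bridge_info = bridge_info), class = "eig_path")
}

#' @export
print.eig_path <- function(x, ...) {
  cat("Path (", x$kind, "): ", nrow(x$points), " points in R^",
      ncol(x$points), ", length ", signif(path_length(x), 4), "\n", sep = "")
  invisible(x)
}

#' Total polyline length of a path
#' @param path an `eig_path`.
#' @export
path_length <- function(path) {
  P <- path$points
  n <- nrow(P)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2)))
}

#' Straight-line path in feature space (O-L)
#'
#' \eqn{\gamma(\alpha) = x' + \alpha (x - x')} on a uniform grid.
#' @param x_prime baseline point.
#' @param x sample point.
#' @param n number of discretisation points (>= 2); 250 is the default
#'   operating resolution.
#' @export
linear_path <- function(x_prime, x, n = 250) {
  stopifnot(n >= 2, length(x) == length(x_prime))
  a <- seq(0, 1, length.out = n)
  P <- outer(1 - a, as.numeric(x_prime)) + outer(a, as.numeric(x))
  P[1, ] <- x_prime
  P[n, ] <- x
  new_path(P, "O-L")
}

#' Latent-linear path (H-L)
#'
#' Encodes both endpoints, walks the straight line between z' = E(x') and
#' z = E(x) in latent space and decodes it back. Because the codec does not
#' reconstruct the endpoints exactly, short linear bridges connect x' to
#' D(z') and D(z) to x; each leg receives interpolation points in proportion
#' to its length. Endpoints are exact.
#'
#' @param x_prime,x baseline and sample points.
#' @param codec an `eig_codec`.
#' @param n total number of points (>= 4).
#' @export
latent_linear_path <- function(x_prime, x, codec, n = 250) {
  stopifnot(n >= 4)
  x_prime <- as.numeric(x_prime); x <- as.numeric(x)
  z0 <- encode(codec, x_prime)
  z1 <- encode(codec, x)
  latent_curve <- function(s) {  # s in [0,1] -> decoded point(s)
    Zs <- outer(1 - s, as.numeric(z0)) + outer(s, as.numeric(z1))
    decode(codec, Zs)
  }
  assemble_bridged_path(x_prime, x, latent_curve, n, kind = "H-L")
}

# Shared assembly for latent paths: a curve(s in [0,1]) between the decoded
# endpoints, plus endpoint bridges. Points are spread over the three legs
# proportionally to (approximate) arc length.
assemble_bridged_path <- function(x_prime, x, curve, n, kind) {
  d0 <- as.numeric(curve(0))
  d1 <- as.numeric(curve(1))
  l1 <- sqrt(sum((x_prime - d0)^2))
  l3 <- sqrt(sum((d1 - x)^2))
  probe <- curve(seq(0, 1, length.out = 33))
  l2 <- sum(sqrt(rowSums((probe[-1, , drop = FALSE] -
                          probe[-33, , drop = FALSE])^2)))
  lens <- c(l1, l2, l3)
  if (sum(lens) < 1e-300) {
    P <- matrix(rep(x, each = n), n)
    P[1, ] <- x_prime
    return(new_path(P, kind, bridge_info = c(0, 0)))
  }
  counts <- allocate_intervals(lens, n - 1)
  pieces <- list()
  if (counts[1] > 0) {
    a <- seq(0, 1, length.out = counts[1] + 1)[-(counts[1] + 1)]
    pieces$b1 <- outer(1 - a, x_prime) + outer(a, d0)
  }
  if (counts[2] > 0) {
    s <- seq(0, 1, length.out = counts[2] + 1)[-(counts[2] + 1)]
    pieces$core <- curve(s)
  }
  if (counts[3] > 0) {
    a <- seq(0, 1, length.out = counts[3] + 1)[-(counts[3] + 1)]
    pieces$b2 <- outer(1 - a, d1) + outer(a, x)
  }
  P <- do.call(rbind, c(pieces, list(matrix(x, 1))))
  P[1, ] <- x_prime
  P[nrow(P), ] <- x
  new_path(P, kind, bridge_info = c(l1, l3))
}

# distribute `total` intervals over segments proportionally to length,
# at least one interval per segment of positive length (largest remainder)
allocate_intervals <- function(lens, total) {
  pos <- lens > 0
  k <- sum(pos)
  stopifnot(total >= k)
  counts <- integer(length(lens))
  if (k == 0) return(counts)
  share <- lens[pos] / sum(lens[pos]) * (total - k)
  base <- floor(share)
  rem <- total - k - sum(base)
  extra <- integer(k)
  if (rem > 0) {
    ord <- order(share - base, decreasing = TRUE)
    extra[ord[seq_len(rem)]] <- 1L
  }
  counts[pos] <- 1L + base + extra
  counts
}

# ---- k-nearest-neighbor graphs ---------------------------------------------

#' k-nearest-neighbor graph over reference points
#'
#' Undirected graph in which an edge (a, b) exists when b is among a's k
#' nearest points or vice versa, weighted by Euclidean distance. Duplicate
#' points yield zero-weight edges.
#'
#' @param points n x p matrix of reference (training) points.
#' @param k neighbor count (`1 <= k < n`); default 10.
#' @param space `"original"` or `"latent"`, recorded so paths know whether
#'   waypoints must be decoded.
#' @return an object of class `eig_knn_graph`.
#' @export
knn_graph <- function(points, k = 10, space = c("original", "latent")) {
  space <- match.arg(space)
  X <- as.matrix(points)
  n <- nrow(X)
  if (!(n > k && k >= 1)) stop("need n > k >= 1")
  D <- as.matrix(stats::dist(X))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    js <- (seq_len(n)[-i])[nb]
    edges <- rbind(edges, cbind(pmin(i, js), pmax(i, js)))
  }
  edges <- unique(edges)
  w <- D[edges]
  structure(list(nodes = X, k = k, space = space,
                 edges = data.frame(from = edges[, 1], to = edges[, 2],
                                    weight = w)),
            class = "eig_knn_graph")
}

#' @export
print.eig_knn_graph <- function(x, ...) {
  cat("kNN graph: ", nrow(x$nodes), " nodes, k = ", x$k, ", ",
      nrow(x$edges), " edges (", x$space, " space)\n", sep = "")
  invisible(x)
}

# Dijkstra between two extra points attached to the graph by their k nearest
# nodes; returns the waypoint matrix including both endpoints.
graph_waypoints <- function(graph, a, b) {
  X <- graph$nodes
  n <- nrow(X)
  da <- sqrt(colSums((t(X) - as.numeric(a))^2))
  db <- sqrt(colSums((t(X) - as.numeric(b))^2))
  ka <- order(da)[seq_len(graph$k)]
  kb <- order(db)[seq_len(graph$k)]
  ed <- rbind(as.matrix(graph$edges[, 1:2]),
              cbind(n + 1L, ka), cbind(n + 2L, kb))
  w <- c(graph$edges$weight, da[ka], db[kb])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- w
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = n + 1L, to = n + 2L, mode = "all",
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0)
    stop("baseline and sample are in disconnected graph components; ",
         "increase k")
  V <- rbind(X, matrix(a, 1, ncol(X)), matrix(b, 1, ncol(X)))
  V[vp, , drop = FALSE]
}

#' Neighbor path (O-N / H-N)
#'
#' Adds the baseline and sample to a k-NN graph (each linked to its k nearest
#' reference points), finds the minimum-total-distance waypoint sequence with
#' Dijkstra's algorithm, and interpolates linearly between consecutive
#' waypoints. Interpolation points are allotted proportionally to segment
#' length with every waypoint retained. For a latent-space graph the
#' waypoints are found between z' = E(x') and z = E(x), the latent polyline
#' is decoded, and endpoint bridges are added as for [latent_linear_path()].
#'
#' @param x_prime,x baseline and sample points (in the original space).
#' @param graph an `eig_knn_graph`.
#' @param n total number of points (at least the number of waypoints).
#' @param codec an `eig_codec`; required when `graph$space == "latent"`.
#' @export
neighbor_path <- function(x_prime, x, graph, n = 250, codec = NULL) {
  x_prime <- as.numeric(x_prime); x <- as.numeric(x)
  if (graph$space == "latent") {
    if (is.null(codec)) stop("latent-space graph requires a codec")
    z0 <- as.numeric(encode(codec, x_prime))
    z1 <- as.numeric(encode(codec, x))
    Wp <- graph_waypoints(graph, z0, z1)
    curve <- function(s) decode(codec, polyline_point(Wp, s))
    return(assemble_bridged_path(x_prime, x, curve, n, kind = "H-N"))
  }
  Wp <- graph_waypoints(graph, x_prime, x)
  m <- nrow(Wp) - 1
  if (n < nrow(Wp)) stop("n must be at least the number of waypoints")
  seg <- sqrt(rowSums((Wp[-1, , drop = FALSE] - Wp[-(m + 1), , drop = FALSE])^2))
  if (sum(seg) < 1e-300) return(new_path(rbind(Wp[1, ], Wp[1, ]), "O-N"))
  counts <- allocate_intervals(seg, n - 1)
  pieces <- vector("list", m)
  for (i in seq_len(m)) {
    if (counts[i] == 0) next
    a <- seq(0, 1, length.out = counts[i] + 1)[-(counts[i] + 1)]
    pieces[[i]] <- outer(1 - a, Wp[i, ]) + outer(a, Wp[i + 1, ])
  }
  P <- do.call(rbind, c(pieces, list(Wp[m + 1, , drop = FALSE])))
  P[1, ] <- x_prime
  P[nrow(P), ] <- x
  new_path(P, "O-N")
}

# point(s) on a waypoint polyline at normalized arc-length position(s) s
polyline_point <- function(Wp, s) {
  m <- nrow(Wp) - 1
  seg <- sqrt(rowSums((Wp[-1, , drop = FALSE] - Wp[-(m + 1), , drop = FALSE])^2))
  if (sum(seg) < 1e-300) return(Wp[rep(1, length(s)), , drop = FALSE])
  cum <- c(0, cumsum(seg)) / sum(seg)
  out <- matrix(NA_real_, length(s), ncol(Wp))
  for (i in seq_along(s)) {
    j <- max(1, min(m, findInterval(s[i], cum, rightmost.closed = TRUE)))
    denom <- cum[j + 1] - cum[j]
    t <- if (denom > 0) (s[i] - cum[j]) / denom else 0
    out[i, ] <- (1 - t) * Wp[j, ] + t * Wp[j + 1, ]
  }
  out
}

#' Build a path of a given kind
#'
#' Convenience dispatcher used by the batch attribution and pipeline layers.
#' @param kind one of `"O-L"`, `"H-L"`, `"O-N"`, `"H-N"`.
#' @param x_prime,x baseline and sample.
#' @param n number of points.
#' @param codec codec for `H-*` kinds.
#' @param graph `eig_knn_graph` for `*-N` kinds.
#' @export
build_path <- function(kind, x_prime, x, n = 250, codec = NULL, graph = NULL) {
  switch(kind,
    "O-L" = linear_path(x_prime, x, n),
    "O-N" = neighbor_path(x_prime, x, graph, n),
    "H-L" = latent_linear_path(x_prime, x, codec, n),
    "H-N" = neighbor_path(x_prime, x, graph, n, codec = codec),
    stop("unknown path kind: ", kind)
  )
}

#' Export a path as TSV (alpha + coordinates per row)
#' @param path an `eig_path`.
#' @param file output path.
#' @export
write_path_tsv <- function(path, file) {
  df <- data.frame(alpha = path$alphas, path$points)
  names(df) <- c("alpha", paste0("x", seq_len(ncol(path$points))))
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", path$kind), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
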