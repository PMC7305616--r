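# Shared fixtures, built once per test run.

# smooth nonlinear prediction function with analytic gradient (p = 3)
smooth_f <- prediction_function(
  function(x) sin(x[1]) + 0.5 * x[2]^2 + x[1] * x[3],
  p = 3,
  grad = function(x) c(cos(x[1]) + x[3], x[2], x[1]),
  name = "smooth3")

# linear model with known coefficients
lin_w <- c(1.5, -2, 0.5, 3)
lin_f <- prediction_function(function(x) sum(lin_w * x), p = 4,
                             grad = function(x) lin_w, name = "linear4")

# small trained reference pair on separable synthetic data (cached)
ref_fixture <- local({
  d <- synth_tabular(n = 160, p = 24, n_informative = 5, effect_size = 3,
                     block_size = 4, block_r = 0.6, seed = 42)
  models <- train_reference_models(
    d$features, d$labels,
    config = list(q = 6, hidden = 24, epochs_ae = 200, epochs_head = 300),
    seed = 7)
  list(data = d, codec = models$codec, model = models$model)
})

# brute-force shortest path by simple-path enumeration (independent of igraph)
brute_shortest <- function(nodes, edges, from, to) {
  n <- nrow(nodes)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]; w <- edges$weight[r]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- list(cost = Inf, path = NULL)
  walk <- function(v, visited, cost, path) {
    if (cost >= best$cost) return()
    if (v == to) {
      best <<- list(cost = cost, path = path)
      return()
    }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        walk(u, visited, cost + nb[r, 2], c(path, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  walk(from, visited, 0, from)
  best
}

# exact hypergeometric pmf via binomial coefficients (oracle)
hyper_pmf_exact <- function(x, K, N, n) {
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}

# upper-tail hypergeometric by direct summation (oracle)
hyper_upper_exact <- function(overlap, selected, known, universe) {
  xs <- overlap:min(selected, known)
  sum(hyper_pmf_exact(xs, known, universe, selected))
}

# two-sided Fisher p by direct pmf summation (oracle); same relative-error
# guard as the conventional definition (include tables at most (1 + 1e-7)
# times as probable as the observed one)
fisher_two_sided_exact <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  xs <- max(0, n - (N - K)):min(n, K)
  pm <- hyper_pmf_exact(xs, K, N, n)
  obs <- hyper_pmf_exact(a, K, N, n)
  sum(pm[pm <= obs * (1 + 1e-7)])
}
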