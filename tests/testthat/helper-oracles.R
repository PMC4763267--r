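# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# double-loop convolution v_j(t) = sum_tau b_j(tau) x(t - lag - tau)
oracle_convolve <- function(x, b, lag = 0) {
  T_ <- length(x)
  M <- length(b)
  v <- numeric(T_)
  for (t in seq_len(T_)) {
    for (tau in 0:(M - 1)) {
      src <- t - lag - tau
      if (src >= 1) v[t] <- v[t] + b[tau + 1] * x[src]
    }
  }
  v
}

# mean shortest-path length over unordered pairs of the largest component
oracle_path_length <- function(g) {
  g <- igraph::as_undirected(g, mode = "collapse")
  comp <- igraph::components(g)
  lc <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  D <- igraph::distances(lc)
  mean(D[upper.tri(D)])
}

# local clustering by explicit neighbour-pair counting
oracle_clustering <- function(g) {
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  local <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, 0)
  mean(local)
}

# exhaustive maximum matching of a digraph edge list (no shared start or
# end vertices), by recursion over edges
oracle_max_matching <- function(el) {
  if (is.null(el) || nrow(el) == 0) return(0L)
  rec <- function(i, used_from, used_to) {
    if (i > nrow(el)) return(0L)
    best <- rec(i + 1L, used_from, used_to)
    f <- el[i, 1]; t <- el[i, 2]
    if (!(f %in% used_from) && !(t %in% used_to)) {
      best <- max(best, 1L + rec(i + 1L, c(used_from, f), c(used_to, t)))
    }
    best
  }
  rec(1L, integer(0), integer(0))
}

# exhaustive ROC sweep: best Youden J over all candidate thresholds
oracle_roc <- function(pred, actual) {
  cand <- sort(unique(pred))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2, cand[length(cand)] + 1)
  best <- -Inf
  for (th in cand) {
    yhat <- as.integer(pred > th)
    tp <- sum(yhat == 1 & actual == 1) / sum(actual == 1)
    tn <- sum(yhat == 0 & actual == 0) / sum(actual == 0)
    best <- max(best, tp + tn - 1)
  }
  best
}

random_digraph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n)
  diag(A) <- FALSE
  igraph::graph_from_adjacency_matrix(A * 1, mode = "directed")
}
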