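#' Graph metrics and small-world-ness
#'
#' All small-world quantities are computed on the binarised, symmetrised
#' version of the input graph (direction is kept only for controllability
#' analyses). Two metrics are provided: the ratio metric
#' \deqn{S_w = (C/C_r) / (L/L_r)}
#' against an Erdos-Renyi reference with matched nodes and edges (values
#' above 1 suggest small-world structure, but the metric grows with network
#' size), and the bounded metric
#' \deqn{\omega = L_r/L - C/C_l}
#' which compares the clustering against a matched ring lattice and the path
#' length against the random reference: values near 0 indicate small-world
#' structure, near +1 a random-like graph, near -1 a lattice-like graph.
#'
#' @name graph_metrics
NULL

as_simple_undirected <- function(g) {
  stopifnot(igraph::is_igraph(g))
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
}

#' Degree distribution
#'
#' Fraction of nodes at each observed degree, on the symmetrised graph.
#'
#' @param net An igraph graph.
#' @return A tibble with columns `degree` and `p`; `p` sums to 1.
#' @export
degree_distribution <- function(net) {
  g <- as_simple_undirected(net)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(g)
  tb <- table(deg)
  tibble::tibble(degree = as.integer(names(tb)),
                 p = as.numeric(tb) / length(deg))
}

#' Average shortest path length
#'
#' Mean hop count over unordered node pairs of the largest connected
#' component of the symmetrised graph.
#'
#' @param net An igraph graph.
#' @return A single number >= 1 (for graphs with at least one edge).
#' @export
average_path_length <- function(net) {
  g <- as_simple_undirected(net)
  if (igraph::vcount(g) < 2) {
    stop("average path length needs at least 2 nodes", call. = FALSE)
  }
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  lc <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  if (igraph::vcount(lc) < 2) {
    stop("largest component has a single node", call. = FALSE)
  }
  igraph::mean_distance(lc, directed = FALSE, unconnected = FALSE)
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient (fraction of realised
#' links among each node's neighbours); nodes of degree < 2 contribute 0.
#'
#' @param net An igraph graph.
#' @return A number in \[0, 1\].
#' @export
average_clustering <- function(net) {
  g <- as_simple_undirected(net)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Deterministic ring lattice with a given edge count
#'
#' Builds the regular-lattice reference for the omega metric: `n` nodes on a
#' ring, connected to nearest neighbours ring-wise (offset 1 for all nodes,
#' then offset 2, ...) until exactly `e` edges are placed.
#'
#' @param n Number of nodes.
#' @param e Number of edges, at most `n*(n-1)/2`.
#' @return An undirected igraph graph.
#' @export
ring_lattice <- function(n, e) {
  stopifnot(n >= 2, e >= 0, e <= n * (n - 1) / 2)
  from <- integer(0); to <- integer(0)
  placed <- 0L
  offset <- 1L
  while (placed < e) {
    i <- seq_len(n)
    j <- ((i - 1L + offset) %% n) + 1L
    # at offset n/2 (even n) each chord appears twice; keep the first half
    if (2L * offset == n) { i <- i[seq_len(n %/% 2L)]; j <- j[seq_len(n %/% 2L)] }
    take <- min(length(i), e - placed)
    from <- c(from, i[seq_len(take)])
    to <- c(to, j[seq_len(take)])
    placed <- placed + take
    offset <- offset + 1L
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (e > 0) g <- igraph::add_edges(g, rbind(from, to))
  g
}

#' Reference graph statistics for small-world metrics
#'
#' Computes the random-reference means `c_r`, `l_r` over `reps` Erdos-Renyi
#' G(N, E) samples, and the lattice reference clustering `c_l` from the
#' deterministic [ring_lattice()]. When an ER sample is disconnected, its
#' path length is taken over the largest component and the result is
#' flagged.
#'
#' @param n,e Node and edge counts matched to the observed graph.
#' @param reps Number of ER replicates (default 20).
#' @param seed Optional RNG seed.
#' @return A one-row tibble: `c_r`, `l_r`, `c_l`, `n`, `e`, `reps`,
#'   `disconnected_reps`.
#' @export
reference_graphs <- function(n, e, reps = 20, seed = NULL) {
  stopifnot(n >= 2, e >= 1, e <= n * (n - 1) / 2, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  cs <- numeric(reps); ls <- numeric(reps); disc <- 0L
  for (r in seq_len(reps)) {
    g <- igraph::sample_gnm(n, e, directed = FALSE)
    cs[r] <- average_clustering(g)
    if (!igraph::is_connected(g)) disc <- disc + 1L
    ls[r] <- average_path_length(g)
  }
  lat <- ring_lattice(n, e)
  tibble::tibble(c_r = mean(cs), l_r = mean(ls),
                 c_l = average_clustering(lat),
                 n = n, e = e, reps = reps, disconnected_reps = disc)
}

#' Small-world-ness ratio metric
#'
#' @param c_bar,l_bar Observed average clustering and path length.
#' @param c_r,l_r Random-reference means from [reference_graphs()].
#' @return `(c_bar/c_r) / (l_bar/l_r)`; NaN with a warning when `c_r` is 0.
#' @export
small_worldness_S <- function(c_bar, l_bar, c_r, l_r) {
  if (any(c(l_bar, l_r) <= 0)) stop("path lengths must be positive", call. = FALSE)
  if (c_r == 0) {
    warning("random-reference clustering is 0; S_w undefined", call. = FALSE)
    return(NaN)
  }
  (c_bar / c_r) / (l_bar / l_r)
}

#' Small-world-ness omega metric
#'
#' @param c_bar,l_bar Observed average clustering and path length.
#' @param c_l Lattice-reference clustering.
#' @param l_r Random-reference path length.
#' @return `l_r/l_bar - c_bar/c_l`; NaN with a warning when `c_l` is 0.
#' @export
small_worldness_omega <- function(c_bar, l_bar, c_l, l_r) {
  if (l_bar <= 0) stop("`l_bar` must be positive", call. = FALSE)
  if (c_l == 0) {
    warning("lattice-reference clustering is 0; omega undefined", call. = FALSE)
    return(NaN)
  }
  l_r / l_bar - c_bar / c_l
}

#' Small-world report for a network
#'
#' Computes the observed metrics, the reference statistics, and both
#' small-world-ness metrics in one pass.
#'
#' @param net An igraph graph (any directedness; symmetrised internally).
#' @param reps ER reference replicates (default 20).
#' @param seed Optional RNG seed for the references.
#' @return An object of class `smallworld_report` with fields `n`, `e`,
#'   `mean_degree`, `l_bar`, `c_bar`, `c_r`, `l_r`, `c_l`, `s_w`, `omega`;
#'   [tidy()][generics::tidy] returns it as a one-row tibble.
#' @export
smallworld_report <- function(net, reps = 20, seed = NULL) {
  g <- as_simple_undirected(net)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n < 4 || e < 1) stop("graph too small for small-world metrics", call. = FALSE)
  l_bar <- average_path_length(g)
  c_bar <- average_clustering(g)
  ref <- reference_graphs(n, e, reps = reps, seed = seed)
  structure(
    list(
      n = n, e = e, mean_degree = 2 * e / n,
      l_bar = l_bar, c_bar = c_bar,
      c_r = ref$c_r, l_r = ref$l_r, c_l = ref$c_l,
      s_w = small_worldness_S(c_bar, l_bar, ref$c_r, ref$l_r),
      omega = small_worldness_omega(c_bar, l_bar, ref$c_l, ref$l_r),
      reps = reps, disconnected_reps = ref$disconnected_reps
    ),
    class = "smallworld_report"
  )
}

#' @export
print.smallworld_report <- function(x, ...) {
  cat(sprintf(
    "<smallworld_report> N=%d E=%d  L=%.3f C=%.3f  S_w=%.3f omega=%.3f\n",
    x$n, x$e, x$l_bar, x$c_bar, x$s_w, x$omega
  ))
  invisible(x)
}

#' @export
tidy.smallworld_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, e = x$e, mean_degree = x$mean_degree,
    l_bar = x$l_bar, c_bar = x$c_bar,
    c_r = x$c_r, l_r = x$l_r, c_l = x$c_l,
    s_w = x$s_w, omega = x$omega
  )
}

#' @export
glance.smallworld_report <- function(x, ...) tidy.smallworld_report(x)
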