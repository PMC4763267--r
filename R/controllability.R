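#' Bipartite representation of a directed graph
#'
#' Splits every node into an out-copy (left) and an in-copy (right); each
#' directed edge u -> v becomes the undirected bipartite edge (u_left,
#' v_right). A matching in this bipartite graph is exactly a set of directed
#' edges sharing no start vertex and no end vertex.
#'
#' @param digraph A directed igraph graph. Self-loops are kept by default.
#' @param include_self_loops Keep self-loops as bipartite edges
#'   (default TRUE): a node with a self-edge can match itself, as in
#'   structural-controllability analyses that retain self-dynamics.
#' @return A list: `n` (nodes), `edges` (2-column matrix of left/right
#'   indices), `names` (vertex names).
#' @export
to_bipartite <- function(digraph, include_self_loops = TRUE) {
  stopifnot(igraph::is_igraph(digraph), igraph::is_directed(digraph))
  el <- igraph::as_edgelist(digraph, names = FALSE)
  if (!include_self_loops && nrow(el) > 0) {
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
  }
  nm <- igraph::V(digraph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(digraph)))
  list(n = igraph::vcount(digraph), edges = el, names = nm)
}

#' Maximum bipartite matching by Hopcroft-Karp
#'
#' Standard Hopcroft-Karp: repeatedly finds a maximal set of shortest
#' augmenting paths by BFS layering plus DFS augmentation, in
#' O(E * sqrt(V)).
#'
#' @param bip A bipartite structure from [to_bipartite()], or a list with
#'   `n` and a 2-column `edges` matrix (left index, right index).
#' @return A list: `size` (matching cardinality), `match_left` and
#'   `match_right` (0 = unmatched, otherwise the partner's index).
#' @export
hopcroft_karp <- function(bip) {
  n <- bip$n
  edges <- bip$edges
  adj <- vector("list", n)
  if (!is.null(edges) && nrow(edges) > 0) {
    sp <- split(edges[, 2], factor(edges[, 1], levels = seq_len(n)))
    adj <- lapply(sp, function(v) unique(as.integer(v)))
  }
  match_l <- integer(n)  # left i -> right partner (0 = free)
  match_r <- integer(n)
  INF <- n + 1L

  bfs <- function() {
    dist <- rep(INF, n)
    queue <- which(match_l == 0L)
    dist[queue] <- 0L
    found <- FALSE
    head <- 1L
    queue <- as.integer(queue)
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1L
      for (v in adj[[u]]) {
        w <- match_r[v]
        if (w == 0L) {
          found <- TRUE
        } else if (dist[w] == INF) {
          dist[w] <- dist[u] + 1L
          queue <- c(queue, w)
        }
      }
    }
    list(found = found, dist = dist)
  }

  dist <- NULL
  dfs <- function(u) {
    for (v in adj[[u]]) {
      w <- match_r[v]
      if (w == 0L || (dist[w] == dist[u] + 1L && dfs(w))) {
        match_l[u] <<- v
        match_r[v] <<- u
        return(TRUE)
      }
    }
    dist[u] <<- INF
    FALSE
  }

  repeat {
    layer <- bfs()
    if (!layer$found) break
    dist <- layer$dist
    for (u in which(match_l == 0L)) {
      if (dist[u] == 0L) dfs(u)
    }
  }
  list(size = sum(match_l != 0L), match_left = match_l, match_right = match_r)
}

#' Minimum driver nodes for structural controllability
#'
#' The minimum number of external inputs needed to structurally control a
#' directed network equals N - M* where M* is the size of a maximum
#' matching of the digraph, floored at 1: a perfectly matched network (for
#' example a directed cycle) is controllable from a single node. The driver
#' set is the set of unmatched in-copies (nodes no matched edge points at);
#' with a perfect matching, the single lexicographically smallest node is
#' reported.
#'
#' @param digraph A directed igraph graph.
#' @param include_self_loops Passed to [to_bipartite()].
#' @return An object of class `control_report`: `n`, `m_star`, `n_drivers`,
#'   `drivers` (character vector of node names).
#' @export
min_driver_nodes <- function(digraph, include_self_loops = TRUE) {
  bip <- to_bipartite(digraph, include_self_loops = include_self_loops)
  if (bip$n < 1) stop("graph has no nodes", call. = FALSE)
  hk <- hopcroft_karp(bip)
  n_drivers <- max(bip$n - hk$size, 1L)
  unmatched <- which(hk$match_right == 0L)
  drivers <- if (length(unmatched) > 0) {
    sort(bip$names[unmatched])
  } else {
    sort(bip$names)[1]
  }
  structure(
    list(n = bip$n, m_star = hk$size, n_drivers = n_drivers,
         drivers = drivers),
    class = "control_report"
  )
}

#' @export
print.control_report <- function(x, ...) {
  cat(sprintf(
    "<control_report> N=%d, max matching M*=%d, driver nodes N_i=%d: %s\n",
    x$n, x$m_star, x$n_drivers,
    paste(utils::head(x$drivers, 8), collapse = ", ")
  ))
  invisible(x)
}

#' @export
glance.control_report <- function(x, ...) {
  tibble::tibble(n = x$n, m_star = x$m_star, n_drivers = x$n_drivers)
}

#' @export
tidy.control_report <- function(x, ...) {
  tibble::tibble(driver = x$drivers)
}
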