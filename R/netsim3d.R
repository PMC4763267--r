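#' Place neurons uniformly in a 3D cuboid
#'
#' The default cuboid, 780 x 320 x 100 micrometres, matches the extent of
#' tissue sampled by a 4-shank extracellular probe with ~200 um inter-shank
#' spacing and ~50 um recording-column radius.
#'
#' @param n Number of neurons (>= 2).
#' @param space Cuboid dimensions in micrometres, length 3.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `x`, `y`, `z` (micrometres).
#' @export
place_neurons <- function(n, space = c(780, 320, 100), seed = NULL) {
  stopifnot(n >= 2, length(space) == 3)
  if (any(space <= 0)) stop("cuboid dimensions must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    x = stats::runif(n, 0, space[1]),
    y = stats::runif(n, 0, space[2]),
    z = stats::runif(n, 0, space[3])
  )
}

pairwise_distances <- function(positions) {
  as.matrix(stats::dist(as.matrix(positions[, c("x", "y", "z")])))
}

new_spatial_network <- function(positions, space, graph, params, seed) {
  structure(
    list(positions = positions, space = space, graph = graph,
         params = params, seed = seed),
    class = "spatial_network"
  )
}

#' @export
print.spatial_network <- function(x, ...) {
  n <- igraph::vcount(x$graph)
  cat(sprintf(
    "<spatial_network> %s: %d neurons, %d edges (density %.4f) in %s um\n",
    x$params$model, n, igraph::ecount(x$graph),
    igraph::edge_density(x$graph), paste(x$space, collapse = " x ")
  ))
  invisible(x)
}

#' @export
glance.spatial_network <- function(x, ...) {
  tibble::tibble(
    model = x$params$model,
    n = igraph::vcount(x$graph),
    e = igraph::ecount(x$graph),
    density = igraph::edge_density(x$graph)
  )
}

# Bernoulli edge draw over unordered pairs given a per-pair probability
# vector aligned with the row order of stats::dist
draw_edges <- function(n, prob) {
  hit <- which(stats::runif(length(prob)) < prob)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(hit) > 0) {
    # invert the dist() linear index to (i, j), i < j
    idx <- hit
    j <- rep(seq_len(n - 1), times = (n - 1):1)
    # column (i) for each linear index of dist: pairs ordered (1,2),(1,3)...(1,n),(2,3)...
    i <- sequence((n - 1):1, from = 2:n) # row index j for each pair
    g <- igraph::add_edges(g, rbind(j[idx], i[idx]))
  }
  g
}

dist_vec <- function(positions) as.numeric(stats::dist(as.matrix(positions[, c("x", "y", "z")])))

#' Distance-threshold connectivity model
#'
#' Every unordered neuron pair closer than the threshold `l` is connected
#' with probability `p_in`; pairs farther apart connect with probability
#' `p_out`. With `p_in > p_out` this produces spatially clustered graphs
#' whose edge density is `p_out + (p_in - p_out) * F(l)`, where `F` is the
#' fraction of pairs within `l`.
#'
#' @param positions Neuron positions from [place_neurons()].
#' @param l Distance threshold (micrometres).
#' @param p_in,p_out Connection probabilities inside/outside the threshold;
#'   requires `0 <= p_out <= p_in <= 1`.
#' @param space Cuboid dimensions recorded in the result.
#' @param seed Optional RNG seed.
#' @return A `spatial_network` object.
#' @export
connect_threshold <- function(positions, l, p_in, p_out,
                              space = c(780, 320, 100), seed = NULL) {
  stopifnot(p_out >= 0, p_in <= 1, l > 0)
  if (p_out > p_in) stop("`p_in` must be >= `p_out`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(positions)
  d <- dist_vec(positions)
  prob <- ifelse(d <= l, p_in, p_out)
  g <- draw_edges(n, prob)
  new_spatial_network(positions, space, g,
                      list(model = "threshold", l = l, p_in = p_in, p_out = p_out),
                      seed)
}

#' Parametric distance-decay connection probability, model 1
#'
#' Geometric decay toward a floor:
#' \eqn{P(d) = P_0 + \alpha \lambda^{d / d_{unit}}}, clipped to \[0, 1\].
#' At zero distance the probability is \eqn{P_0 + \alpha} (with
#' \eqn{\alpha = 1} and \eqn{P_0 = 0} immediate neighbours are certainly
#' connected); as d grows it falls to the bias \eqn{P_0}. Larger `lambda`
#' yields more long-range connections; `alpha` sets the initial state.
#'
#' @param d Distance(s) in micrometres, >= 0.
#' @param alpha,lambda Shape parameters, both strictly inside (0, 1).
#' @param p0 Long-range bias probability (default 0).
#' @param d_unit Distance scale in micrometres (default 50, the
#'   recording-column radius).
#' @return Connection probabilities, same length as `d`.
#' @export
connection_prob_model1 <- function(d, alpha, lambda, p0 = 0, d_unit = 50) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (lambda <= 0 || lambda >= 1) stop("`lambda` must be in (0, 1)", call. = FALSE)
  if (any(d < 0)) stop("distances must be >= 0", call. = FALSE)
  pmin(pmax(p0 + alpha * lambda^(d / d_unit), 0), 1)
}

#' Parametric distance-decay connection probability, model 2
#'
#' Hyperbolic decay with a heavy tail:
#' \eqn{P(d) = P_1 + \gamma / (1 + \beta d / d_{unit})}, clipped to \[0, 1\].
#' The initial state at d = 0 is \eqn{P_1 + \gamma}; the probability decays
#' toward the asymptote \eqn{P_1} from above but, unlike model 1's
#' geometric decay, stays well above it at finite range, so long-range
#' connections are tolerated. Larger `beta` lowers the curve at every
#' positive distance.
#'
#' @param d Distance(s) in micrometres, >= 0.
#' @param beta,gamma Positive shape parameters.
#' @param p1 Long-range bias probability (default 0).
#' @param d_unit Distance scale in micrometres (default 50).
#' @return Connection probabilities, same length as `d`.
#' @export
connection_prob_model2 <- function(d, beta, gamma, p1 = 0, d_unit = 50) {
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (any(d < 0)) stop("distances must be >= 0", call. = FALSE)
  pmin(pmax(p1 + gamma / (1 + beta * d / d_unit), 0), 1)
}

#' Generate a spatial network from a parametric distance-decay model
#'
#' @param positions Neuron positions from [place_neurons()].
#' @inheritParams connection_prob_model1
#' @param space Cuboid dimensions recorded in the result.
#' @param seed Optional RNG seed.
#' @return A `spatial_network` object.
#' @export
connect_model1 <- function(positions, alpha, lambda, p0 = 0, d_unit = 50,
                           space = c(780, 320, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prob <- connection_prob_model1(dist_vec(positions), alpha, lambda, p0, d_unit)
  g <- draw_edges(nrow(positions), prob)
  new_spatial_network(positions, space, g,
                      list(model = "model1", alpha = alpha, lambda = lambda,
                           p0 = p0, d_unit = d_unit), seed)
}

#' @rdname connect_model1
#' @inheritParams connection_prob_model2
#' @export
connect_model2 <- function(positions, beta, gamma, p1 = 0, d_unit = 50,
                           space = c(780, 320, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prob <- connection_prob_model2(dist_vec(positions), beta, gamma, p1, d_unit)
  g <- draw_edges(nrow(positions), prob)
  new_spatial_network(positions, space, g,
                      list(model = "model2", beta = beta, gamma = gamma,
                           p1 = p1, d_unit = d_unit), seed)
}

#' Calibrate the distance threshold to a target edge density
#'
#' The expected density of the threshold model is
#' `p_out + (p_in - p_out) * F(l)` with `F` the empirical CDF of pairwise
#' distances, so the calibrated threshold is the distance quantile at
#' `(target - p_out) / (p_in - p_out)`.
#'
#' @param positions Neuron positions.
#' @param p_in,p_out Threshold-model probabilities.
#' @param target_density Desired expected edge density; must lie between
#'   `p_out` and `p_in`.
#' @return The threshold `l` in micrometres.
#' @export
calibrate_radius <- function(positions, p_in, p_out, target_density) {
  if (p_in <= p_out) stop("needs `p_in` > `p_out`", call. = FALSE)
  frac <- (target_density - p_out) / (p_in - p_out)
  if (frac <= 0 || frac >= 1) {
    stop("`target_density` must lie strictly between `p_out` and `p_in`",
         call. = FALSE)
  }
  as.numeric(stats::quantile(dist_vec(positions), probs = frac, type = 1))
}

#' Place virtual electrodes uniformly in the cuboid
#'
#' @param k Number of electrodes (default 6, the typical count across the
#'   recording sessions this workflow emulates).
#' @param space Cuboid dimensions in micrometres.
#' @param seed Optional RNG seed.
#' @return An object of class `electrode_array`: a tibble of positions with
#'   the space as an attribute.
#' @export
place_electrodes <- function(k = 6, space = c(780, 320, 100), seed = NULL) {
  stopifnot(k >= 1)
  pos <- place_neurons(max(k, 2), space, seed)[seq_len(k), ]
  structure(pos, space = space, class = c("electrode_array", class(pos)))
}

#' Sample the subnetwork visible to an electrode array
#'
#' A neuron is sampled when it lies within `radius` of at least one
#' electrode; the sampled network is the vertex-induced subgraph on the
#' sampled neurons (every edge between two sampled neurons is kept, nothing
#' else).
#'
#' @param snet A `spatial_network`.
#' @param electrodes An [place_electrodes()] array.
#' @param radius Sampling radius l' in micrometres.
#' @return A list: `graph` (induced subgraph), `ids` (sampled vertex
#'   indices), `n_sampled`.
#' @export
sample_network <- function(snet, electrodes, radius) {
  stopifnot(inherits(snet, "spatial_network"), radius > 0)
  pos <- as.matrix(snet$positions[, c("x", "y", "z")])
  epos <- as.matrix(electrodes[, c("x", "y", "z")])
  dmin <- electrode_distances(pos, epos)
  ids <- which(dmin <= radius)
  if (length(ids) == 0) {
    stop("no neurons within the sampling radius of any electrode", call. = FALSE)
  }
  list(graph = igraph::induced_subgraph(snet$graph, ids),
       ids = ids, n_sampled = length(ids))
}

electrode_distances <- function(pos, epos) {
  # min distance from each neuron to any electrode
  apply(epos, 1, function(e) sqrt(colSums((t(pos) - e)^2))) |>
    matrix(nrow = nrow(pos)) |>
    apply(1, min)
}

#' Sampling radius that captures a given number of neurons
#'
#' Chooses l' as the `n_target`-th smallest neuron-to-nearest-electrode
#' distance, so that exactly `n_target` neurons are sampled (deterministic
#' given positions and electrodes).
#'
#' @param snet A `spatial_network`.
#' @param electrodes An electrode array.
#' @param n_target Desired number of sampled neurons.
#' @return The radius in micrometres.
#' @export
calibrate_sampling_radius <- function(snet, electrodes, n_target) {
  pos <- as.matrix(snet$positions[, c("x", "y", "z")])
  epos <- as.matrix(electrodes[, c("x", "y", "z")])
  dmin <- sort(electrode_distances(pos, epos))
  n_target <- min(max(n_target, 1), length(dmin))
  dmin[n_target]
}
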