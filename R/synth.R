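#' Ground-truth network with Laguerre-expansible kernels
#'
#' Draws a random directed graph at the requested edge density and assigns
#' every edge a temporal kernel expressed in the same Laguerre basis the
#' estimator uses, so that end-to-end reconstruction is testable against a
#' known truth. Edge kernels are dominated by the first basis function,
#' with mostly positive (excitatory) leading coefficients; a minority are
#' negative (inhibitory). Baseline rates default to 5 Hz, comfortably above
#' the 0.5 Hz retention floor.
#'
#' @param n_neurons Number of neurons (>= 2).
#' @param edge_density Probability of each ordered pair (excluding
#'   self-pairs) carrying an edge, in \[0, 1\].
#' @param kernel_scale Magnitude of the leading Laguerre coefficient per
#'   edge (per-bin rate units; default 0.3).
#' @param baseline_hz Baseline firing rate per neuron (default 5 Hz).
#' @param bin_width Bin width in seconds (default 0.01).
#' @param duration Default simulated duration in seconds (default 100).
#' @param basis Laguerre basis shared by generator and estimator
#'   (default alpha 0.5, J = 3, M = 50).
#' @param excitatory_prob Probability that an edge's leading coefficient is
#'   positive (default 0.8).
#' @param seed Optional RNG seed.
#' @return An object of class `ground_truth`: `graph` (directed igraph),
#'   `coef` (N x N x J array, `coef[n, i, ]` = coefficients of input n in
#'   output i's kernel), `k0` (per-bin baseline probabilities), `basis`,
#'   `bin_width`, `duration`.
#' @export
make_ground_truth <- function(n_neurons, edge_density, kernel_scale = 0.3,
                              baseline_hz = 5, bin_width = 0.01,
                              duration = 100,
                              basis = laguerre_basis(0.5, 3, 50),
                              excitatory_prob = 0.8, seed = NULL) {
  stopifnot(n_neurons >= 2, edge_density >= 0, edge_density <= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_neurons))
  J <- basis$order
  co <- array(0, dim = c(n_neurons, n_neurons, J),
              dimnames = list(ids, ids, paste0("b", seq_len(J))))
  adj <- matrix(stats::runif(n_neurons^2) < edge_density,
                nrow = n_neurons)
  diag(adj) <- FALSE
  for (n in seq_len(n_neurons)) {
    for (i in seq_len(n_neurons)) {
      if (!adj[n, i]) next
      sgn <- if (stats::runif(1) < excitatory_prob) 1 else -1
      lead <- sgn * stats::runif(1, 0.5, 1) * kernel_scale
      rest <- stats::runif(J - 1, -0.2, 0.2) * kernel_scale
      co[n, i, ] <- c(lead, rest)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "directed")
  igraph::V(g)$name <- ids
  structure(
    list(graph = g, coef = co, k0 = rep(baseline_hz * bin_width, n_neurons),
         neuron_ids = ids, basis = basis, bin_width = bin_width,
         duration = duration),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d neurons, %d edges, baseline %.3g/bin, J=%d M=%d alpha=%g\n",
    length(x$neuron_ids), igraph::ecount(x$graph), x$k0[1],
    x$basis$order, x$basis$memory, x$basis$alpha
  ))
  invisible(x)
}

#' Simulate spike trains from a ground-truth model
#'
#' Generates binary spike trains bin by bin from the linear conditional
#' intensity the estimator assumes: the per-bin spike probability of neuron
#' i at bin t is the baseline plus the kernel-weighted sum of all neurons'
#' spikes over the preceding M bins, clipped to \[0, 1\]; the spike is a
#' Bernoulli draw. The history buffer starts empty. Spike times are
#' reported at bin centres.
#'
#' @param gt A [make_ground_truth()] object.
#' @param duration Simulated length in seconds (default `gt$duration`).
#' @param seed Optional RNG seed.
#' @param keep_rates Attach the unclipped per-bin rate matrix as attribute
#'   `"rates"` (default FALSE); used to check that generator and estimator
#'   share one kernel-evaluation path.
#' @return A [spike_trains()] object.
#' @export
simulate_spike_trains <- function(gt, duration = gt$duration, seed = NULL,
                                  keep_rates = FALSE) {
  stopifnot(inherits(gt, "ground_truth"), duration >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- length(gt$neuron_ids)
  M <- gt$basis$memory
  n_bins <- ceiling(duration / gt$bin_width)
  # outgoing kernels per source neuron: M x N increments added to the future
  # rate of every target when the source fires
  out_kernels <- lapply(seq_len(N), function(n) {
    crossprod(gt$basis$values, t(gt$coef[n, , , drop = TRUE]))  # M x N
  })
  rate <- matrix(rep(gt$k0, each = n_bins), nrow = n_bins)
  x <- matrix(0L, nrow = n_bins, ncol = N)
  clipped <- 0L
  for (t in seq_len(n_bins)) {
    p <- rate[t, ]
    nclip <- sum(p < 0 | p > 1)
    clipped <- clipped + nclip
    p <- pmin(pmax(p, 0), 1)
    sp <- which(stats::runif(N) < p)
    if (length(sp) > 0) {
      x[t, sp] <- 1L
      hor <- min(M, n_bins - t)
      if (hor > 0) {
        for (n in sp) {
          rate[t + seq_len(hor), ] <-
            rate[t + seq_len(hor), ] + out_kernels[[n]][seq_len(hor), ]
        }
      }
    }
  }
  if (clipped > 0.5 * n_bins * N) {
    warning("rate saturation: more than half of all bins were clipped",
            call. = FALSE)
  }
  spikes <- which(x == 1L, arr.ind = TRUE)
  events <- tibble::tibble(
    neuron_id = gt$neuron_ids[spikes[, 2]],
    time_s = (spikes[, 1] - 0.5) * gt$bin_width
  )
  sts <- spike_trains(events, duration = n_bins * gt$bin_width,
                      bin_width = gt$bin_width)
  # keep silent neurons out of the container but preserve id order
  sts$neuron_ids <- intersect(gt$neuron_ids, sts$neuron_ids)
  if (keep_rates) {
    colnames(rate) <- gt$neuron_ids
    attr(sts, "rates") <- rate
  }
  sts
}

#' End-to-end edge-recovery benchmark
#'
#' Simulates spike trains from a ground truth, runs the rate filter and the
#' full sparse-GLM reconstruction, and scores the recovered directed edge
#' set against the generator's graph.
#'
#' @param gt A [make_ground_truth()] object.
#' @param config An [analysis_config()]; the benchmark overrides its bin
#'   width, basis order and memory with the generator's to keep both ends
#'   on the same timescale.
#' @param duration Simulated duration in seconds.
#' @param seed Optional RNG seed.
#' @param return_fits Also return the fitted `glm_network` and the simulated
#'   trains (default FALSE).
#' @return A one-row tibble: `n_true`, `n_recovered`, `tp`, `precision`,
#'   `recall`, `f1`; with `return_fits = TRUE`, a list `(summary, fits,
#'   sts)`.
#' @export
reconstruction_benchmark <- function(gt, config = analysis_config(),
                                     duration = gt$duration, seed = NULL,
                                     return_fits = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  config$bin_width <- gt$bin_width
  config$basis_order <- gt$basis$order
  config$memory_bins <- gt$basis$memory
  sts <- simulate_spike_trains(gt, duration = duration, seed = seed)
  sts <- filter_by_rate(sts, config$rate_floor_hz)
  rec <- reconstruct_network(sts, config)
  true_edges <- apply(igraph::as_edgelist(gt$graph), 1, paste, collapse = "->")
  got_edges <- if (igraph::ecount(rec$network) > 0) {
    apply(igraph::as_edgelist(rec$network), 1, paste, collapse = "->")
  } else character(0)
  tp <- length(intersect(true_edges, got_edges))
  precision <- if (length(got_edges) > 0) tp / length(got_edges) else NA_real_
  recall <- if (length(true_edges) > 0) tp / length(true_edges) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  summary <- tibble::tibble(
    n_true = length(true_edges), n_recovered = length(got_edges),
    tp = tp, precision = precision, recall = recall, f1 = f1
  )
  if (return_fits) list(summary = summary, fits = rec, sts = sts) else summary
}
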