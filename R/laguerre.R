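#' Discrete-time Laguerre basis
#'
#' Constructs the first `order` discrete Laguerre functions over a memory of
#' `memory` time bins. The functions form an orthonormal family of
#' exponentially decaying sequences whose decay rate is set by the Laguerre
#' parameter `alpha`: the smaller `alpha`, the faster the basis (and hence any
#' kernel expanded in it) decays. Temporal kernels of a spiking GLM are
#' expressed as weighted sums of these functions, which reduces the number of
#' coefficients per input from `memory` to `order`.
#'
#' The basis is computed with the standard two-term recursion
#' \deqn{b_1(0) = \sqrt{1-\alpha},\quad b_1(\tau) = \sqrt{\alpha}\, b_1(\tau-1),}
#' \deqn{b_j(\tau) = \sqrt{\alpha}\, b_j(\tau-1) + \sqrt{\alpha}\, b_{j-1}(\tau) - b_{j-1}(\tau-1).}
#' Orthonormality holds over infinite lag; over a finite memory it holds to
#' high accuracy provided `alpha^memory` is negligible.
#'
#' @param alpha Laguerre decay parameter, strictly inside (0, 1).
#' @param order Number of basis functions J (>= 1).
#' @param memory Memory length M in bins (>= order).
#' @return An object of class `laguerre_basis`: a list with elements `alpha`,
#'   `order`, `memory` and `values`, a J x M matrix whose row j holds
#'   \eqn{b_j(\tau)} for \eqn{\tau = 0, \dots, M-1}.
#' @examples
#' b <- laguerre_basis(0.5, 4, 100)
#' tcrossprod(b$values) # ~ identity
#' @export
laguerre_basis <- function(alpha, order, memory) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number strictly inside (0, 1)", call. = FALSE)
  }
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  if (memory < order) stop("`memory` must be >= `order`", call. = FALSE)
  sa <- sqrt(alpha)
  B <- matrix(0, nrow = order, ncol = memory)
  B[1, 1] <- sqrt(1 - alpha)
  if (memory > 1) for (t in 2:memory) B[1, t] <- sa * B[1, t - 1]
  if (order > 1) {
    for (j in 2:order) {
      B[j, 1] <- sa * B[j - 1, 1]
      if (memory > 1) {
        for (t in 2:memory) {
          B[j, t] <- sa * B[j, t - 1] + sa * B[j - 1, t] - B[j - 1, t - 1]
        }
      }
    }
  }
  structure(
    list(alpha = alpha, order = order, memory = memory, values = B),
    class = "laguerre_basis"
  )
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat(sprintf(
    "<laguerre_basis> alpha = %g, order J = %d, memory M = %d bins\n",
    x$alpha, x$order, x$memory
  ))
  invisible(x)
}

#' Convolve binned spike trains with a Laguerre basis
#'
#' Computes the regressors \eqn{v_j^{(n)}(t) = \sum_{\tau=0}^{M-1}
#' b_j(\tau)\, x_n(t - lag - \tau)} for every input train n and basis order j,
#' with \eqn{x_n(t) = 0} for t before the recording starts. With `lag = 0`
#' this is the plain causal convolution of each input with each basis
#' function; a GLM design uses `lag = 1` so that regressors only see strictly
#' past bins.
#'
#' @param x Binned spike trains: a neurons x bins 0/1 matrix (e.g. from
#'   [bin_spikes()]), or a `spike_trains` object.
#' @param basis A [laguerre_basis()].
#' @param lag Extra shift in bins applied to every input (default 0).
#' @return A bins x (N*J) numeric matrix. Columns are ordered input-major:
#'   all J orders of input 1, then input 2, ... Column names are
#'   `<input>.b<j>`.
#' @export
convolve_inputs <- function(x, basis, lag = 0) {
  if (inherits(x, "spike_trains")) x <- bin_spikes(x)
  stopifnot(inherits(basis, "laguerre_basis"), lag >= 0)
  n_bins <- ncol(x)
  if (basis$memory > n_bins) {
    stop("basis memory exceeds the number of time bins", call. = FALSE)
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(x)))
  M <- basis$memory
  out <- matrix(0, nrow = n_bins, ncol = nrow(x) * basis$order)
  cn <- character(ncol(out))
  col <- 0L
  for (n in seq_len(nrow(x))) {
    xp <- c(rep(0, M - 1), as.numeric(x[n, ]))
    for (j in seq_len(basis$order)) {
      v <- stats::filter(xp, basis$values[j, ], method = "convolution", sides = 1)
      v <- as.numeric(v)[M:(M + n_bins - 1)]
      if (lag > 0) v <- c(rep(0, lag), v[seq_len(n_bins - lag)])
      col <- col + 1L
      out[, col] <- v
      cn[col] <- paste0(ids[n], ".b", j)
    }
  }
  colnames(out) <- cn
  attr(out, "inputs") <- ids
  attr(out, "order") <- basis$order
  out
}
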