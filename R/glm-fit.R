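#' Laguerre design matrix for one recording
#'
#' Convolves every neuron's binned train with the basis and shifts the result
#' one bin into the past, so that the regressors for bin t only involve bins
#' strictly before t. The output neuron's own history therefore enters the
#' design like any other input (autoregressive term) without leaking the
#' target bin.
#'
#' @param sts A [spike_trains()] object.
#' @param basis A [laguerre_basis()].
#' @return A list with `design` (bins x N*J matrix), `inputs` (neuron ids in
#'   column-group order) and `order` (J).
#' @export
glm_design <- function(sts, basis) {
  x <- bin_spikes(sts)
  design <- convolve_inputs(x, basis, lag = 1)
  list(design = design, inputs = attr(design, "inputs"), order = basis$order)
}

#' Fit an L1-penalised Gaussian GLM for one output neuron
#'
#' Penalised least squares on the binary binned target: minimises the sum of
#' squared errors subject to an L1 constraint on the coefficients. The
#' penalty weight is chosen from `zeta_grid` by K-fold cross-validated
#' deviance (residual sum of squares for the Gaussian family); folds are
#' contiguous time blocks to respect the serial dependence of spike trains,
#' and ties are broken toward the larger penalty (the sparser model). The
#' numerical path is computed by glmnet.
#'
#' @param design Regressor matrix (bins x N*J), e.g. from [glm_design()].
#' @param target 0/1 vector, the output neuron's binned train.
#' @param zeta_grid Candidate L1 penalties; default 20 points log-spaced over
#'   `[1e-5, 1e-1]`.
#' @param folds Number of contiguous cross-validation blocks (default 5).
#' @param inputs Optional character vector of input neuron ids (length N);
#'   taken from the design's attributes when present.
#' @param order Basis order J used to group columns by input.
#' @param output Optional id of the output neuron; its own input group never
#'   produces a graph edge.
#' @param basis Optional [laguerre_basis()] stored for kernel reconstruction.
#' @return An object of class `spike_glm`: intercept `k0`, an N x J
#'   coefficient matrix `coefficients` (rows named by input), the selected
#'   `zeta`, the per-penalty CV curve `cv` (tibble `zeta`, `deviance`), and
#'   the basis.
#' @export
fit_sparse_glm <- function(design, target,
                           zeta_grid = default_zeta_grid(),
                           folds = 5,
                           inputs = attr(design, "inputs"),
                           order = attr(design, "order"),
                           output = NULL,
                           basis = NULL) {
  stopifnot(nrow(design) == length(target), folds >= 2)
  zeta_grid <- sort(unique(zeta_grid), decreasing = TRUE)
  n <- length(target)
  if (is.null(order)) order <- 1L
  if (is.null(inputs)) inputs <- paste0("n", seq_len(ncol(design) / order))
  cv_tbl <- tibble::tibble(zeta = zeta_grid, deviance = NA_real_)

  degenerate <- all(matrixStats_colVars(design) < .Machine$double.eps)
  if (degenerate || stats::var(target) == 0) {
    warning("degenerate design or constant target; returning all-zero coefficients",
            call. = FALSE)
    co <- matrix(0, nrow = length(inputs), ncol = order,
                 dimnames = list(inputs, paste0("b", seq_len(order))))
    cv_tbl$deviance <- stats::var(target) * (n - 1) / n
    m <- new_spike_glm(mean(target), co, zeta_grid[1], cv_tbl, basis, output)
    m$coef_pvals <- matrix(1, nrow = length(inputs), ncol = order,
                           dimnames = dimnames(co))
    return(m)
  }

  foldid <- rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]
  cvfit <- glmnet::cv.glmnet(
    design, target,
    family = "gaussian", lambda = zeta_grid, foldid = foldid,
    standardize = FALSE, type.measure = "mse"
  )
  # glmnet may drop trailing lambdas; align on those actually fitted
  fitted_z <- cvfit$lambda
  cv_tbl <- tibble::tibble(zeta = fitted_z, deviance = cvfit$cvm)
  best <- which.min(cv_tbl$deviance)  # first index = largest zeta among ties
  zeta <- cv_tbl$zeta[best]
  beta <- as.numeric(stats::coef(cvfit$glmnet.fit, s = zeta, exact = FALSE))
  k0 <- beta[1]
  co <- matrix(beta[-1], nrow = length(inputs), ncol = order, byrow = TRUE,
               dimnames = list(inputs, paste0("b", seq_len(order))))
  m <- new_spike_glm(k0, co, zeta, cv_tbl, basis, output)
  m$coef_pvals <- support_pvalues(design, target, which(beta[-1] != 0),
                                  length(inputs), order, inputs)
  m
}

# Debiased post-selection p-values: ordinary least squares on the columns the
# lasso retained, two-sided t-test per coefficient. Columns outside the
# support get p = 1. Used by the "significant" edge criterion.
support_pvalues <- function(design, target, support, n_inputs, order, inputs) {
  p <- matrix(1, nrow = n_inputs, ncol = order,
              dimnames = list(inputs, paste0("b", seq_len(order))))
  if (length(support) == 0) return(p)
  X <- cbind(1, design[, support, drop = FALSE])
  fit <- stats::lm.fit(X, target)
  keep <- !is.na(fit$coefficients)
  df <- length(target) - sum(keep)
  if (df <= 0) return(p)
  sigma2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)[keep, keep, drop = FALSE]
  XtXinv <- chol2inv(R)
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- fit$coefficients[keep] / se
  pv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  pv <- pv[-1]                       # drop intercept
  sup_kept <- support[keep[-1]]
  # design columns are input-major: column c is input (c-1) %/% J + 1, order
  # (c-1) %% J + 1
  row <- (sup_kept - 1L) %/% order + 1L
  colj <- (sup_kept - 1L) %% order + 1L
  p[cbind(row, colj)] <- pv
  p
}

new_spike_glm <- function(k0, coefficients, zeta, cv, basis, output) {
  structure(
    list(k0 = k0, coefficients = coefficients, zeta = zeta, cv = cv,
         basis = basis, output = output),
    class = "spike_glm"
  )
}

# column variances without an extra dependency
matrixStats_colVars <- function(m) {
  mu <- colMeans(m)
  colMeans(m^2) - mu^2
}

#' Default L1 penalty grid
#'
#' Twenty points log-spaced over `[1e-5, 1e-1]`.
#' @return Numeric vector of penalties.
#' @export
default_zeta_grid <- function() 10^seq(-5, -1, length.out = 20)

#' @export
print.spike_glm <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "<spike_glm>%s k0 = %.4g, zeta = %.3g, %d/%d nonzero coefficients\n",
    if (!is.null(x$output)) paste0(" output ", x$output, ";") else "",
    x$k0, x$zeta, nz, length(x$coefficients)
  ))
  invisible(x)
}

#' @export
tidy.spike_glm <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    input = rep(rownames(co), times = ncol(co)),
    order = rep(seq_len(ncol(co)), each = nrow(co)),
    estimate = as.vector(co)
  )
}

#' @export
glance.spike_glm <- function(x, ...) {
  tibble::tibble(
    output = x$output %||% NA_character_,
    k0 = x$k0,
    zeta = x$zeta,
    n_nonzero = sum(x$coefficients != 0),
    cv_deviance = min(x$cv$deviance, na.rm = TRUE)
  )
}

#' Reconstruct temporal kernels from fitted Laguerre coefficients
#'
#' Each input's kernel is the coefficient-weighted sum of the basis
#' functions, \eqn{k^{(n)}(\tau) = \sum_j c_j^{(n)} b_j(\tau)}.
#'
#' @param model A fitted [fit_sparse_glm()] model carrying a basis.
#' @return An N x M matrix of kernels, rows named by input neuron.
#' @export
reconstruct_kernels <- function(model) {
  stopifnot(inherits(model, "spike_glm"))
  if (is.null(model$basis)) stop("model carries no basis", call. = FALSE)
  model$coefficients %*% model$basis$values
}

#' Predicted conditional intensity of a fitted model
#'
#' @param model A `spike_glm`.
#' @param design The regressor matrix the model was (or would be) fitted on.
#' @return Numeric vector of per-bin predicted intensities (probability of a
#'   spike per bin under the Gaussian/identity reading; may exceed \[0, 1\]
#'   and is clipped only where downstream methods require it).
#' @export
predict_intensity <- function(model, design) {
  stopifnot(inherits(model, "spike_glm"))
  as.numeric(model$k0 + design %*% as.vector(t(model$coefficients)))
}

#' Directed functional network from per-neuron GLMs
#'
#' Draws the edge n -> i when input n's coefficient group in output i's
#' model is selected as significant. Under the default `"significant"`
#' criterion a group qualifies when at least one of its lasso-retained
#' coefficients is significant in the debiased least-squares refit on the
#' selected support, at level `alpha` with a Bonferroni correction over all
#' candidate coefficients of that model; this screens out the handful of
#' noise coefficients that cross-validated penalty selection typically
#' admits. The `"nonzero"` criterion draws an edge for any nonzero
#' coefficient. Self-history terms never become edges, and nodes left
#' without any edge are removed.
#'
#' @param models A named list of `spike_glm` fits, one per output neuron;
#'   names (or the models' `output` fields) give the output ids.
#' @param edge_criterion `"significant"` (default) or `"nonzero"`.
#' @param alpha Family-wise significance level for the default criterion
#'   (default 0.05).
#' @param keep_isolates Keep nodes with no edges (default FALSE).
#' @return A directed igraph graph with vertex names.
#' @export
build_functional_network <- function(models,
                                     edge_criterion = c("significant", "nonzero"),
                                     alpha = 0.05,
                                     keep_isolates = FALSE) {
  edge_criterion <- match.arg(edge_criterion)
  outs <- names(models)
  if (is.null(outs)) outs <- vapply(models, function(m) m$output %||% "", "")
  if (any(!nzchar(outs))) stop("models must be named by output neuron", call. = FALSE)
  edges <- purrr::map2_dfr(models, outs, function(m, out) {
    co <- m$coefficients
    sel <- rowSums(co != 0) > 0
    if (edge_criterion == "significant" && !is.null(m$coef_pvals)) {
      # Bonferroni over every candidate coefficient of the whole network:
      # the reconstructed graph is one family of hypotheses
      cut <- alpha / (length(co) * length(models))
      sel <- sel & (apply(m$coef_pvals, 1, min) < cut)
    }
    from <- rownames(co)[sel]
    from <- setdiff(from, out)
    if (length(from) == 0) return(tibble::tibble(from = character(), to = character()))
    tibble::tibble(from = from, to = out)
  })
  nodes <- unique(c(outs, unlist(lapply(models, function(m) rownames(m$coefficients)))))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!keep_isolates) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g, mode = "all") == 0))
  }
  g
}

#' Reconstruct a functional network from spike trains
#'
#' Runs the full estimation loop: for every retained neuron, fit the
#' L1-penalised Laguerre GLM with the output's spikes as target and all
#' neurons' (strictly past) spikes as inputs, choosing the Laguerre decay
#' `alpha` and the penalty `zeta` jointly by cross-validated deviance; then
#' assemble the directed graph of nonzero input groups.
#'
#' @param sts A [spike_trains()] object (already rate-filtered, or pass
#'   `rate_floor_hz` to filter here).
#' @param config An [analysis_config()]; its `alpha_grid`, `zeta_grid`,
#'   `basis_order`, `memory_bins` and `cv_folds` drive the fit.
#' @param rate_floor_hz If not `NULL`, apply [filter_by_rate()] first.
#' @return A list of class `glm_network`: `models` (named list of
#'   `spike_glm`), `network` (directed igraph), `config`.
#' @export
reconstruct_network <- function(sts, config = analysis_config(),
                                rate_floor_hz = NULL) {
  stopifnot(inherits(sts, "spike_trains"))
  if (!is.null(rate_floor_hz)) sts <- filter_by_rate(sts, rate_floor_hz)
  x <- bin_spikes(sts, bin_width = config$bin_width)
  designs <- lapply(config$alpha_grid, function(a) {
    b <- laguerre_basis(a, config$basis_order, config$memory_bins)
    list(basis = b, design = convolve_inputs(x, b, lag = 1))
  })
  ids <- rownames(x)
  models <- lapply(ids, function(id) {
    target <- as.numeric(x[id, ])
    fits <- lapply(designs, function(d) {
      fit_sparse_glm(d$design, target,
                     zeta_grid = config$zeta_grid, folds = config$cv_folds,
                     output = id, basis = d$basis)
    })
    dev <- vapply(fits, function(f) min(f$cv$deviance, na.rm = TRUE), 0)
    fits[[which.min(dev)]]
  })
  names(models) <- ids
  structure(
    list(models = models,
         network = build_functional_network(models),
         config = config),
    class = "glm_network"
  )
}

#' @export
print.glm_network <- function(x, ...) {
  cat(sprintf(
    "<glm_network> %d models; network: %d nodes, %d directed edges\n",
    length(x$models), igraph::vcount(x$network), igraph::ecount(x$network)
  ))
  invisible(x)
}

#' @export
tidy.glm_network <- function(x, ...) {
  purrr::map_dfr(x$models, glance.spike_glm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
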