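#' Percentage error of sampled small-world-ness
#'
#' Relative deviation of the original network's omega metric from the
#' sampled network's: \eqn{\sigma = (\omega_{ON} - \omega_{SN}) /
#' \omega_{SN}}. Positive sigma means the subsampled graph understates omega
#' (i.e. overstates small-world-ness).
#'
#' @param omega_on,omega_sn Omega of the original and sampled networks.
#' @return The percentage error (as a fraction, not percent); NaN with a
#'   warning when `omega_sn` is 0.
#' @export
percentage_error <- function(omega_on, omega_sn) {
  if (any(omega_sn == 0)) {
    warning("`omega_sn` is 0; percentage error undefined", call. = FALSE)
  }
  out <- (omega_on - omega_sn) / omega_sn
  out[omega_sn == 0] <- NaN
  out
}

#' Two-term exponential error curve
#'
#' Evaluates \eqn{\sigma(N) = a e^{bN} + c e^{dN}}, the model of how the
#' relative error of sampled small-world-ness shrinks with the number of
#' sampled neurons.
#'
#' @param n Number(s) of sampled neurons.
#' @param fit An `error_curve_fit` (or anything with elements a, b, c, d).
#' @return sigma(n), same length as `n`.
#' @export
sigma_curve <- function(n, fit = error_curve_reference()) {
  fit$a * exp(fit$b * n) + fit$c * exp(fit$d * n)
}

#' Construct an error-curve fit object
#'
#' @param a,b,c,d Coefficients of `a*exp(b*N) + c*exp(d*N)`.
#' @param rmse,r_squared Optional fit diagnostics.
#' @param edge_density Edge density of the simulations behind the fit.
#' @param sizes,reps Simulation sizes and repetitions behind the fit.
#' @return An object of class `error_curve_fit`.
#' @export
error_curve_fit <- function(a, b, c, d, rmse = NA_real_, r_squared = NA_real_,
                            edge_density = NA_real_, sizes = NULL, reps = NA) {
  structure(
    list(a = a, b = b, c = c, d = d, rmse = rmse, r_squared = r_squared,
         edge_density = edge_density, sizes = sizes, reps = reps),
    class = "error_curve_fit"
  )
}

#' Reference error-curve coefficients
#'
#' The published reference coefficients for the sampling-bias curve of the
#' omega metric in electrode-subsampled distance-dependent networks at
#' ~8.3% edge density: a = 1.564, b = -0.080, c = 0.279, d = -0.006
#' (reported RMSE 0.060, R-squared 0.8494).
#'
#' @return An [error_curve_fit()].
#' @export
error_curve_reference <- function() {
  error_curve_fit(1.564, -0.080, 0.279, -0.006,
                  rmse = 0.060, r_squared = 0.8494, edge_density = 0.0832)
}

#' @export
print.error_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<error_curve_fit> sigma(N) = %.4g*exp(%.4g*N) + %.4g*exp(%.4g*N)  (RMSE %.3g, R2 %.3g)\n",
    x$a, x$b, x$c, x$d, x$rmse, x$r_squared
  ))
  invisible(x)
}

#' @export
tidy.error_curve_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "d"),
                 estimate = c(x$a, x$b, x$c, x$d))
}

#' @export
glance.error_curve_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, d = x$d,
                 rmse = x$rmse, r_squared = x$r_squared,
                 edge_density = x$edge_density)
}

#' Simulate the sampling-error curve
#'
#' For every combination of network size, sampling fraction and repetition:
#' build a distance-threshold network, compute its omega, subsample it with
#' a virtual electrode array whose radius is calibrated to capture the
#' requested fraction of neurons, compute the sampled omega, and record the
#' percentage error. Points whose sampled graph is too small for the
#' metrics (< 4 nodes) or whose sampled omega is 0 are skipped with a
#' message.
#'
#' @param sizes Network sizes (default the study sizes 500..2500).
#' @param p_in,p_out Threshold-model probabilities (defaults 0.25/0.05, the
#'   ~8.3%-density operating point).
#' @param sample_fractions Fractions of neurons to sample.
#' @param reps Repetitions per (size, fraction) cell.
#' @param n_electrodes Electrodes per repetition (default 6).
#' @param target_density Edge density the threshold is calibrated to; the
#'   default 0.0832 corresponds to p_in 0.25 / p_out 0.05.
#' @param space Cuboid dimensions in micrometres.
#' @param reference_reps ER replicates inside each omega evaluation.
#' @param seed RNG seed.
#' @return A tibble with columns `size`, `fraction`, `rep`, `n_sampled`,
#'   `omega_on`, `omega_sn`, `sigma`.
#' @export
simulate_error_curve <- function(sizes = c(500, 1000, 1500, 2000, 2500),
                                 p_in = 0.25, p_out = 0.05,
                                 sample_fractions = seq(0.05, 0.5, by = 0.05),
                                 reps = 10, n_electrodes = 6,
                                 target_density = 0.0832,
                                 space = c(780, 320, 100),
                                 reference_reps = 20,
                                 seed = NULL) {
  stopifnot(all(sizes >= 50), all(sample_fractions > 0), all(sample_fractions <= 1))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (size in sizes) {
    for (rep_i in seq_len(reps)) {
      pos <- place_neurons(size, space)
      l <- calibrate_radius(pos, p_in, p_out, target_density)
      snet <- connect_threshold(pos, l, p_in, p_out, space = space)
      # one reference seed shared by the original and every sampled report,
      # so that a full sample yields sigma = 0 exactly
      ref_seed <- sample.int(.Machine$integer.max, 1)
      rep_on <- smallworld_report(snet$graph, reps = reference_reps,
                                  seed = ref_seed)
      electrodes <- place_electrodes(n_electrodes, space)
      for (frac in sample_fractions) {
        n_target <- max(round(size * frac), 1)
        radius <- calibrate_sampling_radius(snet, electrodes, n_target)
        sub <- sample_network(snet, electrodes, radius)
        if (sub$n_sampled < 4 || igraph::ecount(sub$graph) < 1) {
          message(sprintf("skipping size %d frac %.2f rep %d: sampled graph too small",
                          size, frac, rep_i))
          next
        }
        rep_sn <- tryCatch(smallworld_report(sub$graph, reps = reference_reps,
                                             seed = ref_seed),
                           error = function(e) NULL)
        if (is.null(rep_sn) || !is.finite(rep_sn$omega) || rep_sn$omega == 0) {
          message(sprintf("skipping size %d frac %.2f rep %d: omega undefined",
                          size, frac, rep_i))
          next
        }
        out[[length(out) + 1]] <- tibble::tibble(
          size = size, fraction = frac, rep = rep_i,
          n_sampled = sub$n_sampled,
          omega_on = rep_on$omega, omega_sn = rep_sn$omega,
          sigma = percentage_error(rep_on$omega, rep_sn$omega)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Fit the two-term exponential error curve
#'
#' Nonlinear least squares of `sigma ~ a*exp(b*n) + c*exp(d*n)` on a
#' simulated error scatter, with the decay rates constrained negative and
#' multi-start initialisation (a base start near the reference coefficients
#' plus randomly perturbed restarts) to avoid poor local minima.
#'
#' @param scatter A data frame with columns `n_sampled` and `sigma`, e.g.
#'   from [simulate_error_curve()].
#' @param starts Number of starts (default 10).
#' @param seed Optional RNG seed for the perturbed starts.
#' @return An [error_curve_fit()] with `rmse` (residual standard error) and
#'   `r_squared` filled in.
#' @export
fit_two_term_exponential <- function(scatter, starts = 10, seed = NULL) {
  stopifnot(all(c("n_sampled", "sigma") %in% names(scatter)))
  scatter <- scatter[is.finite(scatter$sigma), , drop = FALSE]
  if (nrow(scatter) < 8 || length(unique(scatter$n_sampled)) < 3) {
    stop("need >= 8 points spanning >= 3 distinct sampled sizes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  base <- c(a = 1.5, b = -0.1, c = 0.3, d = -0.01)
  starts_list <- c(list(base), lapply(seq_len(starts - 1), function(i) {
    base * exp(stats::rnorm(4, sd = 0.5))
  }))
  best <- NULL
  for (st in starts_list) {
    st[c("b", "d")] <- pmin(st[c("b", "d")], -1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        sigma ~ a * exp(b * n_sampled) + c * exp(d * n_sampled),
        data = scatter, start = as.list(st),
        lower = c(a = -Inf, b = -Inf, c = -Inf, d = -Inf),
        upper = c(a = Inf, b = 0, c = Inf, d = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("two-term exponential fit failed to converge from all starts",
         call. = FALSE)
  }
  co <- stats::coef(best$fit)
  nobs <- nrow(scatter)
  tss <- sum((scatter$sigma - mean(scatter$sigma))^2)
  error_curve_fit(
    co[["a"]], co[["b"]], co[["c"]], co[["d"]],
    rmse = sqrt(best$rss / max(nobs - 4, 1)),
    r_squared = 1 - best$rss / tss
  )
}

#' Adjust sampled small-world-ness for subsampling bias
#'
#' Inverts the percentage-error relation: the estimated original-network
#' omega is \eqn{\hat\omega_{ON} = \omega_{SN} (1 + \sigma(N))} with sigma
#' evaluated from an error-curve fit at the number of sampled neurons. A
#' sampled omega of exactly 0 is returned unchanged. A negative sampled
#' omega is adjusted on its magnitude with the sign preserved, and flagged
#' with a warning, since the error curve was characterised on positive
#' omega.
#'
#' @param omega_sn Sampled-network omega.
#' @param n_sampled Number of sampled neurons (>= 1).
#' @param fit An [error_curve_fit()]; defaults to [error_curve_reference()].
#' @return The adjusted omega estimate.
#' @export
adjust_smallworldness <- function(omega_sn, n_sampled,
                                  fit = error_curve_reference()) {
  stopifnot(all(n_sampled >= 1))
  s <- sigma_curve(n_sampled, fit)
  out <- ifelse(omega_sn == 0, 0,
                sign(omega_sn) * abs(omega_sn) * (1 + s))
  if (any(omega_sn < 0)) {
    warning("negative sampled omega adjusted on magnitude with sign preserved",
            call. = FALSE)
  }
  out
}

#' Adjustment interval across an edge-density sweep
#'
#' Applies [adjust_smallworldness()] under each of several error-curve fits
#' (typically fitted at different edge densities, e.g. the 5.8%-23% range
#' of cortical connectivity estimates) and returns the interval spanned.
#'
#' @param omega_sn Sampled-network omega.
#' @param n_sampled Number of sampled neurons.
#' @param fits A list of [error_curve_fit()] objects.
#' @return A length-2 numeric vector `c(low, high)`.
#' @export
adjust_range <- function(omega_sn, n_sampled, fits) {
  stopifnot(length(fits) >= 1)
  vals <- vapply(fits, function(f) {
    adjust_smallworldness(omega_sn, n_sampled, f)
  }, 0)
  range(vals)
}

#' Estimate neuron count and edge density of a tissue volume
#'
#' Converts volumetric neuron and synapse densities into the expected
#' number of neurons in a cuboid of recorded tissue and the expected edge
#' density (synapses per neuron divided by the number of potential
#' partners).
#'
#' @param neuron_density Neurons per cubic millimetre (default 9.2e4, the
#'   brain-average estimate).
#' @param synapse_density Synapses per cubic millimetre (default 7.2e8).
#' @param dims Cuboid dimensions in micrometres (default 780 x 320 x 100).
#' @return A one-row tibble: `n_neurons`, `edge_density`, `volume_mm3`.
#' @export
estimate_tissue_network <- function(neuron_density = 9.2e4,
                                    synapse_density = 7.2e8,
                                    dims = c(780, 320, 100)) {
  stopifnot(neuron_density > 0, synapse_density > 0, all(dims > 0))
  vol <- prod(dims) / 1e9  # um^3 -> mm^3
  tibble::tibble(
    n_neurons = neuron_density * vol,
    edge_density = (synapse_density / neuron_density) / neuron_density,
    volume_mm3 = vol
  )
}
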