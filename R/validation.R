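#' Time-rescale spike times under a fitted conditional intensity
#'
#' Applies the time-rescaling theorem: if `intensity` is the true conditional
#' intensity of the point process, the integrated intensity between
#' consecutive spikes is a unit-rate exponential sample, and
#' \eqn{z_k = 1 - \exp(-\Delta\Lambda_k)} is uniform on (0, 1). Deviations
#' from uniformity flag model misfit and are assessed with [ks_band_test()].
#'
#' Two integration schemes are available. The default (`discrete = FALSE`)
#' integrates the piecewise-constant intensity exactly between the (possibly
#' off-grid) spike times, which is the natural choice when spike times are
#' continuous. With `discrete = TRUE` the train is treated as a binary
#' sequence of per-bin Bernoulli events: each bin contributes the discrete
#' hazard \eqn{-\log(1 - \lambda(t)\Delta)} and the spike bin's contribution
#' is drawn uniformly within its atom, which makes the rescaled values
#' exactly uniform for binned data and avoids the discreteness bias of the
#' rectangle rule at higher per-bin probabilities. The discrete scheme uses
#' the RNG; fix a seed for reproducibility.
#'
#' Negative predicted intensities (possible under the Gaussian/identity
#' link) are clipped at `eps` before integration.
#'
#' @param spike_times Spike times in seconds, sorted ascending.
#' @param intensity Per-bin predicted intensity in events/second (vector over
#'   the recording's bins).
#' @param bin_width Bin width in seconds of `intensity`.
#' @param discrete Use the discrete-hazard scheme for binned trains
#'   (default FALSE).
#' @param eps Positivity floor applied to the intensity (default 1e-8).
#' @return Numeric vector of rescaled values `z`, one per interspike
#'   interval (in spike order, not sorted).
#' @export
time_rescale <- function(spike_times, intensity, bin_width,
                         discrete = FALSE, eps = 1e-8) {
  if (length(spike_times) < 2) {
    stop("need at least 2 spikes to rescale intervals", call. = FALSE)
  }
  if (is.unsorted(spike_times)) stop("spike times must be sorted", call. = FALSE)
  n_bins <- length(intensity)
  duration <- n_bins * bin_width
  if (max(spike_times) > duration + 1e-12) {
    stop("spike times exceed the span of `intensity`", call. = FALSE)
  }
  lam <- pmax(intensity, eps)
  if (discrete) {
    p <- pmin(pmax(lam * bin_width, eps), 1 - eps)
    q <- -log(1 - p)                       # discrete per-bin hazard
    bins <- pmin(floor(spike_times / bin_width), n_bins - 1) + 1L
    cumq <- c(0, cumsum(q))
    z <- numeric(length(bins) - 1)
    for (k in seq_along(z)) {
      b0 <- bins[k]; b1 <- bins[k + 1]
      gap <- cumq[b1] - cumq[b0 + 1]       # full bins strictly between spikes
      atom <- -log(1 - stats::runif(1) * p[b1])
      z[k] <- 1 - exp(-(gap + atom))
    }
    return(z)
  }
  # exact integral of the piecewise-constant intensity up to each spike time
  cum <- c(0, cumsum(lam) * bin_width)
  Lambda <- function(t) {
    b <- pmin(floor(t / bin_width), n_bins - 1)
    cum[b + 1] + lam[b + 1] * (t - b * bin_width)
  }
  L <- Lambda(spike_times)
  1 - exp(-diff(L))
}

#' Kolmogorov-Smirnov band test of rescaled intervals
#'
#' Compares the empirical distribution of rescaled values against the
#' uniform(0, 1) reference. The 95% acceptance band is the standard
#' \eqn{\pm 1.36/\sqrt{n}} envelope around the diagonal of the K-S plot.
#'
#' @param z Rescaled values from [time_rescale()].
#' @return A one-row tibble: `n`, `ks_statistic`, `band_halfwidth`,
#'   `inside_band`.
#' @export
ks_band_test <- function(z) {
  n <- length(z)
  if (n < 2) stop("need at least 2 rescaled values", call. = FALSE)
  zs <- sort(z)
  i <- seq_len(n)
  d <- max(pmax(abs(zs - (i - 1) / n), abs(zs - i / n)))
  half <- 1.36 / sqrt(n)
  tibble::tibble(n = n, ks_statistic = d, band_halfwidth = half,
                 inside_band = d <= half)
}

#' Autocorrelation of rescaled intervals
#'
#' Serial dependence between consecutive rescaled intervals indicates that
#' the model missed temporal structure even if the marginal distribution
#' looks uniform. Pearson correlations at lags 1..`max_lag` are compared
#' against the \eqn{\pm 1.96/\sqrt{n}} white-noise bounds.
#'
#' @param z Rescaled values.
#' @param max_lag Largest lag to test (default 20, capped at n - 2).
#' @return A tibble with columns `lag`, `correlation`, `bound`,
#'   `significant`; carries an attribute `undefined = TRUE` (with all-NA
#'   correlations) when `z` is constant.
#' @export
autocorr_check <- function(z, max_lag = 20) {
  n <- length(z)
  if (n < 10) stop("need at least 10 values for the autocorrelation check",
                   call. = FALSE)
  max_lag <- min(max_lag, n - 2)
  bound <- 1.96 / sqrt(n)
  if (stats::sd(z) == 0) {
    out <- tibble::tibble(lag = seq_len(max_lag), correlation = NA_real_,
                          bound = bound, significant = NA)
    attr(out, "undefined") <- TRUE
    warning("constant rescaled values; autocorrelation undefined", call. = FALSE)
    return(out)
  }
  corr <- vapply(seq_len(max_lag), function(l) {
    stats::cor(z[seq_len(n - l)], z[seq_len(n - l) + l])
  }, 0)
  out <- tibble::tibble(lag = seq_len(max_lag), correlation = corr,
                        bound = bound, significant = abs(corr) > bound)
  attr(out, "undefined") <- FALSE
  out
}

#' ROC-optimal spike-prediction threshold and TP/TN rates
#'
#' Sweeps a threshold over the predicted per-bin intensity and selects the
#' point on the ROC curve maximising Youden's J = sensitivity +
#' specificity - 1. TP is the accuracy of predicting bins that contain a
#' spike (sensitivity); TN the accuracy on empty bins (specificity).
#'
#' @param predicted Predicted per-bin intensity (any monotone score works).
#' @param actual Binary 0/1 per-bin spike indicator, same length.
#' @return A one-row tibble: `threshold`, `tp`, `tn`, `youden`.
#' @export
roc_threshold <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  actual <- as.integer(actual != 0)
  if (length(unique(actual)) < 2) {
    stop("`actual` must contain both spike and no-spike bins", call. = FALSE)
  }
  r <- pROC::roc(response = actual, predictor = as.numeric(predicted),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  cc <- pROC::coords(r, x = "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  # several thresholds can tie on Youden's J; take the smallest for determinism
  best <- which.max(cc$sensitivity + cc$specificity)
  if (length(best) > 1) best <- best[which.min(cc$threshold[best])]
  tibble::tibble(
    threshold = cc$threshold[best],
    tp = cc$sensitivity[best],
    tn = cc$specificity[best],
    youden = cc$sensitivity[best] + cc$specificity[best] - 1
  )
}

#' Full validation report for one fitted model
#'
#' Combines the time-rescaled K-S band test, the autocorrelation check of
#' rescaled intervals, and the ROC-thresholded TP/TN prediction accuracy.
#'
#' @param model A fitted [fit_sparse_glm()] model.
#' @param design The regressor matrix used for fitting.
#' @param target The output neuron's binned 0/1 train.
#' @param bin_width Bin width in seconds.
#' @param max_lag Passed to [autocorr_check()].
#' @return An object of class `validation_report` (a list of the three
#'   component results) with [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
validate_model <- function(model, design, target, bin_width, max_lag = 20) {
  lambda_bin <- predict_intensity(model, design)        # per-bin probability
  lambda_hz <- lambda_bin / bin_width
  spike_bins <- which(target != 0)
  if (length(spike_bins) < 2) {
    stop("target has fewer than 2 spikes; cannot validate", call. = FALSE)
  }
  spike_times <- (spike_bins - 0.5) * bin_width
  z <- time_rescale(spike_times, lambda_hz, bin_width, discrete = TRUE)
  ks <- ks_band_test(z)
  ac <- autocorr_check(z, max_lag = min(max_lag, length(z) - 2))
  roc <- roc_threshold(lambda_bin, target)
  structure(list(ks = ks, autocorr = ac, roc = roc, z = z),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> KS %.4f (band %.4f, %s); TP %.3f TN %.3f @ thr %.4g\n",
    x$ks$ks_statistic, x$ks$band_halfwidth,
    if (x$ks$inside_band) "inside" else "OUTSIDE",
    x$roc$tp, x$roc$tn, x$roc$threshold
  ))
  invisible(x)
}

#' @export
glance.validation_report <- function(x, ...) {
  dplyr::bind_cols(
    x$ks,
    tibble::tibble(
      autocorr_frac_significant = mean(x$autocorr$significant),
      threshold = x$roc$threshold, tp = x$roc$tp, tn = x$roc$tn
    )
  )
}

#' @export
tidy.validation_report <- function(x, ...) x$autocorr
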