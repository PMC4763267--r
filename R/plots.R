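#' Plot an error-curve fit over its scatter
#'
#' @param object An [error_curve_fit()].
#' @param scatter Optional tibble with `n_sampled` and `sigma` to overlay.
#' @param n_range Range of sampled sizes for the curve (default 1-500).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_curve_fit <- function(object, scatter = NULL,
                                     n_range = c(1, 500), ...) {
  grid <- tibble::tibble(n_sampled = seq(n_range[1], n_range[2], length.out = 400))
  grid$sigma <- sigma_curve(grid$n_sampled, object)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$n_sampled, y = .data$sigma))
  if (!is.null(scatter)) {
    p <- p + ggplot2::geom_point(data = scatter, alpha = 0.4, size = 0.8)
  }
  p + ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "sampled neurons N", y = expression(sigma(N)),
                  title = "Sampling bias of small-world-ness")
}

#' K-S plot of a validation report
#'
#' Empirical CDF of the time-rescaled values against the uniform diagonal,
#' with the 95% acceptance band.
#'
#' @param object A [validate_model()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  z <- sort(object$z)
  n <- length(z)
  df <- tibble::tibble(model_cdf = z, empirical = (seq_len(n) - 0.5) / n)
  half <- object$ks$band_halfwidth
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_cdf, y = .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = half, linetype = 3) +
    ggplot2::geom_abline(slope = 1, intercept = -half, linetype = 3) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "model quantile", y = "empirical quantile",
                  title = "Time-rescaling K-S plot")
}

#' Plot reconstructed kernels of a fitted model
#'
#' @param model A [fit_sparse_glm()] model with a basis.
#' @param bin_width Bin width in seconds used to label the lag axis.
#' @return A ggplot object faceted by input neuron (nonzero kernels only).
#' @export
plot_kernels <- function(model, bin_width = 0.01) {
  K <- reconstruct_kernels(model)
  keep <- rowSums(K != 0) > 0
  if (!any(keep)) stop("model has no nonzero kernels", call. = FALSE)
  df <- tibble::as_tibble(K[keep, , drop = FALSE], rownames = "input") |>
    tidyr::pivot_longer(-"input", names_to = "lag_bin", values_to = "k") |>
    dplyr::mutate(lag_s = (as.integer(gsub("\\D", "", .data$lag_bin)) - 1) * bin_width)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$k)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~input) +
    ggplot2::labs(x = "lag (s)", y = "kernel weight",
                  title = paste("Kernels of output", model$output %||% ""))
}

#' GA convergence plot
#'
#' @param object A [fit_pattern_ga()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$best_objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best squared pattern error",
                  title = "GA pattern-fit convergence")
}
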