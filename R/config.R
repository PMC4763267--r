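#' Analysis configuration
#'
#' Collects every tunable of the reconstruction pipeline in one validated
#' list: binning, Laguerre basis, penalty grid, cross-validation, the
#' firing-rate floor, the simulator geometry and the correction density
#' sweep. Defaults follow the package's standard operating point: 10 ms
#' bins, 0.5 s memory (50 bins), basis order 3, alpha grid 0.2-0.9, 20
#' log-spaced penalties over \[1e-5, 1e-1\], 5 contiguous CV folds, 0.5 Hz
#' rate floor.
#'
#' @param bin_width Bin width in seconds (default 0.01).
#' @param memory_bins Kernel memory M in bins (default 50).
#' @param basis_order Laguerre order J (default 3).
#' @param alpha_grid Candidate Laguerre decay parameters.
#' @param zeta_grid Candidate L1 penalties.
#' @param cv_folds Contiguous cross-validation folds (>= 2).
#' @param rate_floor_hz Minimum firing rate retained (default 0.5).
#' @param seed Default RNG seed carried through the pipeline.
#' @param geometry List: `space` (cuboid, micrometres), `n_electrodes`,
#'   `local_fraction` used when no explicit threshold is given.
#' @param correction List: `densities`, the edge-density sweep for
#'   adjustment intervals (defaults to the 5.8%-23% cortical range plus
#'   the 8.32% working density).
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 0.01,
                            memory_bins = 50,
                            basis_order = 3,
                            alpha_grid = seq(0.2, 0.9, by = 0.1),
                            zeta_grid = default_zeta_grid(),
                            cv_folds = 5,
                            rate_floor_hz = 0.5,
                            seed = 1,
                            geometry = list(space = c(780, 320, 100),
                                            n_electrodes = 6,
                                            local_fraction = 0.5),
                            correction = list(densities = c(0.058, 0.0832, 0.23))) {
  stopifnot(bin_width > 0, memory_bins >= 1, basis_order >= 1,
            length(alpha_grid) >= 1, length(zeta_grid) >= 1,
            cv_folds >= 2, rate_floor_hz >= 0)
  if (any(alpha_grid <= 0 | alpha_grid >= 1)) {
    stop("`alpha_grid` values must be strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(bin_width = bin_width, memory_bins = memory_bins,
         basis_order = basis_order, alpha_grid = alpha_grid,
         zeta_grid = zeta_grid, cv_folds = cv_folds,
         rate_floor_hz = rate_floor_hz, seed = seed,
         geometry = geometry, correction = correction),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(
    paste0("<analysis_config> %.0f ms bins, M=%d, J=%d, %d alphas, ",
           "%d zetas, %d folds, floor %.2g Hz\n"),
    x$bin_width * 1000, x$memory_bins, x$basis_order,
    length(x$alpha_grid), length(x$zeta_grid), x$cv_folds, x$rate_floor_hz
  ))
  invisible(x)
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys raise an error; missing keys keep their defaults.
#'
#' @param path Path to a YAML file whose top-level keys are
#'   [analysis_config()] arguments.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(vals$geometry)) {
    vals$geometry <- utils::modifyList(formals(analysis_config)$geometry |>
                                         eval(), vals$geometry)
  }
  if (!is.null(vals$correction)) {
    vals$correction <- utils::modifyList(formals(analysis_config)$correction |>
                                           eval(), vals$correction)
  }
  do.call(analysis_config, vals)
}
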