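#' Multi-neuron spike trains
#'
#' Bundles per-neuron spike event times (seconds) with the recording duration
#' and the time-bin width used for all binned analyses. The event table is a
#' tibble with columns `neuron_id` and `time_s`, sorted by neuron and time,
#' so the object slots directly into dplyr pipelines via [tidy()][generics::tidy].
#'
#' @param events A data frame with columns `neuron_id` (character-coercible)
#'   and `time_s` (non-negative numeric, seconds).
#' @param duration Recording length in seconds. Defaults to the latest spike
#'   time.
#' @param bin_width Bin width in seconds used by [bin_spikes()] (default
#'   0.01 s).
#' @return An object of class `spike_trains`.
#' @examples
#' sts <- spike_trains(data.frame(neuron_id = c("a", "a", "b"),
#'                                time_s = c(0.1, 0.5, 0.2)))
#' firing_rates(sts)
#' @export
spike_trains <- function(events, duration = NULL, bin_width = 0.01) {
  stopifnot(is.data.frame(events))
  if (!all(c("neuron_id", "time_s") %in% names(events))) {
    stop("`events` must have columns `neuron_id` and `time_s`", call. = FALSE)
  }
  if (nrow(events) == 0) stop("`events` contains no spikes", call. = FALSE)
  if (!is.numeric(events$time_s) || anyNA(events$time_s)) {
    stop("`time_s` must be numeric with no missing values", call. = FALSE)
  }
  if (any(events$time_s < 0)) stop("negative spike times", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  events <- tibble::tibble(
    neuron_id = as.character(events$neuron_id),
    time_s = as.numeric(events$time_s)
  )
  events <- dplyr::arrange(events, .data$neuron_id, .data$time_s)
  if (is.null(duration)) duration <- max(events$time_s)
  if (any(events$time_s > duration)) {
    stop("spike times exceed `duration`", call. = FALSE)
  }
  structure(
    list(
      events = events,
      neuron_ids = unique(events$neuron_id),
      duration = as.numeric(duration),
      bin_width = as.numeric(bin_width)
    ),
    class = "spike_trains"
  )
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf(
    "<spike_trains> %d neurons, %d spikes, %.3f s @ %.0f ms bins\n",
    length(x$neuron_ids), nrow(x$events), x$duration, x$bin_width * 1000
  ))
  invisible(x)
}

#' @rdname spike_trains
#' @param x A `spike_trains` object.
#' @param ... Unused.
#' @export
tidy.spike_trains <- function(x, ...) x$events

#' @rdname spike_trains
#' @export
glance.spike_trains <- function(x, ...) {
  tibble::tibble(
    n_neurons = length(x$neuron_ids),
    n_spikes = nrow(x$events),
    duration_s = x$duration,
    bin_width_s = x$bin_width,
    mean_rate_hz = nrow(x$events) / length(x$neuron_ids) / x$duration
  )
}

#' Per-neuron spike counts and firing rates
#'
#' @param sts A [spike_trains()] object.
#' @return A tibble with columns `neuron_id`, `n_spikes`, `rate_hz`.
#' @export
firing_rates <- function(sts) {
  stopifnot(inherits(sts, "spike_trains"))
  sts$events |>
    dplyr::count(.data$neuron_id, name = "n_spikes") |>
    dplyr::mutate(rate_hz = .data$n_spikes / sts$duration) |>
    dplyr::arrange(match(.data$neuron_id, sts$neuron_ids))
}

#' Bin spike trains into a binary matrix
#'
#' Bins are half-open intervals `[k*bin_width, (k+1)*bin_width)`; a spike at
#' exactly `duration` falls in the last bin. Multiple spikes in one bin clip
#' to 1, matching the binary spike/no-spike framing of the GLM.
#'
#' @param sts A [spike_trains()] object.
#' @param bin_width Optional override of the object's bin width (seconds).
#' @return A neurons x bins 0/1 matrix with neuron ids as row names. The
#'   number of columns is `ceiling(duration / bin_width)`.
#' @export
bin_spikes <- function(sts, bin_width = NULL) {
  stopifnot(inherits(sts, "spike_trains"))
  bw <- if (is.null(bin_width)) sts$bin_width else bin_width
  n_bins <- ceiling(sts$duration / bw)
  ids <- sts$neuron_ids
  out <- matrix(0L, nrow = length(ids), ncol = n_bins,
                dimnames = list(ids, NULL))
  bin <- pmin(floor(sts$events$time_s / bw), n_bins - 1) + 1L
  row <- match(sts$events$neuron_id, ids)
  out[cbind(row, bin)] <- 1L
  out
}

#' Drop neurons with low firing rates
#'
#' Low-rate units carry too few events to support kernel estimation; the
#' conventional cut in functional-connectivity work on hippocampal recordings
#' is 0.5 Hz.
#'
#' @param sts A [spike_trains()] object.
#' @param floor_hz Minimum firing rate in Hz; neurons strictly below it are
#'   removed (default 0.5).
#' @return A `spike_trains` object with the retained neurons, original order
#'   preserved. May contain zero neurons, in which case an error is raised by
#'   the constructor; callers should check [firing_rates()] first if that is
#'   a possibility.
#' @export
filter_by_rate <- function(sts, floor_hz = 0.5) {
  stopifnot(inherits(sts, "spike_trains"), floor_hz >= 0)
  keep <- firing_rates(sts) |>
    dplyr::filter(.data$rate_hz >= floor_hz) |>
    dplyr::pull("neuron_id")
  events <- dplyr::filter(sts$events, .data$neuron_id %in% keep)
  if (nrow(events) == 0) {
    stop("no neurons at or above the rate floor", call. = FALSE)
  }
  out <- spike_trains(events, duration = sts$duration, bin_width = sts$bin_width)
  out$neuron_ids <- keep
  out
}

#' Read spike trains from a two-column TSV file
#'
#' Expects lines of `neuron_id <TAB> time_s`. A header line is detected and
#' skipped if its second field is not numeric.
#'
#' @param path File path.
#' @param duration,bin_width Passed to [spike_trains()].
#' @return A [spike_trains()] object.
#' @export
read_spike_tsv <- function(path, duration = NULL, bin_width = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty spike file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    stop("line ", bad[1], " of ", path, " does not have two tab-separated fields",
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  raw <- vapply(parts, `[[`, "", 2L)
  times <- suppressWarnings(as.numeric(raw))
  start <- 1L
  if (is.na(times[1])) start <- 2L  # header
  if (start > length(lines)) stop("empty spike file: ", path, call. = FALSE)
  idx <- start:length(lines)
  nonnum <- idx[is.na(times[idx])]
  if (length(nonnum)) {
    stop("non-numeric spike time on line ", nonnum[1], " of ", path, call. = FALSE)
  }
  neg <- idx[times[idx] < 0]
  if (length(neg)) {
    stop("negative spike time on line ", neg[1], " of ", path, call. = FALSE)
  }
  spike_trains(
    tibble::tibble(neuron_id = ids[idx], time_s = times[idx]),
    duration = duration, bin_width = bin_width
  )
}

#' Write spike trains to a two-column TSV file
#'
#' @param sts A [spike_trains()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_tsv <- function(sts, path) {
  stopifnot(inherits(sts, "spike_trains"))
  readr::write_tsv(sts$events, path, col_names = TRUE)
  invisible(path)
}

#' Read CRCNS-style paired cluster/timestamp spike files
#'
#' Reads the `.res`/`.clu` file convention used by extracellular recording
#' repositories: the timestamp file holds one integer sample index per spike;
#' the cluster file starts with the number of clusters and then holds one
#' cluster label per spike. Cluster labels 0 and 1 conventionally mark
#' artifact and noise and are dropped by default.
#'
#' @param res_path Path to the timestamp file (integer sample indices).
#' @param clu_path Path to the cluster file.
#' @param sample_rate Sampling rate in Hz used to convert sample indices to
#'   seconds. Must be given explicitly.
#' @param drop_noise Drop cluster labels 0 and 1 (default TRUE).
#' @param prefix Prefix for neuron ids (default "u"); a unit with cluster
#'   label 5 becomes `"u5"`.
#' @param duration,bin_width Passed to [spike_trains()].
#' @return A [spike_trains()] object.
#' @export
read_crcns_pair <- function(res_path, clu_path, sample_rate,
                            drop_noise = TRUE, prefix = "u",
                            duration = NULL, bin_width = 0.01) {
  if (missing(sample_rate) || !is.numeric(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` (Hz) must be supplied explicitly", call. = FALSE)
  }
  res <- scan(res_path, what = numeric(), quiet = TRUE)
  clu <- scan(clu_path, what = integer(), quiet = TRUE)
  if (length(clu) != length(res) + 1) {
    stop("cluster file must hold one leading count plus one label per spike",
         call. = FALSE)
  }
  clu <- clu[-1]
  keep <- if (drop_noise) clu > 1 else rep(TRUE, length(clu))
  if (!any(keep)) stop("no spikes left after dropping noise clusters", call. = FALSE)
  spike_trains(
    tibble::tibble(
      neuron_id = paste0(prefix, clu[keep]),
      time_s = res[keep] / sample_rate
    ),
    duration = duration, bin_width = bin_width
  )
}
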