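test_that("spike TSV reading counts, sorts and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\t0.5", "b\t0.2", "a\t0.1"), f)
  sts <- read_spike_tsv(f)
  expect_s3_class(sts, "spike_trains")
  rates <- firing_rates(sts)
  expect_equal(rates$n_spikes[rates$neuron_id == "a"], 2)
  expect_equal(rates$n_spikes[rates$neuron_id == "b"], 1)
  # per-neuron times sorted even though the file was out of order
  a_times <- sts$events$time_s[sts$events$neuron_id == "a"]
  expect_equal(a_times, sort(a_times))

  writeLines(c("neuron_id\ttime_s", "a\t1.0"), f)
  expect_equal(nrow(read_spike_tsv(f)$events), 1)  # header skipped

  writeLines(c("a\t0.1", "b\t-1"), f)
  expect_error(read_spike_tsv(f), "line 2")
  writeLines(c("a\t0.1", "b\txyz"), f)
  expect_error(read_spike_tsv(f), "non-numeric")
  writeLines(character(0), f)
  expect_error(read_spike_tsv(f), "empty")
})

test_that("spike TSV round-trip preserves times to 1e-9 s", {
  set.seed(42)
  events <- tibble::tibble(
    neuron_id = sample(sprintf("n%02d", 1:8), 200, replace = TRUE),
    time_s = round(stats::runif(200, 0, 60), 6)
  )
  sts <- spike_trains(events, duration = 60)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spike_tsv(sts, f)
  back <- read_spike_tsv(f, duration = 60)
  expect_equal(back$neuron_ids, sts$neuron_ids)
  expect_lt(max(abs(back$events$time_s - sts$events$time_s)), 1e-9)
})

test_that("CRCNS-style paired cluster/timestamp files are read", {
  res <- withr::local_tempfile(); clu <- withr::local_tempfile()
  # 6 spikes at 20 kHz; clusters 0 and 1 are noise
  writeLines(as.character(c(20000, 40000, 60000, 80000, 100000, 120000)), res)
  writeLines(as.character(c(4, 2, 0, 3, 2, 1, 3)), clu)
  sts <- read_crcns_pair(res, clu, sample_rate = 20000)
  expect_setequal(sts$neuron_ids, c("u2", "u3"))
  expect_equal(nrow(sts$events), 4)
  expect_equal(sort(sts$events$time_s[sts$events$neuron_id == "u2"]), c(1, 4))
  expect_error(read_crcns_pair(res, clu), "sample_rate")
})

test_that("rate filtering matches a brute-force recount", {
  # 10 spikes in 60 s = 0.167 Hz, below the 0.5 Hz floor
  slow <- tibble::tibble(neuron_id = "slow", time_s = seq(1, 55, length.out = 10))
  fast <- tibble::tibble(neuron_id = "fast", time_s = seq(0.5, 59, length.out = 40))
  sts <- spike_trains(dplyr::bind_rows(slow, fast), duration = 60)
  kept <- filter_by_rate(sts, 0.5)
  expect_equal(kept$neuron_ids, "fast")
  expect_equal(filter_by_rate(sts, 0)$neuron_ids, sts$neuron_ids)

  set.seed(7)
  n_sp <- pmax(rpois(100, lambda = stats::runif(100, 0, 1) * 60), 1)
  events <- purrr::map_dfr(seq_len(100), function(i) {
    tibble::tibble(neuron_id = sprintf("n%03d", i),
                   time_s = sort(stats::runif(n_sp[i], 0, 60)))
  })
  big <- spike_trains(events, duration = 60)
  expect_kept <- sprintf("n%03d", which(n_sp / 60 >= 0.5))
  expect_setequal(filter_by_rate(big, 0.5)$neuron_ids, expect_kept)
})

test_that("binning respects half-open bins and recounts spikes", {
  sts <- spike_trains(
    tibble::tibble(neuron_id = c("a", "a", "b"), time_s = c(0.0, 0.01, 0.005)),
    duration = 0.03, bin_width = 0.01
  )
  x <- bin_spikes(sts)
  expect_equal(dim(x), c(2, 3))
  expect_equal(x["a", ], c(1, 1, 0))
  expect_equal(x["b", ], c(1, 0, 0))

  # distinct-bin fixture: binning then summing rows equals spike counts
  set.seed(1)
  times <- sort(sample(0:999, 120)) * 0.01 + 0.001
  ids <- sample(c("p", "q", "r"), 120, replace = TRUE)
  sts2 <- spike_trains(tibble::tibble(neuron_id = ids, time_s = times),
                       duration = 10, bin_width = 0.01)
  counts <- rowSums(bin_spikes(sts2))
  rates <- firing_rates(sts2)
  expect_equal(as.numeric(counts[rates$neuron_id]), rates$n_spikes)
})

test_that("networks round-trip through TSV and GraphML", {
  g <- igraph::graph_from_literal(a -+ b, b -+ c)
  for (fmt in c("tsv", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(g, f, fmt)
    back <- read_network(f)
    expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
    expect_setequal(apply(igraph::as_edgelist(back), 1, paste, collapse = ">"),
                    c("a>b", "b>c"))
  }
  # isolated node survives the TSV round-trip
  g2 <- igraph::add_vertices(g, 1, name = "lonely")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(g2, f, "tsv")
  expect_true("lonely" %in% igraph::V(read_network(f))$name)
  expect_error(write_network(g, f, "dot"))
})

test_that("a random 50-node digraph round-trips with identical adjacency", {
  g <- random_digraph(50, 0.08, seed = 99)
  igraph::V(g)$name <- sprintf("v%02d", 1:50)
  for (fmt in c("tsv", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(g, f, fmt)
    back <- read_network(f)
    ord <- match(igraph::V(g)$name, igraph::V(back)$name)
    A0 <- as.matrix(igraph::as_adjacency_matrix(g))
    A1 <- as.matrix(igraph::as_adjacency_matrix(back))[ord, ord]
    expect_true(all(A0 == A1))
  }
})

test_that("configs validate and read from YAML", {
  cfg <- analysis_config()
  expect_equal(cfg$rate_floor_hz, 0.5)
  expect_equal(cfg$cv_folds, 5)
  expect_equal(range(cfg$zeta_grid), c(1e-5, 1e-1))
  expect_error(analysis_config(alpha_grid = c(0.5, 1.2)), "alpha")
  expect_error(analysis_config(cv_folds = 1))

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("bin_width: 0.005", "memory_bins: 40"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$bin_width, 0.005)
  expect_equal(cfg2$memory_bins, 40)
  writeLines("not_a_key: 1", f)
  expect_error(read_config(f), "unknown config keys")
})
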