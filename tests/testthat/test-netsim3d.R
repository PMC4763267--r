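test_that("neuron placement is uniform, bounded and reproducible", {
  p1 <- place_neurons(500, seed = 91)
  p2 <- place_neurons(500, seed = 91)
  expect_identical(p1, p2)
  space <- c(780, 320, 100)
  expect_true(all(p1$x >= 0 & p1$x <= space[1]))
  expect_true(all(p1$y >= 0 & p1$y <= space[2]))
  expect_true(all(p1$z >= 0 & p1$z <= space[3]))
  for (ax in 1:3) {
    v <- p1[[ax]]
    se <- space[ax] / sqrt(12) / sqrt(500)
    expect_lt(abs(mean(v) - space[ax] / 2), 3 * se)
  }
  expect_equal(dim(place_neurons(2, seed = 1)), c(2L, 3L))
  expect_error(place_neurons(10, space = c(1, -1, 1)), "positive")
})

test_that("threshold connectivity hits its degenerate and calibrated regimes", {
  pos <- place_neurons(40, seed = 92)
  full <- connect_threshold(pos, l = 50, p_in = 1, p_out = 1, seed = 1)
  expect_equal(igraph::ecount(full$graph), 40 * 39 / 2)
  none <- connect_threshold(pos, l = 50, p_in = 0, p_out = 0, seed = 1)
  expect_equal(igraph::ecount(none$graph), 0)
  expect_error(connect_threshold(pos, 50, p_in = 0.2, p_out = 0.5), "p_in")

  # empirical conditional probabilities approach P_in and P_out
  pos2 <- place_neurons(300, seed = 93)
  l <- calibrate_radius(pos2, 0.6, 0.1, 0.25)
  d <- as.numeric(dist(as.matrix(pos2)))
  sn <- connect_threshold(pos2, l, 0.6, 0.1, seed = 94)
  A <- as.matrix(igraph::as_adjacency_matrix(sn$graph))
  conn <- A[lower.tri(A)] == 1  # column-major lower triangle = dist() order
  p_in_hat <- mean(conn[d <= l]); n_in <- sum(d <= l)
  p_out_hat <- mean(conn[d > l]); n_out <- sum(d > l)
  expect_lt(abs(p_in_hat - 0.6), 3 * sqrt(0.6 * 0.4 / n_in))
  expect_lt(abs(p_out_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n_out))
})

test_that("radius calibration delivers the target edge density", {
  dens <- replicate(20, {
    pos <- place_neurons(500)
    l <- calibrate_radius(pos, 0.25, 0.05, 0.0832)
    igraph::edge_density(connect_threshold(pos, l, 0.25, 0.05)$graph)
  })
  expect_lt(abs(mean(dens) - 0.0832), 0.005)
})

test_that("distance-decay model 1 behaves as a geometric decay", {
  expect_equal(connection_prob_model1(0, alpha = 0.7, lambda = 0.5), 0.7)
  d <- seq(0, 500, by = 25)
  hi <- connection_prob_model1(d, 0.5, 0.9)
  lo <- connection_prob_model1(d, 0.5, 0.1)
  expect_true(all(hi[-1] > lo[-1]))
  expect_true(all(diff(hi) < 0))
  expect_lt(connection_prob_model1(1e5, 0.5, 0.9), 1e-6)
  expect_error(connection_prob_model1(10, 1.5, 0.5), "alpha")
  expect_error(connection_prob_model1(10, 0.5, 0), "lambda")
})

test_that("distance-decay model 2 keeps a long-range tolerance", {
  expect_equal(connection_prob_model2(0, beta = 2, gamma = 0.8), 0.8)
  d <- seq(10, 2000, by = 50)
  p <- connection_prob_model2(d, beta = 2, gamma = 0.8, p1 = 0.02)
  expect_true(all(p > 0.02))          # asymptote approached from above
  p_lowbeta <- connection_prob_model2(d, beta = 0.5, gamma = 0.8, p1 = 0.02)
  expect_true(all(p_lowbeta > p))     # larger beta lowers every P(d>0)
  expect_true(all(diff(p) < 0))
  expect_error(connection_prob_model2(10, beta = 0, gamma = 1), "beta")
  expect_error(connection_prob_model2(10, beta = 1, gamma = -1), "gamma")

  # both parametric generators produce valid spatial networks
  pos <- place_neurons(60, seed = 95)
  s1 <- connect_model1(pos, alpha = 0.8, lambda = 0.6, seed = 96)
  s2 <- connect_model2(pos, beta = 1, gamma = 0.8, seed = 97)
  for (s in list(s1, s2)) {
    expect_false(igraph::any_loop(s$graph))
    expect_false(igraph::is_directed(s$graph))
  }
})

test_that("electrode sampling returns exact induced subgraphs", {
  pos <- place_neurons(200, seed = 98)
  l <- calibrate_radius(pos, 0.3, 0.05, 0.12)
  snet <- connect_threshold(pos, l, 0.3, 0.05, seed = 99)
  el <- place_electrodes(6, seed = 100)

  # radius beyond the cuboid diagonal samples everything
  whole <- sample_network(snet, el, radius = 1e4)
  expect_equal(whole$n_sampled, 200)
  expect_equal(igraph::ecount(whole$graph), igraph::ecount(snet$graph))
  expect_error(sample_network(snet, el, radius = 1e-6), "no neurons")

  r <- calibrate_sampling_radius(snet, el, 50)
  sub <- sample_network(snet, el, r)
  expect_equal(sub$n_sampled, 50)
  # brute-force pair scan: every kept edge joins sampled nodes, and every
  # original edge between sampled nodes is kept
  A <- as.matrix(igraph::as_adjacency_matrix(snet$graph))
  A_sub <- as.matrix(igraph::as_adjacency_matrix(sub$graph))
  expect_true(all(A_sub == A[sub$ids, sub$ids]))
})

test_that("the GA recovers self-generated patterns and saturates correctly", {
  # target taken from an actual simulated graph must be reachable
  set.seed(101)
  pos <- place_neurons(40)
  d <- as.numeric(dist(as.matrix(pos)))
  l <- stats::quantile(d, 0.5, type = 1)
  g <- connect_threshold(pos, l, 0.75, 0.15)$graph
  target_l <- average_path_length(g)
  target_c <- average_clustering(g)
  ga <- fit_pattern_ga(target_l, target_c, 40, generations = 30, pop = 30,
                       seed = 102)
  expect_lt(ga$objective, 1e-3)

  # pattern (1, 1) pushes toward the complete graph
  ga2 <- fit_pattern_ga(1, 1, 20, generations = 15, pop = 20, seed = 103)
  expect_gt(ga2$achieved_c, 0.9)

  expect_error(fit_pattern_ga(1.5, 1.2, 40), "target_c")
  expect_error(fit_pattern_ga(0.5, 0.5, 40), "target_l")
})
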