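# shared small design fixture: 5 inputs, J = 3, 5000 bins
make_design_fixture <- function(seed, n_bins = 5000, n_inputs = 5, p = 0.05) {
  set.seed(seed)
  x <- matrix(rbinom(n_inputs * n_bins, 1, p), nrow = n_inputs,
              dimnames = list(sprintf("n%02d", seq_len(n_inputs)), NULL))
  b <- laguerre_basis(0.5, 3, 30)
  list(x = x, basis = b, design = convolve_inputs(x, b, lag = 1))
}

test_that("an independent target yields a mostly zero model", {
  fx <- make_design_fixture(11)
  set.seed(99)
  target <- rbinom(ncol(fx$x), 1, 0.05)   # independent of every input
  m <- fit_sparse_glm(fx$design, target)
  expect_gte(mean(m$coefficients == 0), 0.9)
})

test_that("a planted single-input signal is recovered cleanly", {
  hits <- 0
  runs <- 50
  for (s in seq_len(runs)) {
    fx <- make_design_fixture(1000 + s)
    v <- fx$design[, "n03.b1"]
    set.seed(2000 + s)
    target <- 0.8 * v + rnorm(length(v), sd = 0.1)
    m <- fit_sparse_glm(fx$design, target)
    # the edge-relevant notion of selection: lasso support screened by the
    # debiased significance test (Bonferroni over all candidates)
    cut <- 0.05 / length(m$coefficients)
    sig <- apply(m$coef_pvals, 1, min) < cut & rowSums(m$coefficients != 0) > 0
    hits <- hits + (sig[["n03"]] && sum(sig) == 1)
  }
  expect_gte(hits / runs, 0.95)
})

test_that("an overwhelming penalty empties the model", {
  fx <- make_design_fixture(21)
  set.seed(22)
  target <- rbinom(ncol(fx$x), 1, 0.05)
  m <- fit_sparse_glm(fx$design, target, zeta_grid = c(default_zeta_grid(), 1e6))
  # grid includes a penalty large enough to zero everything; check that end
  # of the path rather than the CV-selected model
  expect_true(all(m$cv$deviance[m$cv$zeta == max(m$cv$zeta)] >= min(m$cv$deviance)))
  m_forced <- fit_sparse_glm(fx$design, target, zeta_grid = c(1e6, 2e6))
  expect_true(all(m_forced$coefficients == 0))
  expect_equal(m_forced$k0, mean(target), tolerance = 1e-6)
})

test_that("degenerate designs return zero coefficients with a warning", {
  d <- matrix(1, nrow = 100, ncol = 6)
  attr(d, "inputs") <- c("a", "b"); attr(d, "order") <- 3L
  set.seed(5)
  expect_warning(m <- fit_sparse_glm(d, rbinom(100, 1, 0.3)), "degenerate")
  expect_true(all(m$coefficients == 0))
})

test_that("selected penalty minimises the CV deviance curve", {
  fx <- make_design_fixture(31)
  set.seed(32)
  target <- 0.5 * fx$design[, "n02.b1"] + rnorm(ncol(fx$x), sd = 0.2)
  m <- fit_sparse_glm(fx$design, target)
  sel <- m$cv$deviance[m$cv$zeta == m$zeta]
  expect_true(all(sel <= m$cv$deviance))
})

test_that("kernels rebuild from coefficients exactly", {
  b <- laguerre_basis(0.5, 3, 40)
  co <- matrix(0, 2, 3, dimnames = list(c("a", "b"), paste0("b", 1:3)))
  m <- spikesw:::new_spike_glm(0.1, co, 1e-3, tibble::tibble(), b, "a")
  expect_true(all(reconstruct_kernels(m) == 0))
  co[1, 1] <- 1
  m$coefficients <- co
  expect_equal(reconstruct_kernels(m)["a", ], b$values[1, ], tolerance = 1e-14)
  set.seed(8)
  co[] <- rnorm(6)
  m$coefficients <- co
  expect_equal(reconstruct_kernels(m), co %*% b$values, tolerance = 1e-14)
})

test_that("kernel-route and coefficient-route predictions agree", {
  # route 1: k0 + design %*% vec(coefficients); route 2: direct convolution
  # of the reconstructed kernels with the lagged inputs
  fx <- make_design_fixture(41, n_bins = 400)
  set.seed(42)
  co <- matrix(rnorm(15, sd = 0.1), nrow = 5, ncol = 3,
               dimnames = list(rownames(fx$x), paste0("b", 1:3)))
  m <- spikesw:::new_spike_glm(0.07, co, 1e-3, tibble::tibble(), fx$basis, "n01")
  route1 <- predict_intensity(m, fx$design)
  K <- reconstruct_kernels(m)
  route2 <- rep(0.07, ncol(fx$x))
  for (n in seq_len(nrow(fx$x))) {
    route2 <- route2 + oracle_convolve(fx$x[n, ], K[n, ], lag = 1)
  }
  expect_equal(route1, route2, tolerance = 1e-10)
})

test_that("a planted chain is reconstructed with no self-loops", {
  runs <- 10
  good <- 0
  for (s in seq_len(runs)) {
    basis <- laguerre_basis(0.5, 3, 50)
    gt <- make_ground_truth(3, edge_density = 0, kernel_scale = 0.4,
                            basis = basis, seed = 300 + s)
    # plant exactly the chain n01 -> n02 -> n03
    gt$coef["n01", "n02", ] <- c(0.35, 0, 0)
    gt$coef["n02", "n03", ] <- c(0.35, 0, 0)
    gt$graph <- igraph::graph_from_edgelist(
      rbind(c("n01", "n02"), c("n02", "n03")), directed = TRUE)
    sts <- simulate_spike_trains(gt, duration = 100, seed = 400 + s)
    cfg <- analysis_config(alpha_grid = 0.5)
    rec <- reconstruct_network(sts, cfg)
    edges <- apply(igraph::as_edgelist(rec$network), 1, paste, collapse = ">")
    has_chain <- all(c("n01>n02", "n02>n03") %in% edges)
    few_extra <- length(setdiff(edges, c("n01>n02", "n02>n03"))) <= 1
    good <- good + (has_chain && few_extra)
    expect_false(any(vapply(strsplit(edges, ">"),
                            function(e) e[1] == e[2], TRUE)))
  }
  expect_gte(good / runs, 0.9)
})

test_that("all-zero models give an empty network after isolate removal", {
  co <- matrix(0, 2, 3, dimnames = list(c("a", "b"), paste0("b", 1:3)))
  models <- list(
    a = spikesw:::new_spike_glm(0, co, 1e-3, tibble::tibble(), NULL, "a"),
    b = spikesw:::new_spike_glm(0, co, 1e-3, tibble::tibble(), NULL, "b")
  )
  g <- build_functional_network(models)
  expect_equal(igraph::vcount(g), 0)
  g2 <- build_functional_network(models, keep_isolates = TRUE)
  expect_equal(igraph::vcount(g2), 2)
})
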