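test_that("percentage error and adjustment are exact inverses", {
  expect_equal(percentage_error(0.5, 0.5), 0)
  expect_equal(percentage_error(0.8, 0.4), 1)
  expect_warning(expect_true(is.nan(percentage_error(0.5, 0))))

  set.seed(111)
  for (k in 1:20) {
    on <- runif(1, 0.01, 1); sn <- runif(1, 0.01, 1)
    s <- percentage_error(on, sn)
    # invert through a constant error curve equal to sigma
    fit <- error_curve_fit(s, 0, 0, 0)
    expect_equal(adjust_smallworldness(sn, 10, fit), on, tolerance = 1e-12)
  }
})

test_that("the reference curve is positive, decreasing, and ordered in N", {
  ref <- error_curve_reference()
  n <- 1:500
  s <- sigma_curve(n, ref)
  expect_true(all(is.finite(s)))
  expect_true(all(s > 0))
  expect_true(all(diff(s) < 0))
  expect_true(sigma_curve(36, ref) > sigma_curve(53, ref))
  expect_true(sigma_curve(53, ref) > sigma_curve(64, ref))
  expect_lt(sigma_curve(2000, ref), 0.01)
})

test_that("adjustment reproduces the published session endpoints", {
  expect_equal(round(adjust_smallworldness(0.0451, 53), 4), 0.0553)
  expect_equal(round(adjust_smallworldness(0.0429, 64), 4), 0.0515)
  expect_equal(adjust_smallworldness(0, 7), 0)
  # a negative sampled omega is magnitude-adjusted, sign kept, and flagged
  expect_warning(adj_neg <- adjust_smallworldness(-0.0357, 6))
  expect_equal(round(abs(adj_neg), 4), 0.0799)
  expect_lt(adj_neg, 0)
})

test_that("noiseless coefficients are recovered and noise sets the RMSE floor", {
  ref <- error_curve_reference()
  nv <- rep(seq(10, 400, by = 10), each = 3)
  clean <- tibble::tibble(n_sampled = nv, sigma = sigma_curve(nv, ref))
  fit <- fit_two_term_exponential(clean, seed = 112)
  expect_lt(abs(fit$a - 1.564), 1e-4)
  expect_lt(abs(fit$b - -0.080), 1e-4)
  expect_lt(abs(fit$c - 0.279), 1e-4)
  expect_lt(abs(fit$d - -0.006), 1e-4)

  set.seed(113)
  noisy <- clean
  noisy$sigma <- noisy$sigma + rnorm(nrow(noisy), sd = 0.06)
  fit2 <- fit_two_term_exponential(noisy, seed = 114)
  expect_lt(abs(fit2$rmse - 0.06), 0.01)

  # single-exponential data: the nested model degenerates gracefully
  set.seed(115)
  single <- tibble::tibble(n_sampled = nv,
                           sigma = 1.2 * exp(-0.05 * nv) + rnorm(length(nv), sd = 0.02))
  fit3 <- fit_two_term_exponential(single, seed = 116)
  expect_lt(abs(fit3$rmse - 0.02), 0.01)

  expect_error(fit_two_term_exponential(
    tibble::tibble(n_sampled = c(10, 10, 20), sigma = 1:3)), "8 points")
})

test_that("adjustment ranges span the density sweep", {
  f1 <- error_curve_fit(1.0, -0.08, 0.2, -0.006)
  f2 <- error_curve_fit(1.8, -0.08, 0.35, -0.006)
  r1 <- adjust_range(0.05, 40, list(f1))
  expect_equal(r1[1], r1[2])
  r2 <- adjust_range(0.05, 40, list(f1, f2))
  expect_lt(r2[1], r2[2])
  mid <- adjust_smallworldness(0.05, 40, error_curve_reference())
  expect_true(mid >= r2[1] && mid <= r2[2])
})

test_that("tissue estimates scale with density and volume", {
  est <- estimate_tissue_network()
  expect_equal(round(est$n_neurons), 2296)
  expect_equal(est$edge_density, 0.085, tolerance = 0.01)
  est2 <- estimate_tissue_network(dims = c(780, 320, 100) * 2)
  expect_equal(est2$n_neurons, est$n_neurons * 8, tolerance = 1e-12)
  expect_equal(est2$edge_density, est$edge_density)
})

test_that("simulated error scatter is reproducible and signed as expected", {
  sc1 <- simulate_error_curve(sizes = 300, sample_fractions = c(0.15, 0.9),
                              reps = 2, reference_reps = 8, seed = 117)
  sc2 <- simulate_error_curve(sizes = 300, sample_fractions = c(0.15, 0.9),
                              reps = 2, reference_reps = 8, seed = 117)
  expect_identical(sc1, sc2)
  expect_true(all(c("n_sampled", "sigma", "omega_on", "omega_sn") %in% names(sc1)))

  # sampling the whole network leaves no error
  sc_full <- simulate_error_curve(sizes = 150, sample_fractions = 1,
                                  reps = 2, reference_reps = 8, seed = 118)
  expect_true(all(abs(sc_full$omega_on - sc_full$omega_sn) < 1e-12))
  expect_true(all(sc_full$sigma == 0))

  # small samples overestimate small-world-ness (positive mean sigma)
  sc_small <- simulate_error_curve(sizes = 500,
                                   sample_fractions = c(0.06, 0.1, 0.16),
                                   reps = 3, reference_reps = 8, seed = 119)
  expect_true(all(sc_small$n_sampled < 100))
  expect_gt(mean(sc_small$sigma), 0)
})
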