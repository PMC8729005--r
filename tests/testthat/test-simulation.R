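test_that("random model generator honors config and seed", {
  expect_equal(unname(random_ggm(5, edge_prob = 0, seed = 1)), diag(5),
               ignore_attr = TRUE)
  expect_equal(random_ggm(8, seed = 3), random_ggm(8, seed = 3))
  expect_false(identical(random_ggm(8, seed = 3), random_ggm(8, seed = 4)))
  P <- random_ggm(10, seed = 2)
  expect_silent(validate_pcor(P))
  off <- P[upper.tri(P)]
  expect_true(all(abs(off) < 1))
  expect_error(random_ggm(6, edge_prob = 1, partial_range = c(0.99, 0.999),
                          max_attempts = 5),
               "narrower partial_range")
})

test_that("accepted-model edge density tracks the Bernoulli rate", {
  # With narrow partials nearly every draw is accepted, so the conditioned
  # density must match Bernoulli(0.2) within 3 SDs of the batch mean.
  dens <- vapply(1:500, function(s) {
    P <- random_ggm(10, partial_range = c(-0.3, 0.3), seed = s)
    mean(abs(P[upper.tri(P)]) > 0)
  }, numeric(1))
  band <- 3 * sqrt(0.2 * 0.8 / (45 * 500))
  expect_lt(abs(mean(dens) - 0.2), band)
  # At the default wide range, PD rejection thins dense draws; the deviation
  # is real and is reported here rather than asserted away.
  dens_wide <- vapply(1:100, function(s) {
    P <- random_ggm(10, seed = 5000 + s)
    mean(abs(P[upper.tri(P)]) > 0)
  }, numeric(1))
  expect_lt(mean(dens_wide), 0.2)
})

test_that("gaussian sampling matches the implied correlation structure", {
  expect_equal(sample_gaussian(chain_P(3), 10, seed = 9),
               sample_gaussian(chain_P(3), 10, seed = 9))
  P <- random_ggm(5, edge_prob = 0.5, partial_range = c(-0.6, 0.6), seed = 13)
  C <- correlation_from_partial(P)
  X <- sample_gaussian(P, 100000, seed = 14)
  expect_lt(max(abs(cor(X) - C)), 0.01)
  X0 <- sample_gaussian(labeled(diag(4)), 5000, seed = 15)
  expect_lt(max(abs(cor(X0)[upper.tri(diag(4))])), 0.06)
})

test_that("Erdos-Renyi expected path length formula and its inverse", {
  expect_equal(er_expected_path_length(100, 2.4),
               (log(100) - 0.577) / log(2.4) + 0.5)
  expect_equal(round(er_expected_path_length(100, 2.4), 2), 5.1)
  expect_equal(round(er_mean_degree_for_length(100, 5), 1), 2.4)
  expect_equal(er_expected_path_length(100, er_mean_degree_for_length(100, 5)), 5)
  d <- seq(1.5, 6, by = 0.5)
  expect_true(all(diff(er_expected_path_length(100, d)) < 0))
  expect_error(er_expected_path_length(100, 1), "exceed 1")
})

test_that("oracle estimators give perfect experiment scores", {
  P <- random_ggm(8, edge_prob = 0.25, seed = 17)
  res <- success_rate_experiment(P, n_grid = 100, reps = 2, K = 7,
                                 estimator = "oracle", seed = 1)
  expect_true(all(res$success))
  expect_equal(attr(res, "n_estimator_failures"), 0L)

  ks <- k_sensitivity_experiment(P, n_grid = 100, K_grid = 2:7, reps = 1,
                                 seed = 1, estimator = "oracle")
  expect_equal(max(ks$percent_error[ks$K == 7]), 0)
  expect_true(all(ks$percent_error >= 0))
})

test_that("success-rate results are reproducible and well-formed", {
  P <- random_ggm(7, edge_prob = 0.3, seed = 23)
  res1 <- success_rate_experiment(P, n_grid = c(100, 400), reps = 3, K = 4,
                                  estimator = "inverse_pearson", seed = 5)
  res2 <- success_rate_experiment(P, n_grid = c(100, 400), reps = 3, K = 4,
                                  estimator = "inverse_pearson", seed = 5)
  expect_equal(res1, res2)
  summ <- summarize_success(res1)
  expect_true(all(summ$success >= 0 & summ$success <= 1))
  expect_true(all(summ$replicates == 3))
})

test_that("truncation experiment excludes long-path and zero-score pairs", {
  P <- random_ggm(7, edge_prob = 0.3, seed = 29)
  ks <- k_sensitivity_experiment(P, n_grid = 500, K_grid = 2:6, reps = 2, seed = 2)
  expect_true(all(ks$pmax_length <= 6))
  summ <- summarize_percent_error(ks)
  expect_true(all(summ$reps > 0))
  expect_true(all(summ$mean >= 0))
})
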