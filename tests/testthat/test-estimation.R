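test_that("covariate residualization removes linear effects", {
  # zero covariate: data unchanged up to centering/scaling
  X <- sample_gaussian(chain_P(3), 50, seed = 1)
  Z0 <- matrix(0, 50, 1, dimnames = list(rownames(X), "z"))
  adj <- adjust_covariates(X, Z0)
  expect_equal(unname(adj), unname(scale(X)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # planted linear effect: post-adjustment correlation with covariate ~ 0
  z <- rnorm(50)
  X2 <- X + outer(z, c(2, -1, 0.5))
  Z <- matrix(z, 50, 1, dimnames = list(rownames(X), "z"))
  adj2 <- adjust_covariates(X2, Z)
  expect_lt(max(abs(cor(adj2, z))), 1e-10)

  # collinear covariates named in the error
  Z2 <- cbind(Z, z2 = 2 * z)
  expect_error(adjust_covariates(X2, Z2), "collinear.*z2")

  # feature equal to a covariate: flagged as zero residual
  X3 <- cbind(X, dup = z)
  expect_warning(adjust_covariates(X3, Z), "zero residual.*dup")
})

test_that("inverse Pearson estimation recovers the model as n grows", {
  P <- random_ggm(5, edge_prob = 0.5, partial_range = c(-0.6, 0.6), seed = 21)
  errs <- vapply(c(500, 50000), function(n) {
    est <- estimate_inverse_pearson(sample_gaussian(P, n, seed = 31))
    expect_s3_class(est, "estimated_ggm")
    expect_silent(validate_pcor(est$pcor))
    max(abs(est$pcor - P))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05)

  # independent features: off-diagonal estimates are O(1/sqrt(n)) noise
  X <- sample_gaussian(labeled(diag(6)), 4000, seed = 7)
  est <- estimate_inverse_pearson(X)
  off <- est$pcor[upper.tri(est$pcor)]
  expect_lt(max(abs(off)), 6 / sqrt(4000))
})

test_that("inverse Pearson refuses n <= p and singular inputs", {
  X <- sample_gaussian(labeled(diag(6)), 5, seed = 1)
  expect_error(estimate_inverse_pearson(X), "n > p")
  Xd <- sample_gaussian(labeled(diag(3)), 100, seed = 2)
  Xd <- cbind(Xd, d = Xd[, 1])
  expect_error(estimate_inverse_pearson(Xd), "singular|regularized")
})

test_that("graphical lasso shrinks to the empty graph and to the MLE", {
  P <- random_ggm(6, edge_prob = 0.4, partial_range = c(-0.6, 0.6), seed = 5)
  X <- sample_gaussian(P, 300, seed = 6)

  big <- estimate_glasso(X, lambda = 5)
  expect_equal(unname(big$pcor), diag(6))

  g0 <- estimate_glasso(X, lambda = 0)
  ip <- estimate_inverse_pearson(X)
  expect_lt(max(abs(g0$pcor - ip$pcor)), 1e-6)

  # sparsity is non-increasing in lambda on a fixed dataset
  edges <- vapply(c(0.01, 0.05, 0.1, 0.3), function(l) {
    Ph <- estimate_glasso(X, lambda = l)$pcor
    sum(Ph[upper.tri(Ph)] != 0)
  }, numeric(1))
  expect_true(all(diff(edges) <= 0))
  expect_silent(validate_pcor(estimate_glasso(X, lambda = 0.05)$pcor))
})

test_that("cross-validated glasso recovers a strong-edge support", {
  P <- labeled(diag(6))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6))
  for (r in seq_len(nrow(edges))) {
    P[edges[r, 1], edges[r, 2]] <- P[edges[r, 2], edges[r, 1]] <- 0.4
  }
  validate_pcor(P)
  hits <- vapply(1:3, function(s) {
    X <- sample_gaussian(P, 1500, seed = 50 + s)
    Ph <- estimate_glasso(X, lambda = "cv", seed = s)$pcor
    mean(Ph[edges] != 0)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("lambda selection is deterministic and sensitive to sparsity", {
  P <- random_ggm(6, edge_prob = 0.3, partial_range = c(-0.5, 0.5), seed = 11)
  X <- sample_gaussian(P, 200, seed = 12)
  expect_equal(as.numeric(select_lambda_cv(X, seed = 42)),
               as.numeric(select_lambda_cv(X, seed = 42)))
  expect_equal(as.numeric(select_lambda_cv(X, grid = 0.2)), 0.2)
  expect_error(select_lambda_cv(X[1:6, ], folds = 5), "degenerate folds")

  # sparser truth selects a larger penalty (seeded directional check)
  lam <- function(ep, s) {
    Pt <- random_ggm(8, edge_prob = ep, partial_range = c(-0.6, 0.6), seed = 100 + s)
    as.numeric(select_lambda_cv(sample_gaussian(Pt, 300, seed = 200 + s), seed = s))
  }
  sparse <- mean(vapply(1:3, function(s) lam(0.1, s), numeric(1)))
  dense <- mean(vapply(1:3, function(s) lam(0.6, s), numeric(1)))
  expect_gt(sparse, dense)
})

test_that("estimated subscores converge to the truth in n", {
  P <- random_ggm(6, edge_prob = 0.4, partial_range = c(-0.6, 0.6), seed = 77)
  labs <- rownames(P)
  truth <- true_pair <- NULL
  sc <- max_pps_scan(P)
  true_pair <- c(sc$node_a[1], sc$node_b[1])
  truth <- sc$score[1]
  med_err <- vapply(c(100, 1000, 10000), function(n) {
    errs <- vapply(1:20, function(r) {
      X <- sample_gaussian(P, n, seed = derive_seed(r, paste0("cons", n)))
      est <- estimate_inverse_pearson(X)$pcor
      m <- max_pps(est, true_pair[1], true_pair[2], K = 5, validate = FALSE)
      abs(m$score - truth)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})
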