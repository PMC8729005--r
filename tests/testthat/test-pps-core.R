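test_that("path products multiply signed partials along the path", {
  P <- three_node_P()
  expect_equal(path_tau(P, c("a", "b")), 0.3)
  expect_equal(path_tau(P, c("a", "c", "b")), 0.4 * 0.2)

  Pz <- labeled(diag(3))
  expect_warning(tz <- path_tau(Pz, c("a", "b")), "zero partial")
  expect_equal(tz, 0)
  expect_error(path_tau(P, c("a", "b", "a")), "repeated node")

  # |tau| never grows when a path is extended: every factor has |.| <= 1
  Pr <- random_ggm(6, edge_prob = 0.8, seed = 3)
  g <- support_graph(Pr)
  labs <- rownames(Pr)
  paths <- enumerate_paths(g, labs[1], labs[2], 5)
  for (p in paths[vapply(paths, length, integer(1)) > 2]) {
    expect_lte(abs(path_tau(Pr, p)), abs(path_tau(Pr, p[-length(p)])) + 1e-15)
  }
})

test_that("gamma matches hand-evaluated determinant weights", {
  # 2-node model: all three determinants trivial, gamma = pi
  P2 <- labeled(diag(2)); P2[1, 2] <- P2[2, 1] <- 0.6
  expect_equal(path_gamma(P2, c("a", "b")), 0.6)

  P <- three_node_P()
  denom <- sqrt((1 - 0.2^2) * (1 - 0.4^2))
  expect_equal(path_gamma(P, c("a", "b")), 0.3 / denom, tolerance = 1e-12)
  expect_equal(path_gamma(P, c("a", "c", "b")), 0.08 / denom, tolerance = 1e-12)
  # the two contributions must sum to the marginal correlation
  expect_equal(path_gamma(P, c("a", "b")) + path_gamma(P, c("a", "c", "b")),
               correlation_from_partial(P)["a", "b"], tolerance = 1e-12)
})

test_that("full decomposition reconstructs every marginal correlation", {
  for (s in 1:10) {
    P <- random_ggm(5, edge_prob = 0.5, seed = 400 + s)
    C <- correlation_from_partial(P)
    labs <- rownames(P)
    for (i in 1:4) for (j in (i + 1):5) {
      d <- decompose_correlation(P, labs[i], labs[j], validate = FALSE)
      expect_lt(abs(attr(d, "reconstructed") - C[i, j]), 1e-10)
      expect_equal(sum(d$gamma), attr(d, "reconstructed"))
    }
  }
})

test_that("disconnected pairs decompose to zero and score as no_paths", {
  P <- labeled(diag(4)); P[1, 2] <- P[2, 1] <- 0.5; P[3, 4] <- P[4, 3] <- 0.5
  d <- decompose_correlation(P, "a", "c")
  expect_equal(nrow(d), 0)
  expect_equal(attr(d, "reconstructed"), 0)
  expect_equal(correlation_from_partial(P)["a", "c"], 0)

  tab <- pps(P, "a", "c")
  expect_equal(attr(tab, "status"), "no_paths")
  expect_equal(nrow(tab), 0)
  expect_error(max_pps(P, "a", "c"), "no path")
})

test_that("subscores normalize the worked three-node example", {
  tab <- pps(three_node_P(), "a", "b")
  expect_equal(attr(tab, "status"), "ok")
  expect_equal(tab$score, c(0.3, 0.08) / 0.38, tolerance = 1e-12)  # 0.7895, 0.2105
  expect_equal(sum(tab$score), 1)
  expect_true(tab$is_max[1])

  m <- max_pps(three_node_P(), "a", "b")
  expect_equal(m$path, c("a", "b"))
  expect_equal(m$score, 0.3 / 0.38, tolerance = 1e-12)

  # single connecting path scores 1
  tab1 <- pps(chain_P(3), "a", "c")
  expect_equal(tab1$score, 1)
})

test_that("a longer path can outscore the direct edge", {
  P <- labeled(diag(3))
  P[1, 2] <- P[2, 1] <- 0.05
  P[1, 3] <- P[3, 1] <- 0.6
  P[2, 3] <- P[3, 2] <- 0.6
  m <- max_pps(P, "a", "b")
  expect_equal(m$path, c("a", "c", "b"))
  expect_gt(m$score, 0.5)
})

test_that("sign rule and score range hold on seeded random models", {
  for (s in 1:15) {
    P <- random_ggm(6, edge_prob = 0.4, seed = 700 + s)
    labs <- rownames(P)
    pairs <- utils::combn(labs, 2)
    for (k in seq_len(ncol(pairs))) {
      d <- decompose_correlation(P, pairs[1, k], pairs[2, k], validate = FALSE)
      if (nrow(d) == 0) next
      expect_equal(sign(d$gamma), sign(d$tau))
      tab <- pps(P, pairs[1, k], pairs[2, k], validate = FALSE)
      if (attr(tab, "status") == "ok") {
        expect_equal(sum(tab$score), 1, tolerance = 1e-12)
        expect_true(all(tab$score >= 0 & tab$score <= 1))
      }
    }
  }
})

test_that("relative ranking of two paths does not depend on K", {
  for (s in 1:10) {
    P <- random_ggm(7, edge_prob = 0.45, seed = 900 + s)
    labs <- rownames(P)
    full <- pps(P, labs[1], labs[2], K = 6, validate = FALSE)
    if (nrow(full) < 2) next
    kappa <- max(full$length[1:2])
    ord_full <- order(full$score[1:2])
    for (K in kappa:6) {
      tab <- pps(P, labs[1], labs[2], K = K, validate = FALSE)
      idx <- match(full$path[1:2], tab$path)
      expect_equal(order(tab$score[idx]), ord_full)
    }
  }
})

test_that("decomposition tables serialize to TSV and JSON", {
  tab <- pps(three_node_P(), "a", "b")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pps_tsv(tab, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$score, tab$score)
  expect_equal(back$path, c("a|b", "a|c|b"))

  js <- jsonlite::fromJSON(write_pps_json(tab))
  expect_equal(js$K, 2)
  expect_equal(js$entries$score, tab$score)
  expect_equal(unlist(js$pair), c("a", "b"))
})
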