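test_that("scan of a chain scores every pair's unique path at 1", {
  sc <- max_pps_scan(chain_P(5))
  expect_equal(nrow(sc), choose(5, 2))
  expect_true(all(sc$score == 1))
  expect_true(all(sc$n_paths == 1))
  expect_equal(attr(sc, "n_disconnected"), 0L)
  # pair orientation is canonical: node_a < node_b
  expect_true(all(sc$node_a < sc$node_b))
})

test_that("scan agrees with direct per-pair calls and logs disconnection", {
  P <- random_ggm(10, seed = 37)
  sc <- max_pps_scan(P, K = 4)
  for (r in seq_len(min(nrow(sc), 8))) {
    m <- max_pps(P, sc$node_a[r], sc$node_b[r], K = 4, validate = FALSE)
    expect_equal(paste(m$path, collapse = "|"), sc$path[r])
    expect_equal(m$score, sc$score[r])
  }
  expect_equal(nrow(sc) + attr(sc, "n_disconnected"), choose(10, 2))
})

test_that("condition differences rank a planted edge change on top", {
  sc <- max_pps_scan(clique_plus_edge_P())
  self <- condition_difference(sc, sc)
  expect_true(all(self$abs_difference == 0))
  expect_false(any(self$one_sided))
  # ties are ordered deterministically by pair labels
  expect_equal(self[order(self$node_a, self$node_b), "node_a"],
               sort(self$node_a))

  P2 <- clique_plus_edge_P()
  P2["a", "b"] <- P2["b", "a"] <- 0  # remove one clique edge in condition B
  diff <- condition_difference(sc, max_pps_scan(P2))
  expect_equal(c(diff$node_a[1], diff$node_b[1]), c("a", "b"))

  # a pair connected in only one condition is one-sided against 0
  P3 <- clique_plus_edge_P()
  P3["e", "f"] <- P3["f", "e"] <- 0
  diff3 <- condition_difference(sc, max_pps_scan(P3))
  ef <- diff3[diff3$node_a == "e" & diff3$node_b == "f", ]
  expect_true(ef$one_sided)
  expect_equal(ef$score_b, 0)

  scx <- sc; scx$node_a <- paste0("zz", scx$node_a); scx$node_b <- paste0("zz", scx$node_b)
  expect_error(condition_difference(sc, scx), "share no node labels")
})

test_that("node averages separate embedded from pendant nodes", {
  sc <- max_pps_scan(clique_plus_edge_P())
  one <- node_average_max_pps(sc, "e")
  expect_equal(one$average, 1)  # single-path partner only
  hub <- node_average_max_pps(sc, "a")
  expect_lt(hub$average, one$average)
  expect_equal(hub$n_partners, 3L)

  P <- labeled(diag(3)); P[1, 2] <- P[2, 1] <- 0.5
  iso <- node_average_max_pps(max_pps_scan(P), "c")
  expect_equal(iso$status, "isolated")
  expect_true(is.na(iso$average))
})

test_that("edge-class summaries mirror the direct-vs-embedded contrast", {
  P <- clique_plus_edge_P()
  cmap <- c(a = "dense", b = "dense", c = "dense", d = "dense",
            e = "direct", f = "direct")
  ec <- edge_class_pps(P, class_map = cmap)
  expect_equal(ec$direct$n, 1L)
  expect_equal(ec$direct$mean, 1)
  expect_equal(ec$dense$n, 6L)
  expect_lt(ec$dense$mean, ec$direct$mean)

  # invariant to relabeling nodes within classes
  perm <- c(a = "b", b = "c", c = "d", d = "a", e = "f", f = "e")
  P2 <- P; dimnames(P2) <- list(perm[rownames(P)], perm[colnames(P)])
  ec2 <- edge_class_pps(P2, class_map = setNames(cmap[names(perm)], perm))
  expect_equal(ec2$dense$mean, ec$dense$mean)
  expect_equal(ec2$direct$mean, ec$direct$mean)

  # class with no adjacent pairs: empty summary, not an error
  cmap2 <- c(a = "x", f = "x")
  ec3 <- edge_class_pps(P, class_map = cmap2)
  expect_equal(ec3$x$n, 0L)
})

test_that("bootstrap CIs are deterministic and track degeneracy", {
  X <- sample_gaussian(chain_P(3), 60, seed = 41)
  const <- bootstrap_ci(X, function(d) 0.7, B = 50, seed = 1)
  expect_equal(c(const$lower, const$upper), c(0.7, 0.7))

  stat <- function(d) max_pps(estimate_inverse_pearson(d)$pcor, "a", "c",
                              K = 2, validate = FALSE)$score
  ci1 <- bootstrap_ci(X, stat, B = 40, seed = 9)
  ci2 <- bootstrap_ci(X, stat, B = 40, seed = 9)
  expect_equal(ci1$replicates, ci2$replicates)
  expect_lte(ci1$lower, ci1$upper)

  # failing replicates are recorded as missing, not fatal
  flaky <- local({
    calls <- 0
    function(d) {
      calls <<- calls + 1
      if (calls %% 3 == 0) stop("disconnected")
      mean(d)
    }
  })
  ci3 <- bootstrap_ci(X, flaky, B = 30, seed = 2)
  expect_gt(ci3$n_missing, 0)
  expect_true(is.finite(ci3$lower))
})
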