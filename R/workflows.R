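## Hypothesis-generation workflows: all-pairs max-PPS scans, cross-condition
## differences, per-node averages, edge-class summaries, bootstrap CIs.

## Shared scan engine: one determinant cache serves every pair.
scan_core <- function(P, K, pairs = NULL, zero_threshold = 0) {
  P <- ensure_labels(P)
  labs <- node_labels(P)
  n <- length(labs)
  if (is.null(K)) K <- n - 1
  g <- support_graph(P, zero_threshold)
  A <- build_normalized_precision(P, validate = FALSE)
  ld <- new_det_cache(A)
  if (is.null(pairs)) {
    ordered <- sort(labs, method = "radix")
    pairs <- t(utils::combn(ordered, 2))
  } else {
    pairs <- as.matrix(pairs)
    # canonical orientation: lexicographically smaller label first
    flip <- pairs[, 1] > pairs[, 2]
    pairs[flip, ] <- pairs[flip, 2:1]
  }
  rows <- vector("list", nrow(pairs))
  n_disconnected <- 0L
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    paths <- enumerate_paths(g, a, b, K)
    gam <- gamma_for_paths(P, paths, ld, labels = labs)
    total <- sum(abs(gam))
    if (length(paths) == 0 || total == 0) {
      n_disconnected <- n_disconnected + 1L
      next
    }
    score <- abs(gam) / total
    best <- which.max(score)  # paths length-lex ordered; ties -> shortest/lex
    rows[[r]] <- data.frame(node_a = a, node_b = b,
                            path = format_path(paths[[best]]),
                            length = length(paths[[best]]) - 1L,
                            score = score[best], gamma = gam[best],
                            n_paths = length(paths), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(node_a = character(0), node_b = character(0),
                      path = character(0), length = integer(0),
                      score = numeric(0), gamma = numeric(0),
                      n_paths = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, n_disconnected = n_disconnected, K = K)
}

#' All-pairs scan for the highest-scoring path
#'
#' Applies the pair-path subscore to every unordered pair of connected nodes
#' and records each pair's best path and score — the unit of the
#' hypothesis-generation analyses. Disconnected pairs are omitted with a
#' count in the `n_disconnected` attribute.
#'
#' @param x an `estimated_ggm` or a partial correlation matrix.
#' @param K length cutoff (default full enumeration; use 4-5 in practice).
#' @param zero_threshold support-graph threshold.
#' @return object of class `max_pps_scan`: data frame with columns `node_a`,
#'   `node_b`, `path`, `length`, `score`, `gamma`, `n_paths`; attributes `K`,
#'   `method`, `n_disconnected`.
#' @export
max_pps_scan <- function(x, K = NULL, zero_threshold = 0) {
  P <- get_pcor(x)
  out <- scan_core(P, K, pairs = NULL, zero_threshold = zero_threshold)
  structure(as.data.frame(out), class = c("max_pps_scan", "data.frame"),
            K = attr(out, "K"),
            method = if (inherits(x, "estimated_ggm")) x$method else "supplied",
            n_disconnected = attr(out, "n_disconnected"))
}

#' @export
print.max_pps_scan <- function(x, ...) {
  cat(sprintf("Max-PPS scan (K = %d, estimator = %s): %d connected pair(s), %d disconnected\n",
              attr(x, "K"), attr(x, "method"), nrow(x), attr(x, "n_disconnected")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")

#' Rank node pairs by cross-condition difference in maximum PPS
#'
#' Compares two scans (e.g. fasting vs post-load, mothers vs newborns) and
#' ranks pairs by the absolute difference of their best path scores. A pair
#' connected in only one condition is compared against 0 and flagged
#' `one_sided`.
#'
#' @param scan_a,scan_b `max_pps_scan` objects sharing node labels.
#' @return data frame with columns `node_a`, `node_b`, `score_a`, `score_b`,
#'   `difference` (`score_a - score_b`), `abs_difference`, `one_sided`,
#'   ordered by decreasing `abs_difference` (ties: lexicographic pair).
#' @export
condition_difference <- function(scan_a, scan_b) {
  a <- as.data.frame(scan_a); b <- as.data.frame(scan_b)
  nodes_a <- unique(c(a$node_a, a$node_b)); nodes_b <- unique(c(b$node_a, b$node_b))
  if (length(intersect(nodes_a, nodes_b)) == 0) {
    stop("the two scans share no node labels", call. = FALSE)
  }
  a$key <- pair_key(a$node_a, a$node_b)
  b$key <- pair_key(b$node_a, b$node_b)
  keys <- union(a$key, b$key)
  ia <- match(keys, a$key); ib <- match(keys, b$key)
  sa <- ifelse(is.na(ia), 0, a$score[ia])
  sb <- ifelse(is.na(ib), 0, b$score[ib])
  parts <- strsplit(keys, "~", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, character(1), 1),
                    node_b = vapply(parts, `[`, character(1), 2),
                    score_a = sa, score_b = sb,
                    difference = sa - sb, abs_difference = abs(sa - sb),
                    one_sided = is.na(ia) | is.na(ib),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_difference, out$node_a, out$node_b, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Average maximum PPS of one node over its connected partners
#'
#' A single per-node measure of network involvement: nodes whose marginal
#' correlations arise from many different paths have a low average (high
#' involvement); nodes dominated by single paths have a high one.
#'
#' @param scan a `max_pps_scan`.
#' @param node node label.
#' @return list with `node`, `average` (NA when isolated), `n_partners`, and
#'   `status` (`"ok"` or `"isolated"`).
#' @export
node_average_max_pps <- function(scan, node) {
  df <- as.data.frame(scan)
  hit <- df$node_a == node | df$node_b == node
  if (!any(hit)) {
    return(list(node = node, average = NA_real_, n_partners = 0L,
                status = "isolated"))
  }
  list(node = node, average = mean(df$score[hit]), n_partners = sum(hit),
       status = "ok")
}

#' Edge subscores summarized by node class
#'
#' For each class, takes every adjacent within-class pair and computes the
#' subscore of the direct edge (the length-1 path): the fraction of the
#' pair's marginal correlation carried by the direct connection rather than
#' the rest of the network. Mirrors the contrast between directly-converting
#' metabolite classes (high edge scores) and densely interconnected ones
#' (low edge scores).
#'
#' @param x an `estimated_ggm` or partial correlation matrix.
#' @param K length cutoff for the normalizing path set.
#' @param class_map named character vector mapping node label to class.
#' @param zero_threshold support-graph threshold.
#' @return list per class: data frame of `node_a`, `node_b`, `edge_score`,
#'   plus `mean`, `sd`, `n`. Classes with no adjacent pair give `n = 0`.
#' @export
edge_class_pps <- function(x, K = NULL, class_map, zero_threshold = 0) {
  P <- get_pcor(x)
  labs <- node_labels(P)
  g <- support_graph(P, zero_threshold)
  A <- build_normalized_precision(P, validate = FALSE)
  ld <- new_det_cache(A)
  if (is.null(K)) K <- length(labs) - 1
  classes <- sort(unique(class_map), method = "radix")
  out <- list()
  for (cl in classes) {
    members <- intersect(names(class_map)[class_map == cl], labs)
    rows <- list()
    if (length(members) >= 2) {
      cand <- t(utils::combn(sort(members, method = "radix"), 2))
      for (r in seq_len(nrow(cand))) {
        a <- cand[r, 1]; b <- cand[r, 2]
        if (P[a, b] == 0 || abs(P[a, b]) <= zero_threshold) next
        paths <- enumerate_paths(g, a, b, K)
        gam <- gamma_for_paths(P, paths, ld, labels = labs)
        total <- sum(abs(gam))
        if (total == 0) next
        direct <- which(vapply(paths, length, integer(1)) == 2)
        rows[[length(rows) + 1]] <- data.frame(node_a = a, node_b = b,
                                               edge_score = abs(gam[direct]) / total,
                                               stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(node_a = character(0), node_b = character(0),
                 edge_score = numeric(0), stringsAsFactors = FALSE)
    out[[cl]] <- list(scores = df, mean = if (nrow(df)) mean(df$edge_score) else NA_real_,
                      sd = if (nrow(df) > 1) stats::sd(df$edge_score) else NA_real_,
                      n = nrow(df))
  }
  out
}

#' Nonparametric bootstrap confidence interval for a scan-derived statistic
#'
#' Resamples rows of the data with replacement, re-estimates the network and
#' recomputes the statistic on each resample, and reports the 2.5/97.5
#' percentile interval. Replicates on which the statistic is undefined
#' (e.g. the pair of interest disconnected in a resample) are recorded as
#' missing and excluded, with their count reported.
#'
#' @param data samples x features numeric matrix.
#' @param statistic function of a data matrix returning a scalar (it should
#'   perform estimation internally, so the whole pipeline is resampled).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed; the interval is deterministic given it.
#' @param level confidence level (default 0.95).
#' @param label statistic label carried in the result.
#' @return object of class `bootstrap_ci`: list with `label`, `estimate`
#'   (statistic on the full data), `lower`, `upper`, `B`, `n_missing`,
#'   `seed`, `replicates`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, seed = 1, level = 0.95,
                         label = "statistic") {
  data <- as_data_matrix(data)
  stopifnot(B >= 2)
  n <- nrow(data)
  est <- statistic(data)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(statistic(data[idx, , drop = FALSE])),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- reps[!is.na(reps)]
  if (length(ok) == 0) stop("statistic undefined on every bootstrap replicate", call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
  structure(list(label = label, estimate = est, lower = qs[1], upper = qs[2],
                 B = B, n_missing = sum(is.na(reps)), seed = seed,
                 level = level, replicates = reps),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%s: %.4g (%.0f%% bootstrap CI %.4g, %.4g; B = %d, %d missing)\n",
              x$label, x$estimate, 100 * x$level, x$lower, x$upper, x$B,
              x$n_missing))
  invisible(x)
}
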