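#' Support graph of a Gaussian graphical model
#'
#' The support graph is the undirected labeled graph whose edges are the
#' nonzero partial correlations; path enumeration for the pair-path subscore
#' runs on it. Graphical-lasso estimates contain exact zeros, so the default
#' threshold is exact; for dense (inverse Pearson) estimates a small
#' threshold such as `1e-10` screens float noise.
#'
#' @param P partial correlation matrix.
#' @param zero_threshold edge present iff `|pi_ij| > zero_threshold`.
#' @return an [igraph::igraph] object with vertex `name`s and edge attribute
#'   `weight` holding the signed partial correlation.
#' @export
support_graph <- function(P, zero_threshold = 0) {
  stopifnot(zero_threshold >= 0)
  P <- ensure_labels(P)
  Adj <- abs(P) > zero_threshold
  diag(Adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(Adj, mode = "undirected", diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    igraph::E(g)$weight <- P[cbind(el[, 1], el[, 2])]
  }
  g
}

## Deterministic ordering shared by all path-returning functions:
## by length first, then lexicographic on the node-label sequence.
## Each undirected path is reported once, oriented from `from` to `to`.
order_paths <- function(paths) {
  if (length(paths) == 0) return(paths)
  lens <- vapply(paths, length, integer(1))
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(lens, keys, method = "radix")]
}

#' Enumerate simple paths between two nodes up to a length cutoff
#'
#' Returns every simple (no repeated node) path from `i` to `j` with at most
#' `K` edges, in deterministic order: sorted by length, then lexicographically
#' by node sequence. A single edge is a path of length 1.
#'
#' @param g support graph from [support_graph()].
#' @param i,j terminal node labels, `i != j`.
#' @param K maximum number of edges per path (`K >= 1`).
#' @return list of character vectors of node labels (possibly empty).
#' @export
enumerate_paths <- function(g, i, j, K) {
  stopifnot(K >= 1)
  if (identical(i, j)) stop("terminal nodes must differ (i == j)", call. = FALSE)
  labs <- igraph::V(g)$name
  label_index(labs, c(i, j))
  vp <- igraph::all_simple_paths(g, from = i, to = j, cutoff = K)
  paths <- lapply(vp, function(p) igraph::as_ids(p))
  order_paths(paths)
}

#' Count simple paths between a fixed pair in the complete graph
#'
#' Closed form for the number of simple `i`-`j` paths of length at most `K`
#' in the complete graph on `N` nodes: `sum_k (N-2)! / (N-1-k)!`. Used as an
#' enumeration oracle and to size worst-case (fully connected network) runs.
#'
#' @param N node count (`N >= 2`).
#' @param K length cutoff, `1 <= K <= N - 1`.
#' @return path count (numeric; exact for the sizes where enumeration is
#'   feasible).
#' @export
#' @examples
#' count_paths_complete_graph(4, 3)  # 5
count_paths_complete_graph <- function(N, K) {
  stopifnot(N >= 2, K >= 1)
  if (K >= N) stop("K must be at most N - 1: no simple path has more edges", call. = FALSE)
  k <- seq_len(K)
  # (N-2)! / (N-1-k)! = prod of (N-2)(N-3)...(N-k) falling factorial
  sum(vapply(k, function(kk) {
    if (kk == 1) 1 else prod(seq(N - 2, N - kk))
  }, numeric(1)))
}

#' Export a support graph as a weighted edge list
#'
#' @param g support graph.
#' @param path output TSV path (columns `node_a`, `node_b`,
#'   `partial_correlation`).
#' @return the edge-list data frame, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   partial_correlation = if (nrow(el) > 0) igraph::E(g)$weight else numeric(0),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a support graph as GraphML
#'
#' @param g support graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
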