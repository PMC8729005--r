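## Determinant cache for principal submatrices of the normalized precision
## matrix A. The same |A_{p*}| recurs across paths sharing a node set, and
## enumeration cost dominates otherwise. Determinants are kept in log space
## (all principal submatrices of a PD matrix have positive determinant);
## the empty (0 x 0) matrix has determinant 1, i.e. log-determinant 0.
new_det_cache <- function(A) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  n <- nrow(A)
  function(removed_idx) {
    if (length(removed_idx) >= n) return(0)
    key <- paste(removed_idx, collapse = ",")
    val <- env[[key]]
    if (is.null(val)) {
      sub <- if (length(removed_idx) == 0) A else A[-removed_idx, -removed_idx, drop = FALSE]
      val <- as.numeric(determinant(sub, logarithm = TRUE)$modulus)
      env[[key]] <- val
    }
    val
  }
}

#' Path product of partial correlations
#'
#' `tau_p` is the product of the partial correlations along the consecutive
#' edges of a path. It carries the sign of the path's contribution and
#' shrinks (in absolute value) as the path is extended, since every factor
#' has magnitude at most 1.
#'
#' @param P partial correlation matrix.
#' @param path character vector of at least two node labels.
#' @return signed scalar product.
#' @export
#' @examples
#' P <- diag(3); dimnames(P) <- list(c("a","b","c"), c("a","b","c"))
#' P["a","c"] <- P["c","a"] <- 0.4; P["c","b"] <- P["b","c"] <- 0.2
#' path_tau(P, c("a", "c", "b"))  # 0.08
path_tau <- function(P, path) {
  P <- ensure_labels(P)
  if (length(path) < 2) stop("a path needs at least two nodes", call. = FALSE)
  if (anyDuplicated(path)) stop("not a simple path: repeated node", call. = FALSE)
  idx <- label_index(node_labels(P), path)
  vals <- P[cbind(idx[-length(idx)], idx[-1])]
  if (any(vals == 0)) {
    warning("path traverses a zero partial correlation; it is not in the support graph",
            call. = FALSE)
  }
  prod(vals)
}

#' Determinant-weighted contribution of one path to a marginal correlation
#'
#' `gamma_p = tau_p * |A_{p*}| / sqrt(|A_{i*}| |A_{j*}|)`, where `A` is the
#' normalized precision matrix, `A_{p*}` deletes every node on the path
#' (terminals included) and `A_{i*}` deletes only terminal `i`. Summed over
#' all simple paths joining `i` and `j`, the `gamma_p` reconstruct the
#' marginal Pearson correlation exactly. The weighting determinants are
#' positive (principal submatrices of a positive definite matrix), so
#' `sign(gamma_p) = sign(tau_p)`.
#'
#' @inheritParams path_tau
#' @param validate validate `P` first.
#' @return signed scalar contribution.
#' @export
path_gamma <- function(P, path, validate = TRUE) {
  if (validate) P <- validate_pcor(P)
  P <- ensure_labels(P)
  A <- build_normalized_precision(P, validate = FALSE)
  ld <- new_det_cache(A)
  idx <- label_index(node_labels(P), path)
  tau <- path_tau(P, path)
  i <- idx[1]; j <- idx[length(idx)]
  tau * exp(ld(sort(idx)) - 0.5 * (ld(i) + ld(j)))
}

## Shared engine: gamma for a list of paths between one pair, using a caller
## supplied determinant cache so scans can share work across pairs.
gamma_for_paths <- function(P, paths, ld, labels = node_labels(P)) {
  if (length(paths) == 0) return(numeric(0))
  vapply(paths, function(path) {
    idx <- match(path, labels)
    tau <- prod(P[cbind(idx[-length(idx)], idx[-1])])
    if (tau == 0) return(0)
    tau * exp(ld(sort(idx)) - 0.5 * (ld(idx[1]) + ld(idx[length(idx)])))
  }, numeric(1))
}

format_path <- function(path) paste(path, collapse = "|")

#' Decompose a marginal correlation into path contributions
#'
#' Enumerates every simple path between `i` and `j` of length at most `K` in
#' the support graph and computes each path's signed contribution `gamma_p`.
#' With full enumeration (`K = N - 1`) the contributions sum exactly to the
#' marginal correlation `c_ij` implied by the model; smaller `K` truncates
#' the tail of long, weak paths.
#'
#' @param P partial correlation matrix.
#' @param i,j terminal node labels.
#' @param K length cutoff; default `NULL` means full enumeration (`N - 1`).
#' @param zero_threshold support-graph threshold, see [support_graph()].
#' @param validate validate `P` first (skip inside tight loops).
#' @return object of class `path_decomposition`: a data frame with columns
#'   `path` (labels joined by `|`), `length`, `tau`, `gamma`, plus attributes
#'   `pair`, `K`, `reconstructed` (sum of gamma). A disconnected pair yields
#'   zero rows and reconstructed correlation 0.
#' @export
decompose_correlation <- function(P, i, j, K = NULL, zero_threshold = 0,
                                  validate = TRUE) {
  if (validate) P <- validate_pcor(P)
  P <- ensure_labels(P)
  n <- nrow(P)
  if (is.null(K)) K <- n - 1
  g <- support_graph(P, zero_threshold)
  paths <- enumerate_paths(g, i, j, K)
  A <- build_normalized_precision(P, validate = FALSE)
  ld <- new_det_cache(A)
  gam <- gamma_for_paths(P, paths, ld)
  tau <- vapply(paths, function(path) {
    idx <- match(path, node_labels(P))
    prod(P[cbind(idx[-length(idx)], idx[-1])])
  }, numeric(1))
  out <- data.frame(path = vapply(paths, format_path, character(1)),
                    length = vapply(paths, length, integer(1)) - 1L,
                    tau = tau, gamma = gam, stringsAsFactors = FALSE)
  structure(out, class = c("path_decomposition", "data.frame"),
            pair = c(i, j), K = K, reconstructed = sum(gam))
}

#' @export
print.path_decomposition <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("Path decomposition of Cor(%s, %s), K = %d\n", pair[1], pair[2],
              attr(x, "K")))
  cat(sprintf("  %d path(s); reconstructed correlation = %.6g\n", nrow(x),
              attr(x, "reconstructed")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Pair-path subscores for a node pair
#'
#' Normalizes the absolute path contributions into scores
#' `s_p = |gamma_p| / sum_q |gamma_q|` over the paths of length at most `K`:
#' the fraction of the pair's marginal association attributable to each
#' path. Scores lie in `[0, 1]` and sum to 1 whenever any contribution is
#' nonzero.
#'
#' @inheritParams decompose_correlation
#' @return object of class `pps_table`: data frame with columns `path`,
#'   `length`, `tau`, `gamma`, `score`, `is_max`; attributes `pair`, `K`,
#'   `status` (`"ok"` or `"no_paths"`), `reconstructed`, and `cancellation`
#'   (`TRUE` when individual contributions cancel to a near-zero marginal
#'   correlation). A disconnected pair returns a zero-row table with status
#'   `"no_paths"` rather than dividing by zero.
#' @export
pps <- function(P, i, j, K = NULL, zero_threshold = 0, validate = TRUE) {
  dec <- decompose_correlation(P, i, j, K, zero_threshold, validate)
  total <- sum(abs(dec$gamma))
  if (nrow(dec) == 0 || total == 0) {
    out <- data.frame(path = character(0), length = integer(0),
                      tau = numeric(0), gamma = numeric(0),
                      score = numeric(0), is_max = logical(0))
    return(structure(out, class = c("pps_table", "data.frame"),
                     pair = attr(dec, "pair"), K = attr(dec, "K"),
                     status = "no_paths", reconstructed = attr(dec, "reconstructed"),
                     cancellation = FALSE))
  }
  score <- abs(dec$gamma) / total
  best <- which.max(score)  # rows are length-lex ordered, so ties break right
  out <- data.frame(path = dec$path, length = dec$length, tau = dec$tau,
                    gamma = dec$gamma, score = score,
                    is_max = seq_along(score) == best,
                    stringsAsFactors = FALSE)
  cancel <- abs(attr(dec, "reconstructed")) < 1e-12 * total
  structure(out, class = c("pps_table", "data.frame"),
            pair = attr(dec, "pair"), K = attr(dec, "K"), status = "ok",
            reconstructed = attr(dec, "reconstructed"), cancellation = cancel)
}

#' @export
print.pps_table <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("Pair-path subscores for (%s, %s), K = %d [%s]\n",
              pair[1], pair[2], attr(x, "K"), attr(x, "status")))
  if (isTRUE(attr(x, "cancellation"))) {
    cat("  note: path contributions cancel; marginal correlation ~ 0\n")
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Highest-scoring path between a pair of nodes
#'
#' @inheritParams pps
#' @return list with elements `path` (character vector of node labels),
#'   `score`, `length`, and `gamma`. Ties are broken by shortest length then
#'   lexicographic node order.
#' @export
max_pps <- function(P, i, j, K = NULL, zero_threshold = 0, validate = TRUE) {
  tab <- pps(P, i, j, K, zero_threshold, validate)
  if (attr(tab, "status") == "no_paths") {
    stop(sprintf("no path with nonzero contribution connects %s and %s (K = %d)",
                 i, j, attr(tab, "K")), call. = FALSE)
  }
  best <- which(tab$is_max)
  list(path = strsplit(tab$path[best], "|", fixed = TRUE)[[1]],
       score = tab$score[best], length = tab$length[best],
       gamma = tab$gamma[best])
}

#' Serialize a decomposition or subscore table to TSV
#'
#' One row per path: pair, path (`a|b|c`), length, tau, gamma and (for
#' subscore tables) score.
#'
#' @param x a `path_decomposition` or `pps_table`.
#' @param path output file path.
#' @return the written data frame, invisibly.
#' @export
write_pps_tsv <- function(x, path) {
  pair <- attr(x, "pair")
  df <- cbind(data.frame(node_a = pair[1], node_b = pair[2], K = attr(x, "K"),
                         stringsAsFactors = FALSE),
              as.data.frame(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Serialize a decomposition or subscore table to JSON
#'
#' @inheritParams write_pps_tsv
#' @return JSON string, invisibly; written to `path` if given.
#' @export
write_pps_json <- function(x, path = NULL) {
  payload <- list(pair = as.list(attr(x, "pair")), K = attr(x, "K"),
                  reconstructed_correlation = attr(x, "reconstructed"),
                  status = if (!is.null(attr(x, "status"))) attr(x, "status") else "ok",
                  cancellation = isTRUE(attr(x, "cancellation")),
                  entries = as.data.frame(x))
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
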