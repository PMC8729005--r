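#' Generate a random valid partial-correlation network
#'
#' Emulates the stated generative world: Erdos-Renyi edges with probability
#' `edge_prob` (default 0.2), edge partial correlations drawn uniformly from
#' `partial_range` (default `(-1, 1)`), non-edges exactly zero. Models whose
#' normalized precision matrix is not positive definite are rejected and
#' redrawn, which preserves the stated marginal distributions conditional on
#' acceptance.
#'
#' @param n_nodes node count.
#' @param edge_prob Bernoulli edge probability in `(0, 1]`.
#' @param partial_range interval (within `(-1, 1)`) for edge partials.
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param max_attempts rejection budget before giving up.
#' @param labels optional node labels (default `V1..Vn`).
#' @return a valid partial correlation matrix with attribute `attempts`.
#' @export
#' @examples
#' P <- random_ggm(10, seed = 1)
random_ggm <- function(n_nodes, edge_prob = 0.2, partial_range = c(-1, 1),
                       seed = NULL, max_attempts = 1000, labels = NULL) {
  stopifnot(n_nodes >= 2, edge_prob >= 0, edge_prob <= 1,
            length(partial_range) == 2, partial_range[1] < partial_range[2],
            partial_range[1] >= -1, partial_range[2] <= 1)
  if (is.null(labels)) labels <- paste0("V", seq_len(n_nodes))
  stopifnot(length(labels) == n_nodes)
  m <- n_nodes * (n_nodes - 1) / 2
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      vals <- stats::rbinom(m, 1, edge_prob) *
        stats::runif(m, partial_range[1], partial_range[2])
      P <- diag(n_nodes)
      P[upper.tri(P)] <- vals
      P <- P + t(P) - diag(n_nodes)
      diag(P) <- 1
      dimnames(P) <- list(labels, labels)
      A <- build_normalized_precision(P, validate = FALSE)
      if (min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) > .PD_TOL) {
        attr(P, "attempts") <- attempt
        return(P)
      }
    }
    stop(sprintf(paste0("no positive definite model found in %d attempts; ",
                        "try a narrower partial_range"), max_attempts),
         call. = FALSE)
  })
}

#' Sample Gaussian data from a partial-correlation network
#'
#' Draws `n` observations from a zero-mean multivariate normal whose
#' covariance is the correlation matrix implied by `P`, so every node is
#' marginally `N(0, 1)`.
#'
#' @param P valid partial correlation matrix.
#' @param n number of samples.
#' @param seed integer seed.
#' @return `n x p` data matrix with feature labels from `P` and sample ids
#'   `S1..Sn`.
#' @export
sample_gaussian <- function(P, n, seed = NULL) {
  P <- validate_pcor(P)
  C <- correlation_from_partial(P)
  L <- chol(C)
  p <- ncol(C)
  X <- with_seed(seed, matrix(stats::rnorm(n * p), n, p) %*% L)
  dimnames(X) <- list(paste0("S", seq_len(n)), node_labels(P))
  X
}

#' Expected path length of an Erdos-Renyi network
#'
#' Closed form `(log p - gamma) / log D + 1/2` with `gamma = 0.577` the
#' Euler-Mascheroni constant, `p` the node count and `D` the mean degree.
#' Used to judge whether a truncation length `K` of 4-5 exceeds typical path
#' lengths in a network of given size and density.
#'
#' @param p_nodes node count (`>= 2`).
#' @param mean_degree mean degree `D > 1`.
#' @return expected path length.
#' @export
#' @examples
#' er_expected_path_length(100, 2.4)  # ~5.10
er_expected_path_length <- function(p_nodes, mean_degree) {
  stopifnot(p_nodes >= 2)
  if (any(mean_degree <= 1)) {
    stop("mean degree must exceed 1 (log nonpositive otherwise)", call. = FALSE)
  }
  (log(p_nodes) - 0.577) / log(mean_degree) + 0.5
}

#' Mean degree at which an Erdos-Renyi network reaches a given expected path length
#'
#' Inverts the expected-path-length formula:
#' `D = exp((log p - gamma) / (L - 1/2))`.
#'
#' @param p_nodes node count.
#' @param target_length desired expected path length (`> 1/2`).
#' @return mean degree.
#' @export
#' @examples
#' round(er_mean_degree_for_length(100, 5), 1)  # 2.4
er_mean_degree_for_length <- function(p_nodes, target_length) {
  stopifnot(p_nodes >= 2, target_length > 0.5)
  exp((log(p_nodes) - 0.577) / (target_length - 0.5))
}
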