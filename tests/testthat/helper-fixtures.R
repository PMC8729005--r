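# Fixtures are built in code; no binary data anywhere.

labeled <- function(m, labels = letters[seq_len(nrow(m))]) {
  dimnames(m) <- list(labels, labels)
  m
}

# The worked three-node model: pi_ab = 0.3, pi_ac = 0.4, pi_bc = 0.2.
# Closed form: c_ab = (0.3 + 0.4*0.2) / (sqrt(1-0.2^2) * sqrt(1-0.4^2)).
three_node_P <- function() {
  P <- diag(3)
  P[1, 2] <- P[2, 1] <- 0.3
  P[1, 3] <- P[3, 1] <- 0.4
  P[2, 3] <- P[3, 2] <- 0.2
  labeled(P)
}

# chain a - b - c - ... with constant partial rho
chain_P <- function(k = 3, rho = 0.5) {
  P <- diag(k)
  for (i in seq_len(k - 1)) P[i, i + 1] <- P[i + 1, i] <- rho
  labeled(P)
}

# clique {a,b,c,d} (partials 0.25) plus a separate edge e - f (0.4):
# clique pairs have many competing paths, the pendant pair exactly one.
clique_plus_edge_P <- function() {
  P <- diag(6)
  P[1:4, 1:4] <- 0.25
  diag(P) <- 1
  P[5, 6] <- P[6, 5] <- 0.4
  labeled(P)
}

# Three-node marginal correlation closed form, the scalar oracle the generic
# determinant machinery must reproduce.
three_node_cor_closed_form <- function(P) {
  p12 <- P[1, 2]; p13 <- P[1, 3]; p23 <- P[2, 3]
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- (p12 + p13 * p23) / (sqrt(1 - p23^2) * sqrt(1 - p13^2))
  C[1, 3] <- C[3, 1] <- (p13 + p12 * p23) / (sqrt(1 - p23^2) * sqrt(1 - p12^2))
  C[2, 3] <- C[3, 2] <- (p23 + p12 * p13) / (sqrt(1 - p13^2) * sqrt(1 - p12^2))
  dimnames(C) <- dimnames(P)
  C
}

# brute-force simple-path enumeration by recursive extension, independent of
# igraph; oracle for enumerate_paths and the complete-graph count formula
brute_force_paths <- function(adj, i, j, K) {
  labs <- rownames(adj)
  out <- list()
  extend <- function(path) {
    tip <- path[length(path)]
    if (tip == j) {
      if (length(path) >= 2) out[[length(out) + 1]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= K) return(invisible())
    for (nb in labs[adj[tip, ] & !(labs %in% path)]) {
      extend(c(path, nb))
    }
  }
  extend(i)
  out
}
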