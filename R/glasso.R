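## Graphical lasso: L1-penalized sparse precision estimation by block
## coordinate descent (Friedman, Hastie & Tibshirani 2008, Biostatistics).
## Implemented here because the surrounding estimation contract needs exact
## zeros in the partial correlation estimate; only the off-diagonal is
## penalized and W is initialized at S + rho I, the usual convention.

glasso_fit <- function(S, rho, tol = 1e-5, max_iter = 500L,
                       inner_tol = 1e-8, inner_max = 1000L) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), rho >= 0)
  p <- nrow(S)
  if (p == 1) {
    return(list(w = S + rho, theta = matrix(1 / (S[1, 1] + rho), 1, 1),
                iterations = 0L, converged = TRUE))
  }
  if (rho < .Machine$double.eps) {
    # unpenalized limit: plain inversion of S
    theta <- solve(S)
    theta <- (theta + t(theta)) / 2
    return(list(w = S, theta = theta, iterations = 0L, converged = TRUE))
  }
  W <- S + diag(rho, p)
  B <- matrix(0, p - 1L, p)  # lasso coefficients per column subproblem
  off <- abs(S); diag(off) <- 0
  thr <- tol * max(mean(off), .Machine$double.eps)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    W_prev <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      V <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      # coordinate descent on 0.5 b'Vb - s12'b + rho ||b||_1
      for (sweep in seq_len(inner_max)) {
        dmax <- 0
        for (k in seq_len(p - 1L)) {
          r <- s12[k] - sum(V[k, ] * beta) + V[k, k] * beta[k]
          bk <- sign(r) * max(abs(r) - rho, 0) / V[k, k]
          if (bk != beta[k]) {
            dmax <- max(dmax, abs(bk - beta[k]))
            beta[k] <- bk
          }
        }
        if (dmax < inner_tol) break
      }
      B[, j] <- beta
      w12 <- as.numeric(V %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_prev)) < thr) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("graphical lasso did not converge (lambda = %.4g, %d iterations)",
                 rho, iter), call. = FALSE)
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    beta <- B[, j]
    t22 <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    theta[j, j] <- t22
    theta[idx, j] <- -beta * t22
  }
  # the converged zero pattern is symmetric; enforce it exactly so support
  # graphs see true zeros, then symmetrize values against float drift
  zero <- theta == 0 | t(theta) == 0
  theta <- (theta + t(theta)) / 2
  theta[zero] <- 0
  dimnames(theta) <- dimnames(S)
  dimnames(W) <- dimnames(S)
  list(w = W, theta = theta, iterations = iter, converged = TRUE)
}

## Held-out Gaussian log-likelihood (up to constants) of a fitted precision:
## log det Theta - tr(S_test Theta)
gaussian_loglik <- function(theta, S_test) {
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  as.numeric(ld$modulus) - sum(S_test * theta)
}
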