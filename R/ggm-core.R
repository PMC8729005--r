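#' Validate a partial correlation matrix
#'
#' A partial correlation matrix `P` defines a Gaussian graphical model: it is
#' symmetric with unit diagonal, entries in `[-1, 1]`, and its associated
#' normalized precision matrix (unit diagonal, off-diagonals `-pi_ij`) must be
#' positive definite for the model to be a valid multivariate normal.
#'
#' @param P square numeric matrix of partial correlations, with row/column
#'   labels (unlabeled input is labeled `V1..Vn`).
#' @param require_pd check positive definiteness of the normalized precision.
#' @param tol symmetry / unit-diagonal tolerance.
#' @return `P` with labels enforced, invisibly usable downstream.
#' @export
#' @examples
#' P <- diag(3); dimnames(P) <- list(letters[1:3], letters[1:3])
#' validate_pcor(P)
validate_pcor <- function(P, require_pd = TRUE, tol = 1e-8) {
  if (!is.matrix(P) || !is.numeric(P)) stop("P must be a numeric matrix", call. = FALSE)
  if (nrow(P) != ncol(P)) stop("P must be square", call. = FALSE)
  P <- ensure_labels(P)
  lab <- node_labels(P)
  bad <- which(abs(P - t(P)) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("P is not symmetric: entry (%s, %s) differs from its transpose by %.3g",
                 lab[bad[1, 1]], lab[bad[1, 2]],
                 abs(P[bad[1, 1], bad[1, 2]] - P[bad[1, 2], bad[1, 1]])),
         call. = FALSE)
  }
  dbad <- which(abs(diag(P) - 1) > tol)
  if (length(dbad) > 0) {
    stop(sprintf("P must have unit diagonal: entry (%s, %s) is %.6g",
                 lab[dbad[1]], lab[dbad[1]], P[dbad[1], dbad[1]]), call. = FALSE)
  }
  if (any(abs(P) > 1 + tol)) {
    bad <- which(abs(P) > 1 + tol, arr.ind = TRUE)[1, ]
    stop(sprintf("partial correlation out of [-1, 1]: entry (%s, %s) = %.6g",
                 lab[bad[1]], lab[bad[2]], P[bad[1], bad[2]]), call. = FALSE)
  }
  if (require_pd) {
    A <- build_normalized_precision(P, validate = FALSE)
    ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= .PD_TOL) {
      stop(sprintf(paste0("invalid model: normalized precision matrix is not ",
                          "positive definite (min eigenvalue %.3g <= %.0e)"),
                   ev, .PD_TOL), call. = FALSE)
    }
  }
  P
}

#' Build the normalized precision matrix of a partial correlation matrix
#'
#' The normalized precision matrix `A` has `a_ii = 1` and `a_ij = -pi_ij` for
#' `i != j`. It is the object inverted when converting partial correlations to
#' marginal correlations, and the matrix whose principal-submatrix
#' determinants weight the path decomposition.
#'
#' @param P partial correlation matrix.
#' @param validate run [validate_pcor()] first (without the positive
#'   definiteness check, which would be circular here).
#' @return labeled matrix `A` of the same dimension.
#' @export
build_normalized_precision <- function(P, validate = TRUE) {
  if (validate) P <- validate_pcor(P, require_pd = FALSE)
  A <- -P
  diag(A) <- 1
  ensure_labels(A)
}

## Symmetric PD inversion; output symmetrized against float drift before it
## feeds determinant ratios downstream.
.invert_pd <- function(A, what = "matrix") {
  ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= .PD_TOL) {
    stop(sprintf("invalid model: %s is not positive definite (min eigenvalue %.3g <= %.0e)",
                 what, ev, .PD_TOL), call. = FALSE)
  }
  inv <- chol2inv(chol(A))
  dimnames(inv) <- dimnames(A)
  (inv + t(inv)) / 2
}

#' Marginal correlation matrix implied by a partial correlation matrix
#'
#' Inverts the normalized precision matrix and rescales to unit diagonal:
#' `C = D^-1 A^-1 D^-1` with `d_ii = sqrt((A^-1)_ii)`. This is the exact
#' map from a Gaussian graphical model's conditional structure to the
#' marginal Pearson correlations it implies, and serves as the independent
#' oracle for the path decomposition.
#'
#' @param P partial correlation matrix (validated).
#' @return labeled correlation matrix with unit diagonal.
#' @export
#' @examples
#' P <- diag(3)
#' P[1, 2] <- P[2, 1] <- 0.3; P[1, 3] <- P[3, 1] <- 0.4; P[2, 3] <- P[3, 2] <- 0.2
#' dimnames(P) <- list(c("a","b","c"), c("a","b","c"))
#' correlation_from_partial(P)["a", "b"]  # 0.4232...
correlation_from_partial <- function(P) {
  P <- validate_pcor(P, require_pd = FALSE)
  A <- build_normalized_precision(P, validate = FALSE)
  Ainv <- .invert_pd(A, "normalized precision matrix")
  d <- sqrt(diag(Ainv))
  C <- Ainv / tcrossprod(d)
  diag(C) <- 1
  ensure_labels((C + t(C)) / 2)
}

#' Partial correlation matrix from a marginal correlation matrix
#'
#' Inverts `C`, normalizes by the square roots of the diagonal of the inverse,
#' and flips the signs of the off-diagonal entries. Round-trips with
#' [correlation_from_partial()] to numerical tolerance.
#'
#' @param C correlation matrix (symmetric, unit diagonal, invertible).
#' @param max_condition condition-number threshold above which estimation is
#'   refused with advice to use regularization.
#' @return labeled partial correlation matrix.
#' @export
partial_from_correlation <- function(C, max_condition = 1e12) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("C must be a square matrix", call. = FALSE)
  C <- ensure_labels(C)
  kap <- kappa(C, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop(sprintf(paste0("correlation matrix is singular or near-singular ",
                        "(condition number %.3g): use a regularized estimator ",
                        "such as estimate_glasso()"), kap), call. = FALSE)
  }
  Omega <- solve(C)
  Omega <- (Omega + t(Omega)) / 2
  partial_from_precision(Omega, check_pd = FALSE)
}

#' Partial correlations from a precision matrix
#'
#' Standard normalization: `pi_ij = -omega_ij / sqrt(omega_ii * omega_jj)`,
#' unit diagonal.
#'
#' @param Omega symmetric positive definite precision matrix.
#' @param check_pd verify positive definiteness (default `TRUE`).
#' @return labeled partial correlation matrix.
#' @export
partial_from_precision <- function(Omega, check_pd = TRUE) {
  if (!is.matrix(Omega) || nrow(Omega) != ncol(Omega)) {
    stop("Omega must be a square matrix", call. = FALSE)
  }
  Omega <- ensure_labels(Omega)
  if (max(abs(Omega - t(Omega))) > 1e-8) stop("Omega must be symmetric", call. = FALSE)
  if (check_pd) {
    ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= .PD_TOL) {
      stop(sprintf("Omega is not positive definite (min eigenvalue %.3g)", ev),
           call. = FALSE)
    }
  }
  d <- sqrt(diag(Omega))
  if (any(d <= 0)) stop("Omega has nonpositive diagonal entries", call. = FALSE)
  P <- -Omega / tcrossprod(d)
  diag(P) <- 1
  ensure_labels((P + t(P)) / 2)
}
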