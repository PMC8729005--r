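## Estimation of the partial-correlation network from a samples x features
## data matrix, by inverse Pearson correlation (dense, n > p) or
## cross-validated graphical lasso (sparse). Both return an `estimated_ggm`
## whose partial correlation matrix passes validate_pcor().

as_data_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric samples x features matrix", call. = FALSE)
  }
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
  if (anyDuplicated(colnames(data))) {
    stop("duplicate feature names: ",
         paste(unique(colnames(data)[duplicated(colnames(data))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data)) stop("data contains missing values; preprocess first", call. = FALSE)
  if (nrow(data) < 3) stop("need at least 3 samples", call. = FALSE)
  data
}

new_estimated_ggm <- function(pcor, method, lambda = NA_real_, n = NA_integer_,
                              extra = list()) {
  structure(c(list(pcor = pcor, method = method, lambda = lambda, n = n), extra),
            class = "estimated_ggm")
}

#' @export
print.estimated_ggm <- function(x, ...) {
  p <- nrow(x$pcor)
  edges <- sum(abs(x$pcor[upper.tri(x$pcor)]) > 0)
  cat(sprintf("Estimated GGM (%s): %d nodes, %d edges, n = %s%s\n",
              x$method, p, edges, x$n,
              if (is.finite(x$lambda)) sprintf(", lambda = %.4g", x$lambda) else ""))
  invisible(x)
}

## Accept either an estimated_ggm or a bare partial correlation matrix in
## downstream workflows.
get_pcor <- function(x) {
  if (inherits(x, "estimated_ggm")) x$pcor else ensure_labels(x)
}

#' Residualize features on covariates
#'
#' Replaces each feature by its residual after ordinary least-squares
#' adjustment for all covariates (plus intercept), then centers and scales
#' each residualized feature to unit variance. This is the standard way to
#' control for demographic or technical variables before estimating a
#' partial-correlation network.
#'
#' @param data samples x features numeric matrix (rownames = sample ids).
#' @param covariates samples x covariates numeric matrix with matching
#'   sample ids (or matching row order when ids are absent).
#' @return adjusted data matrix, same shape as `data`. Features whose
#'   residual is numerically zero (feature collinear with the covariates)
#'   trigger a warning naming them.
#' @export
adjust_covariates <- function(data, covariates) {
  data <- as_data_matrix(data)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.null(rownames(data)) && !is.null(rownames(covariates))) {
    if (!setequal(rownames(data), rownames(covariates))) {
      stop("sample ids of data and covariates do not match", call. = FALSE)
    }
    covariates <- covariates[rownames(data), , drop = FALSE]
  } else if (nrow(covariates) != nrow(data)) {
    stop("covariates must have one row per sample", call. = FALSE)
  }
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("Z", seq_len(ncol(covariates)))
  }
  # constant covariates are absorbed by the intercept, not an error
  keep <- apply(covariates, 2, function(z) stats::sd(z) > 0)
  covariates <- covariates[, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qx, data)
  sds <- apply(res, 2, stats::sd)
  dead <- sds < 1e-12
  if (any(dead)) {
    warning("feature(s) fully explained by covariates (zero residual): ",
            paste(colnames(data)[dead], collapse = ", "), call. = FALSE)
    sds[dead] <- 1
  }
  out <- scale(res, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  dimnames(out) <- dimnames(data)
  out
}

#' Estimate a GGM by inverting the Pearson correlation matrix
#'
#' The unpenalized estimator: invert the sample Pearson correlation matrix,
#' normalize, and flip off-diagonal signs. Requires `n > p`; the resulting
#' support graph is generically complete, so downstream path enumeration
#' needs a length cutoff for feasibility.
#'
#' @param data samples x features numeric matrix.
#' @return an `estimated_ggm` with method `"inverse_pearson"`.
#' @export
estimate_inverse_pearson <- function(data) {
  data <- as_data_matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n <= p) {
    stop(sprintf(paste0("inverse Pearson estimation needs n > p (got n = %d, ",
                        "p = %d): use estimate_glasso() for a regularized fit"),
                 n, p), call. = FALSE)
  }
  C <- stats::cor(data)
  P <- partial_from_correlation(C)
  new_estimated_ggm(validate_pcor(P), "inverse_pearson", n = n)
}

#' Cross-validation for the graphical lasso penalty
#'
#' Selects the penalty maximizing the mean held-out Gaussian log-likelihood
#' (`log det Theta - tr(S_test Theta)`) over folds. Fold assignment is
#' deterministic given the seed.
#'
#' @param data samples x features numeric matrix (standardized internally).
#' @param folds number of folds (default 5).
#' @param grid penalty grid; default 30 log-spaced values spanning
#'   `[1e-3, 1] * max |off-diagonal covariance|` of the standardized data.
#' @param seed integer seed for fold assignment.
#' @return selected penalty, with attribute `cv` holding the grid and mean
#'   held-out log-likelihoods.
#' @export
select_lambda_cv <- function(data, folds = 5, grid = NULL, seed = 1) {
  data <- as_data_matrix(data)
  n <- nrow(data)
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  if (n < 2 * folds) {
    stop(sprintf("degenerate folds: %d samples cannot fill %d folds with >= 2 each",
                 n, folds), call. = FALSE)
  }
  Z <- scale(data)
  if (is.null(grid)) {
    S <- stats::cov(Z)
    smax <- max(abs(S[upper.tri(S)]))
    grid <- exp(seq(log(1e-3 * smax), log(smax), length.out = 30))
  }
  grid <- sort(grid)
  assignment <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  score <- vapply(grid, function(lam) {
    ll <- vapply(seq_len(folds), function(f) {
      train <- Z[assignment != f, , drop = FALSE]
      test <- Z[assignment == f, , drop = FALSE]
      fit <- glasso_fit(stats::cov(train), lam)
      gaussian_loglik(fit$theta, stats::cov(test))
    }, numeric(1))
    mean(ll)
  }, numeric(1))
  best <- grid[which.max(score)]
  attr(best, "cv") <- list(grid = grid, mean_loglik = score, folds = folds,
                           seed = seed)
  best
}

#' Estimate a sparse GGM by graphical lasso
#'
#' L1-penalized precision estimation producing exact zero partial
#' correlations; features are standardized first so the penalty is
#' scale-free. With `lambda = "cv"` the penalty is chosen by
#' [select_lambda_cv()].
#'
#' @param data samples x features numeric matrix.
#' @param lambda nonnegative penalty, or `"cv"` for cross-validated choice.
#' @param folds,grid,seed passed to [select_lambda_cv()] when `lambda = "cv"`.
#' @return an `estimated_ggm` with method `"glasso"`, the penalty used, and
#'   (for CV fits) the CV trace in `$cv`.
#' @export
estimate_glasso <- function(data, lambda = "cv", folds = 5, grid = NULL,
                            seed = 1) {
  data <- as_data_matrix(data)
  n <- nrow(data)
  cv <- NULL
  if (identical(lambda, "cv")) {
    lambda <- select_lambda_cv(data, folds = folds, grid = grid, seed = seed)
    cv <- attr(lambda, "cv")
    lambda <- as.numeric(lambda)
  }
  stopifnot(is.numeric(lambda), lambda >= 0)
  Z <- scale(data)
  S <- stats::cov(Z)
  fit <- glasso_fit(S, lambda)
  P <- partial_from_precision(fit$theta, check_pd = FALSE)
  # exact zeros in theta must survive the normalization
  P[fit$theta == 0 & row(P) != col(P)] <- 0
  new_estimated_ggm(validate_pcor(P), "glasso", lambda = lambda, n = n,
                    extra = list(cv = cv, iterations = fit$iterations))
}
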