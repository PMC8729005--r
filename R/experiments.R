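## The two simulation experiments: path-identification success rate over
## sample size (estimator comparison) and truncation (K) sensitivity of the
## estimated maximum subscore.

## Truth table for a simulated model: per connected pair, the best path
## under full enumeration, its length, and the smallest |partial| it
## traverses (the quantity that governs identification difficulty).
true_scan <- function(P_true) {
  scan <- scan_core(P_true, K = NULL, pairs = NULL, zero_threshold = 0)
  if (nrow(scan) == 0) return(scan)
  scan$min_abs_partial <- vapply(seq_len(nrow(scan)), function(r) {
    nodes <- strsplit(scan$path[r], "|", fixed = TRUE)[[1]]
    min(abs(P_true[cbind(nodes[-length(nodes)], nodes[-1])]))
  }, numeric(1))
  scan
}

#' Success rate of maximum-PPS path identification over sample size
#'
#' For each pair of connected nodes in a known model, repeatedly samples
#' data, estimates the network, and checks whether the estimated
#' highest-scoring path equals the true one. Results are stratifiable by the
#' true path's length and by the smallest absolute partial correlation it
#' contains.
#'
#' @param P_true true partial correlation matrix.
#' @param n_grid sample sizes.
#' @param reps replicate datasets per sample size (default 100).
#' @param K length cutoff used for the estimated scan (default 4).
#' @param estimator `"inverse_pearson"`, `"glasso_cv"`, or `"oracle"` (plugs
#'   the truth back in; success must be 1).
#' @param seed global seed; replicate streams are derived from it.
#' @param folds,grid graphical-lasso CV controls.
#' @return data frame, one row per pair x n x replicate: `estimator`, `n`,
#'   `rep`, `node_a`, `node_b`, `success` (NA when the estimator failed on
#'   that replicate), `true_length`, `min_abs_partial`. Attribute
#'   `n_estimator_failures` counts excluded replicates.
#' @export
success_rate_experiment <- function(P_true, n_grid, reps = 100, K = 4,
                                    estimator = c("inverse_pearson", "glasso_cv", "oracle"),
                                    seed = 1, folds = 5, grid = NULL) {
  estimator <- match.arg(estimator)
  P_true <- validate_pcor(P_true)
  truth <- true_scan(P_true)
  if (nrow(truth) == 0) stop("the true model has no connected pairs", call. = FALSE)
  pairs <- as.matrix(truth[, c("node_a", "node_b")])
  out <- list()
  failures <- 0L
  for (n in n_grid) {
    for (r in seq_len(reps)) {
      sub_seed <- derive_seed(seed, paste(estimator, n, r))
      est <- tryCatch({
        if (estimator == "oracle") {
          P_true
        } else {
          data <- sample_gaussian(P_true, n, seed = sub_seed)
          if (estimator == "inverse_pearson") {
            estimate_inverse_pearson(data)$pcor
          } else {
            estimate_glasso(data, lambda = "cv", folds = folds, grid = grid,
                            seed = derive_seed(sub_seed, "cv"))$pcor
          }
        }
      }, error = function(e) NULL)
      if (is.null(est)) {
        failures <- failures + 1L
        success <- rep(NA, nrow(truth))
      } else {
        sc <- scan_core(est, K = K, pairs = pairs, zero_threshold = 0)
        key_est <- pair_key(sc$node_a, sc$node_b)
        key_true <- pair_key(truth$node_a, truth$node_b)
        est_path <- sc$path[match(key_true, key_est)]
        # a pair disconnected in the estimate cannot match the true path
        success <- !is.na(est_path) & est_path == truth$path
      }
      out[[length(out) + 1]] <- data.frame(
        estimator = estimator, n = n, rep = r,
        node_a = truth$node_a, node_b = truth$node_b, success = success,
        true_length = truth$length, min_abs_partial = truth$min_abs_partial,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, n_estimator_failures = failures, K = K, seed = seed)
}

#' Summarize a success-rate experiment per pair and sample size
#'
#' @param result output of [success_rate_experiment()].
#' @return data frame of per-pair, per-n success fractions with replicate
#'   counts.
#' @export
summarize_success <- function(result) {
  agg <- stats::aggregate(success ~ node_a + node_b + n + true_length + min_abs_partial,
                          data = result, FUN = function(s) mean(s, na.rm = TRUE))
  cnt <- stats::aggregate(success ~ node_a + node_b + n, data = result,
                          FUN = function(s) sum(!is.na(s)))
  names(cnt)[names(cnt) == "success"] <- "replicates"
  merge(agg, cnt, by = c("node_a", "node_b", "n"), sort = TRUE)
}

#' Truncation sensitivity of the estimated maximum subscore
#'
#' Measures the percent error `|shat^K_pmax - s_pmax| / s_pmax` of the
#' truncated, estimated subscore of each pair's true best path, across
#' sample sizes and cutoffs `K`. Path enumeration runs on the true support
#' graph with estimated partial correlations plugged in, so that the largest
#' `K` corresponds exactly to the untruncated estimator; pairs with any
#' connecting path longer than `max(K_grid)` are excluded (as are pairs with
#' a zero true score, with a log entry via the `n_excluded` attribute).
#'
#' @param P_true true partial correlation matrix.
#' @param n_grid sample sizes.
#' @param K_grid cutoffs (default 2:6).
#' @param reps replicates per sample size (default 100).
#' @param seed global seed.
#' @param estimator `"inverse_pearson"`, or `"oracle"` to plug the truth back
#'   in (percent error must then vanish at `K = max(K_grid)`).
#' @return data frame, one row per pair x n x K x replicate, with columns
#'   `n`, `K`, `rep`, `node_a`, `node_b`, `pmax_length`, `percent_error`.
#' @export
k_sensitivity_experiment <- function(P_true, n_grid, K_grid = 2:6, reps = 100,
                                     seed = 1,
                                     estimator = c("inverse_pearson", "oracle")) {
  estimator <- match.arg(estimator)
  P_true <- validate_pcor(P_true)
  labs <- node_labels(P_true)
  Kmax <- max(K_grid)
  g <- support_graph(P_true, 0)
  A_true <- build_normalized_precision(P_true, validate = FALSE)
  ld_true <- new_det_cache(A_true)
  ordered <- sort(labs, method = "radix")
  cand <- t(utils::combn(ordered, 2))
  jobs <- list()
  n_excluded <- 0L
  for (r in seq_len(nrow(cand))) {
    a <- cand[r, 1]; b <- cand[r, 2]
    paths <- enumerate_paths(g, a, b, length(labs) - 1)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1)) - 1L
    if (max(lens) > Kmax) {  # truncation would not be exact for this pair
      n_excluded <- n_excluded + 1L
      next
    }
    gam <- gamma_for_paths(P_true, paths, ld_true, labels = labs)
    total <- sum(abs(gam))
    if (total == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    s <- abs(gam) / total
    best <- which.max(s)
    jobs[[length(jobs) + 1]] <- list(a = a, b = b, paths = paths, lens = lens,
                                     best = best, s_true = s[best],
                                     pmax_length = lens[best])
  }
  if (length(jobs) == 0) stop("no eligible pairs after exclusions", call. = FALSE)
  out <- list()
  for (n in n_grid) {
    for (r in seq_len(reps)) {
      Phat <- if (estimator == "oracle") P_true else {
        data <- sample_gaussian(P_true, n, seed = derive_seed(seed, paste("ks", n, r)))
        estimate_inverse_pearson(data)$pcor
      }
      Ahat <- build_normalized_precision(Phat, validate = FALSE)
      ld_hat <- new_det_cache(Ahat)
      for (job in jobs) {
        gam_hat <- abs(gamma_for_paths(Phat, job$paths, ld_hat, labels = labs))
        for (K in K_grid) {
          keep <- job$lens <= K
          denom <- sum(gam_hat[keep])
          shat <- if (job$pmax_length <= K && denom > 0) gam_hat[job$best] / denom else 0
          out[[length(out) + 1]] <- data.frame(
            n = n, K = K, rep = r, node_a = job$a, node_b = job$b,
            pmax_length = job$pmax_length,
            percent_error = abs(shat - job$s_true) / job$s_true,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, n_excluded = n_excluded, seed = seed)
}

#' Summarize a truncation-sensitivity experiment
#'
#' @param result output of [k_sensitivity_experiment()].
#' @return data frame of mean, median and SD percent error per `n`, `K` and
#'   true-path-length stratum, with replicate counts.
#' @export
summarize_percent_error <- function(result) {
  agg <- stats::aggregate(percent_error ~ n + K + pmax_length, data = result,
                          FUN = function(x) c(mean = mean(x), median = stats::median(x),
                                              sd = stats::sd(x), reps = length(x)))
  cbind(agg[, c("n", "K", "pmax_length")], as.data.frame(agg$percent_error))
}
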