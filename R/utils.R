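#' @keywords internal
"_PACKAGE"

## Minimum eigenvalue above which a normalized precision matrix is declared
## positive definite. Separates genuine model invalidity from float noise.
.PD_TOL <- 1e-10

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to run without touching the RNG.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a global seed
#'
#' Every stochastic step in a pipeline run draws its stream from the single
#' top-level seed via a named offset, so independent components (folds,
#' bootstrap, simulator) are reproducible yet decoupled.
#'
#' @param seed integer global seed.
#' @param name character substream label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "bootstrap")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h) %% (2^31 - 1))
}

## Shared label bookkeeping: matrices carry mandatory dimnames; positional
## indices never leave the package.
node_labels <- function(m) {
  lab <- rownames(m)
  if (is.null(lab)) {
    lab <- paste0("V", seq_len(nrow(m)))
  }
  lab
}

ensure_labels <- function(m) {
  lab <- node_labels(m)
  dimnames(m) <- list(lab, lab)
  m
}

label_index <- function(labels, node) {
  idx <- match(node, labels)
  if (anyNA(idx)) {
    stop("unknown node label(s): ", paste(node[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}
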