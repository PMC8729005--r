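## CSV readers/writers. Data CSV: header row of feature names, one row per
## sample, optional leading non-numeric sample-id column. Matrix CSV: first
## row and first column carry node labels.

#' Read a samples x features data matrix from CSV
#'
#' @param path CSV file with a header of unique feature names; an optional
#'   first column of non-numeric sample ids is used as rownames.
#' @return numeric matrix with sample rownames and feature colnames.
#' @export
read_data_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged CSV: line %d has %d field(s), expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 1 && !is.numeric(df[[1]])) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- ids
  }
  dup <- colnames(df)[duplicated(colnames(df))]
  if (length(dup) > 0) {
    stop("duplicate feature name(s) in header: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) & !is.na(df[[j]]))[1]
      stop(sprintf("non-numeric cell in column '%s' (data row %s)",
                   colnames(df)[j], bad), call. = FALSE)
    }
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    rows <- which(apply(m, 1, anyNA))
    stop("missing values in data row(s): ", paste(rows, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  m
}

#' Write a data matrix to CSV at full float precision
#'
#' Values are formatted with 17 significant digits so that a write/read
#' round trip is bit-lossless.
#'
#' @param data numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_data_csv <- function(data, path) {
  data <- as_data_matrix(data)
  header <- paste(c("sample_id", colnames(data)), collapse = ",")
  body <- vapply(seq_len(nrow(data)), function(i) {
    paste(c(rownames(data)[i], sprintf("%.17g", data[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labeled partial correlation matrix from CSV
#'
#' First row and first column are node labels. The matrix is validated:
#' squareness, symmetry to `1e-8`, unit diagonal, and positive definiteness
#' of the normalized precision matrix.
#'
#' @param path CSV file path.
#' @param require_pd validate positive definiteness (default `TRUE`).
#' @return validated partial correlation matrix.
#' @export
read_partial_matrix_csv <- function(path, require_pd = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix is not square: %d rows, %d columns", nrow(m), ncol(m)),
         call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row labels do not match column labels", call. = FALSE)
  }
  storage.mode(m) <- "double"
  validate_pcor(m, require_pd = require_pd)
}

#' Write a labeled matrix to CSV at full float precision
#'
#' @param m labeled square matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  m <- ensure_labels(m)
  header <- paste(c("", colnames(m)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
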