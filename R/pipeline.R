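## Reproducible run driver binding the modules together, plus the thin
## command-line front end (inst/cli/pairpath). One global seed is fanned out
## to named substreams; the full config is echoed into run metadata.

`%||%` <- function(a, b) if (is.null(a)) b else a

load_model <- function(config, meta) {
  if (!is.null(config$matrix)) {
    meta$log <- c(meta$log, "matrix input: estimation stage skipped")
    list(ggm = read_partial_matrix_csv(config$matrix), meta = meta)
  } else if (!is.null(config$data)) {
    data <- read_data_csv(config$data)
    if (!is.null(config$covariates)) {
      data <- adjust_covariates(data, read_data_csv(config$covariates))
      meta$log <- c(meta$log, "covariate adjustment applied")
    }
    est <- estimate_from_config(data, config)
    meta$log <- c(meta$log,
                  sprintf("estimated GGM: method=%s n=%d p=%d lambda=%s",
                          est$method, nrow(data), ncol(data),
                          format(est$lambda)))
    list(ggm = est, data = data, meta = meta)
  } else {
    stop("config needs either 'matrix' or 'data'", call. = FALSE)
  }
}

estimate_from_config <- function(data, config) {
  estimator <- config$estimator %||% "glasso"
  if (estimator == "inverse_pearson") {
    estimate_inverse_pearson(data)
  } else if (estimator == "glasso") {
    lambda <- config$lambda %||% "cv"
    if (!identical(lambda, "cv")) lambda <- as.numeric(lambda)
    estimate_glasso(data, lambda = lambda, folds = config$cv_folds %||% 5,
                    seed = derive_seed(config$seed %||% 1, "cv-folds"))
  } else {
    stop("unknown estimator: ", estimator, call. = FALSE)
  }
}

#' Run a configured analysis end to end
#'
#' Dispatches on `config$command` (`estimate`, `decompose`, `pps`, `scan`,
#' `compare`, `bootstrap`, `simulate`, `benchmark`), reads the configured
#' inputs, runs the corresponding module, and serializes the results plus a
#' JSON metadata file (package version, config echo, seed, timings) into
#' `config$output`. Identical config and seed give identical outputs.
#'
#' @param config named list; see the package vignette and the `pairpath`
#'   command-line help for the fields each command uses (`data`, `matrix`,
#'   `covariates`, `estimator`, `lambda`, `cv_folds`, `k`, `pair`, `classes`,
#'   `boot_reps`, `seed`, `zero_threshold`, `n_nodes`, `edge_prob`,
#'   `n_samples`, `output`).
#' @return list with `outputs` (paths written) and `results` (in-memory
#'   objects), invisibly.
#' @export
run_pipeline <- function(config) {
  command <- config$command %||% stop("config$command is required", call. = FALSE)
  out_dir <- config$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  K <- if (!is.null(config$k)) as.integer(config$k) else NULL
  zt <- as.numeric(config$zero_threshold %||% 0)
  meta <- list(package = "pairpath",
               version = as.character(utils::packageVersion("pairpath")),
               command = command, seed = seed, config = config,
               log = character())
  started <- Sys.time()
  outputs <- character()
  results <- list()
  path_for <- function(name) file.path(out_dir, name)

  if (command == "estimate") {
    lm <- load_model(config, meta); meta <- lm$meta
    P <- get_pcor(lm$ggm)
    write_matrix_csv(P, path_for("partial_correlations.csv"))
    write_edge_list(support_graph(P, zt), path_for("edges.tsv"))
    write_graphml(support_graph(P, zt), path_for("network.graphml"))
    outputs <- c(outputs, path_for("partial_correlations.csv"),
                 path_for("edges.tsv"), path_for("network.graphml"))
    results$ggm <- lm$ggm
  } else if (command %in% c("decompose", "pps")) {
    lm <- load_model(config, meta); meta <- lm$meta
    pair <- config$pair %||% stop("config$pair is required", call. = FALSE)
    P <- get_pcor(lm$ggm)
    obj <- if (command == "decompose") {
      decompose_correlation(P, pair[1], pair[2], K, zero_threshold = zt)
    } else {
      pps(P, pair[1], pair[2], K, zero_threshold = zt)
    }
    meta$log <- c(meta$log, sprintf("pair (%s, %s): %d path(s) enumerated",
                                    pair[1], pair[2], nrow(obj)))
    write_pps_tsv(obj, path_for(paste0(command, ".tsv")))
    write_pps_json(obj, path_for(paste0(command, ".json")))
    outputs <- c(outputs, path_for(paste0(command, ".tsv")),
                 path_for(paste0(command, ".json")))
    results[[command]] <- obj
  } else if (command == "scan") {
    lm <- load_model(config, meta); meta <- lm$meta
    scan <- max_pps_scan(lm$ggm, K = K, zero_threshold = zt)
    meta$log <- c(meta$log, sprintf("scan: %d connected pair(s), %d disconnected",
                                    nrow(scan), attr(scan, "n_disconnected")))
    utils::write.table(as.data.frame(scan), path_for("scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, path_for("scan.tsv"))
    if (!is.null(config$classes)) {
      cls <- utils::read.csv(config$classes, stringsAsFactors = FALSE)
      class_map <- stats::setNames(cls[[2]], cls[[1]])
      summ <- edge_class_pps(lm$ggm, K = K, class_map = class_map,
                             zero_threshold = zt)
      writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA),
                 path_for("edge_classes.json"))
      outputs <- c(outputs, path_for("edge_classes.json"))
      results$edge_classes <- summ
    }
    results$scan <- scan
  } else if (command == "compare") {
    cfg_a <- config; cfg_a$matrix <- config$matrix_a; cfg_a$data <- config$data_a
    cfg_b <- config; cfg_b$matrix <- config$matrix_b; cfg_b$data <- config$data_b
    lm_a <- load_model(cfg_a, meta); meta <- lm_a$meta
    lm_b <- load_model(cfg_b, meta); meta <- lm_b$meta
    diff <- condition_difference(max_pps_scan(lm_a$ggm, K = K, zero_threshold = zt),
                                 max_pps_scan(lm_b$ggm, K = K, zero_threshold = zt))
    utils::write.table(diff, path_for("differences.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, path_for("differences.tsv"))
    results$differences <- diff
  } else if (command == "bootstrap") {
    if (is.null(config$data)) stop("bootstrap requires config$data", call. = FALSE)
    pair <- config$pair %||% stop("config$pair is required", call. = FALSE)
    data <- read_data_csv(config$data)
    if (!is.null(config$covariates)) {
      data <- adjust_covariates(data, read_data_csv(config$covariates))
    }
    stat <- function(d) {
      est <- estimate_from_config(d, config)
      max_pps(est$pcor, pair[1], pair[2], K, zero_threshold = zt,
              validate = FALSE)$score
    }
    ci <- bootstrap_ci(data, stat, B = as.integer(config$boot_reps %||% 1000),
                       seed = derive_seed(seed, "bootstrap"),
                       label = sprintf("max PPS(%s, %s)", pair[1], pair[2]))
    writeLines(jsonlite::toJSON(ci[c("label", "estimate", "lower", "upper",
                                     "B", "n_missing", "seed", "level")],
                                auto_unbox = TRUE, digits = NA),
               path_for("bootstrap.json"))
    outputs <- c(outputs, path_for("bootstrap.json"))
    results$ci <- ci
  } else if (command == "simulate") {
    P <- random_ggm(as.integer(config$n_nodes %||% 10),
                    edge_prob = as.numeric(config$edge_prob %||% 0.2),
                    seed = derive_seed(seed, "simulator"))
    write_matrix_csv(P, path_for("true_partial_correlations.csv"))
    outputs <- c(outputs, path_for("true_partial_correlations.csv"))
    if (!is.null(config$n_samples)) {
      X <- sample_gaussian(P, as.integer(config$n_samples),
                           seed = derive_seed(seed, "sampler"))
      write_data_csv(X, path_for("samples.csv"))
      outputs <- c(outputs, path_for("samples.csv"))
      results$data <- X
    }
    results$pcor <- P
  } else if (command == "benchmark") {
    P <- random_ggm(as.integer(config$n_nodes %||% 10),
                    edge_prob = as.numeric(config$edge_prob %||% 0.2),
                    seed = derive_seed(seed, "simulator"))
    Kb <- K %||% 4L
    tm <- system.time(scan <- max_pps_scan(P, K = Kb))[["elapsed"]]
    bench <- list(n_nodes = nrow(P), K = Kb, pairs_scanned = nrow(scan),
                  elapsed_seconds = tm)
    writeLines(jsonlite::toJSON(bench, auto_unbox = TRUE, digits = NA),
               path_for("benchmark.json"))
    outputs <- c(outputs, path_for("benchmark.json"))
    results$benchmark <- bench
  } else {
    stop("unknown command: ", command, call. = FALSE)
  }

  meta$elapsed_seconds <- as.numeric(difftime(Sys.time(), started, units = "secs"))
  meta$outputs <- outputs
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, force = TRUE),
             path_for("run_metadata.json"))
  invisible(list(outputs = c(outputs, path_for("run_metadata.json")),
                 results = results))
}

#' Command-line entry point
#'
#' Parses `pairpath <command> [--flag value ...]` argument vectors into a
#' [run_pipeline()] config. Flags use dashes (`--cv-folds 5`) and map to the
#' corresponding config fields; `--pairs a,b` names the node pair. The
#' installed script lives at `system.file("cli", "pairpath", package =
#' "pairpath")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return the [run_pipeline()] result, invisibly.
#' @export
pairpath_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: pairpath <estimate|decompose|pps|scan|compare|bootstrap|simulate|benchmark>",
        "  [--data file.csv] [--matrix file.csv] [--covariates file.csv]",
        "  [--estimator glasso|inverse_pearson] [--lambda cv|<number>]",
        "  [--cv-folds n] [--k n] [--pairs a,b] [--classes file.csv]",
        "  [--boot-reps n] [--seed n] [--zero-threshold x]",
        "  [--n-nodes n] [--edge-prob p] [--n-samples n] [--output dir]",
        sep = "\n")
    return(invisible(NULL))
  }
  config <- list(command = args[1])
  args <- args[-1]
  numeric_keys <- c("cv_folds", "k", "boot_reps", "seed", "zero_threshold",
                    "n_nodes", "edge_prob", "n_samples")
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i], call. = FALSE)
    key <- gsub("-", "_", substring(args[i], 3))
    if (i == length(args)) stop("flag without value: ", args[i], call. = FALSE)
    val <- args[i + 1]
    if (key == "pairs") {
      config$pair <- strsplit(val, ",", fixed = TRUE)[[1]]
    } else if (key %in% numeric_keys) {
      config[[key]] <- as.numeric(val)
    } else {
      config[[key]] <- val
    }
    i <- i + 2
  }
  run_pipeline(config)
}
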