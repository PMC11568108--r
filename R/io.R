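#' Read an ADT count matrix from disk
#'
#' Supported formats: delimited text (`"tsv"`/`"csv"`: header row of
#' antibody names, first column `cell_id`) and MatrixMarket triplets
#' (`"mtx"`: the `.mtx` file plus sidecar name files `<stem>.rows.txt` with
#' cell ids and `<stem>.cols.txt` with antibody names, one per line).
#' Entries must be nonnegative integers; violations are format errors, never
#' silently clipped. Antibodies whose name contains `isotype_pattern`
#' (default `"IgG"`) are auto-flagged as isotype controls unless explicit
#' `isotype_flags` are given.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the
#'   extension.
#' @param isotype_flags optional explicit logical flags (win over pattern).
#' @param isotype_pattern name substring for auto-flagging.
#' @return an [adt_counts()].
#' @export
read_counts <- function(path, format = NULL, isotype_flags = NULL,
                        isotype_pattern = "IgG") {
  if (!file.exists(path)) {
    adtgp_error(sprintf("file not found: %s", path), "adtgp_error_io")
  }
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                               adtgp_error(sprintf("cannot guess format of '%s'", path),
                                           "adtgp_error_io"))
  if (format %in% c("tsv", "csv")) {
    df <- utils::read.table(path, header = TRUE, sep = if (format == "tsv") "\t" else ",",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "cell_id") {
      adtgp_error("first column of a delimited count file must be 'cell_id'",
                  "adtgp_error_format")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    colnames(m) <- names(df)[-1]   # undo make.unique from data-frame subsetting
    rownames(m) <- df[[1]]
  } else {
    mm <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rf <- paste0(stem, ".rows.txt"); cf <- paste0(stem, ".cols.txt")
    if (!file.exists(rf) || !file.exists(cf)) {
      adtgp_error(sprintf("MTX sidecar name files missing: %s / %s", rf, cf),
                  "adtgp_error_io")
    }
    rownames(mm) <- readLines(rf)
    colnames(mm) <- readLines(cf)
    m <- mm
  }
  adt_counts(m, isotype_flags = isotype_flags, isotype_pattern = isotype_pattern)
}

#' Write an ADT count matrix
#'
#' Inverse of [read_counts()]; writing then reading is lossless.
#'
#' @param x an [adt_counts()].
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "adt_counts"))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                               adtgp_error(sprintf("cannot guess format of '%s'", path),
                                           "adtgp_error_io"))
  if (format %in% c("tsv", "csv")) {
    df <- data.frame(cell_id = rownames(x), unclass(x), check.names = FALSE)
    utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                       row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(x), paste0(stem, ".rows.txt"))
    writeLines(colnames(x), paste0(stem, ".cols.txt"))
  }
  invisible(path)
}

#' Read a design matrix
#'
#' Delimited text (TSV or CSV by extension) with a header; the first column
#' must be `mu0` (all 1). Covariate levels are validated and re-indexed by
#' [adt_design()].
#'
#' @param path input file.
#' @return an [adt_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    adtgp_error(sprintf("file not found: %s", path), "adtgp_error_io")
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  adt_design(df)
}

#' @rdname read_design
#' @param x an [adt_design()].
#' @export
write_design <- function(x, path) {
  stopifnot(inherits(x, "adt_design"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Everything needed to reproduce one fit: input paths, antibody selection,
#' prior overrides, sampler settings and the output directory. Serializable
#' to/from a single YAML file; [run_fit_command()] always writes the
#' resolved configuration next to its outputs.
#'
#' @param counts_path,design_path input files for [read_counts()] /
#'   [read_design()].
#' @param protein,isotype antibody names: the modeled target and the
#'   isotype control used for the GP offset.
#' @param out_dir output directory (created if missing).
#' @param priors an [adtgp_priors()], or NULL to tune `rho_sq` from the
#'   isotype counts at run time.
#' @param chains,iter_warmup,iter_sampling,seed sampler settings.
#' @param allow_unconverged succeed even when the convergence flag fails.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts_path, design_path, protein, isotype, out_dir,
                       priors = NULL, chains = 4, iter_warmup = 3000,
                       iter_sampling = 1000, seed = 1,
                       allow_unconverged = FALSE) {
  structure(list(counts_path = counts_path, design_path = design_path,
                 protein = protein, isotype = isotype, out_dir = out_dir,
                 priors = priors, chains = as.integer(chains),
                 iter_warmup = as.integer(iter_warmup),
                 iter_sampling = as.integer(iter_sampling),
                 seed = as.integer(seed),
                 allow_unconverged = isTRUE(allow_unconverged)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- if (!is.null(y$priors)) do.call(adtgp_priors, y$priors) else NULL
  run_config(y$counts_path, y$design_path, y$protein, y$isotype, y$out_dir,
             priors = pr, chains = as.integer(y$chains %||% 4),
             iter_warmup = as.integer(y$iter_warmup %||% 3000),
             iter_sampling = as.integer(y$iter_sampling %||% 1000),
             seed = as.integer(y$seed %||% 1),
             allow_unconverged = isTRUE(y$allow_unconverged))
}

#' @rdname run_config
#' @export
write_run_config <- function(x, path) {
  stopifnot(inherits(x, "run_config"))
  y <- unclass(x)
  if (!is.null(y$priors)) y$priors <- unclass(y$priors)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run a full fit from a configuration
#'
#' Orchestrates one analysis: read counts and design, tune priors if none
#' given, fit, and write artifacts into `out_dir`:
#' `posterior_samples.csv` (conditional predictive draws, one labeled column
#' per covariate combination), `diagnostics.tsv`, `effect_summary.json`
#' (when the design yields exactly two combinations), `config.yaml` (the
#' resolved configuration) and `run.log` (per-stage timings). The returned
#' status is 0 when the fit converged (or `allow_unconverged` is set),
#' 2 for missing inputs, 1 for any other failure; the failing stage is
#' named in the error/log.
#'
#' @param config a [run_config()].
#' @return invisibly, list with `status`, `paths` of written artifacts, and
#'   the `fit`.
#' @export
run_fit_command <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_all <- Sys.time()
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      adtgp_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  "adtgp_error_stage")
    })
    log_lines <<- c(log_lines, sprintf("%s: %.2fs", name,
                                       as.numeric(Sys.time() - t0, units = "secs")))
    r
  }
  for (p in c(config$counts_path, config$design_path)) {
    if (!file.exists(p)) {
      message(sprintf("input file not found: %s", p))
      return(invisible(list(status = 2L, paths = character(0), fit = NULL)))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- stage("read_counts", read_counts(config$counts_path))
  design <- stage("read_design", read_design(config$design_path))
  for (ab in c(config$protein, config$isotype)) {
    if (!ab %in% colnames(counts)) {
      adtgp_error(sprintf("stage 'select': antibody '%s' not in panel", ab),
                  "adtgp_error_stage")
    }
  }
  igg <- as.integer(counts[, config$isotype])
  priors <- config$priors %||% stage("tune_priors", tune_rhosq(igg))
  fit <- stage("fit", adtgp(as.integer(counts[, config$protein]), igg, design,
                            priors = priors, chains = config$chains,
                            iter_warmup = config$iter_warmup,
                            iter_sampling = config$iter_sampling,
                            seed = config$seed))
  paths <- c(samples = file.path(config$out_dir, "posterior_samples.csv"),
             diagnostics = file.path(config$out_dir, "diagnostics.tsv"),
             config = file.path(config$out_dir, "config.yaml"),
             log = file.path(config$out_dir, "run.log"))
  stage("write_samples", utils::write.csv(as.data.frame(fit$cond_samples),
                                          paths["samples"], row.names = FALSE))
  stage("write_diagnostics", utils::write.table(
    as.data.frame(fit$diagnostics), paths["diagnostics"], sep = "\t",
    row.names = FALSE, quote = FALSE))
  if (ncol(fit$cond_samples) == 2) {
    labs <- colnames(fit$cond_samples)
    eff <- log2fc_posterior(fit, labs[1], labs[2])
    paths["effect"] <- file.path(config$out_dir, "effect_summary.json")
    stage("write_effect", jsonlite::write_json(list(
      contrast = sprintf("%s vs %s", labs[1], labs[2]),
      posterior_mean = eff$posterior_mean,
      posterior_median = eff$posterior_median,
      ci90 = central_interval(eff, 0.9),
      pseudo_p = eff$pseudo_p), paths["effect"], auto_unbox = TRUE, digits = NA))
  }
  resolved <- config
  resolved$priors <- priors
  stage("write_config", write_run_config(resolved, paths["config"]))
  log_lines <- c(log_lines, sprintf("total: %.2fs",
                                    as.numeric(Sys.time() - t_all, units = "secs")))
  writeLines(log_lines, paths["log"])
  converged <- isTRUE(attr(fit$diagnostics, "converged"))
  status <- if (converged || config$allow_unconverged) 0L else 1L
  if (status != 0L) message("fit did not pass the convergence flag")
  invisible(list(status = status, paths = paths, fit = fit))
}
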