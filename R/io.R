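# Strict TSV/CSV readers and writers for the pipeline's matrix formats.
# Layout: header row of taxon ids, first column sample ids (or transposed
# with orientation = "taxa-rows").

detect_sep <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read a count matrix from TSV/CSV
#'
#' @param path file path; `.csv` implies comma separation, else tab.
#' @param orientation `"samples-rows"` (default) or `"taxa-rows"` (the file
#'   is transposed on read).
#' @return Numeric matrix, samples in rows.
#' @export
read_count_matrix <- function(path,
                              orientation = c("samples-rows", "taxa-rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (orientation == "taxa-rows") m <- t(m)
  validate_counts(m)
}

#' Write a matrix (or log_matrix) to TSV/CSV
#'
#' @param x numeric matrix or [log_matrix()] (its values are written).
#' @param path destination; `.csv` implies comma separation, else tab.
#' @param id_column name for the leading id column, default `"sample_id"`.
#' @export
write_matrix <- function(x, path, id_column = "sample_id") {
  if (inherits(x, "log_matrix")) x <- x$values
  df <- data.frame(rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = detect_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a square taxon distance matrix
#'
#' @param path TSV/CSV with header and first column both holding taxon ids.
#' @return Validated symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          row.names = 1, check.names = FALSE)
  D <- as.matrix(df)
  if (!identical(rownames(D), colnames(D)))
    stop("distance matrix row and column ids disagree")
  validate_distance_matrix(D)
}

#' Read a sample covariate table
#'
#' Rows are matched to `sample_ids` by the first column; out-of-order rows
#' are reordered with a message, missing samples are an error.
#'
#' @param path TSV/CSV with a leading sample-id column.
#' @param sample_ids ids the rows must cover.
#' @return data.frame with rownames = `sample_ids`.
#' @export
read_covariates <- function(path, sample_ids) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in covariate table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(sample_ids, ids)
  if (length(missing) > 0)
    stop("covariate table is missing samples: ",
         paste(utils::head(missing), collapse = ", "))
  if (!identical(ids[seq_along(sample_ids)], sample_ids))
    message("reordering covariate table to match the count matrix")
  out <- df[match(sample_ids, ids), -1, drop = FALSE]
  rownames(out) <- sample_ids
  out
}

#' Run the imputation pipeline from a configuration and write artifacts
#'
#' Programmatic equivalent of the command-line `impute` entry point: reads
#' the inputs, runs [tphpmf()], and writes the imputed matrix, the
#' per-entry posterior sds, the flag mask, per-level objective traces, and
#' a resolved-configuration manifest sufficient to reproduce the run.
#'
#' @param config named list (or path to a YAML file) with entries `counts`
#'   (path, required), optional `covariates`, `tree`, `distances`,
#'   `orientation`, `out_dir` (default `"tphpmf_out"`), `seed`, and any
#'   [tphpmf_control()] fields under `control`.
#' @return The `"tphpmf"` fit, invisibly.
#' @export
run_impute <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$counts)) stop("config$counts (input path) is required")
  out_dir <- config$out_dir %||% "tphpmf_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_count_matrix(config$counts,
                              orientation = config$orientation %||%
                                "samples-rows")
  covariates <- if (!is.null(config$covariates))
    read_covariates(config$covariates, rownames(counts)) else NULL
  distances <- if (!is.null(config$distances))
    read_distance_matrix(config$distances) else NULL
  control <- do.call(tphpmf_control, config$control %||% list())
  fit <- tphpmf(counts, covariates = covariates, tree = config$tree,
                distances = distances, control = control,
                seed = config$seed)
  write_matrix(fit$imputed, file.path(out_dir, "imputed.tsv"))
  write_matrix(fit$posterior_sd, file.path(out_dir, "posterior_sd.tsv"))
  write_matrix(fit$flags * 1, file.path(out_dir, "flags.tsv"))
  utils::write.csv(fit$diagnostics,
                   file.path(out_dir, "objective_trace.csv"),
                   row.names = FALSE)
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("tphpmf"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("seed: %s", config$seed %||% "NULL"),
    sprintf("counts: %s", config$counts),
    sprintf("covariates: %s", config$covariates %||% "NULL"),
    sprintf("tree: %s", config$tree %||% "NULL"),
    sprintf("distances: %s", config$distances %||% "NULL"),
    vapply(names(control), function(k)
      sprintf("control.%s: %s", k,
              paste(control[[k]] %||% "NULL", collapse = ",")),
      character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(fit)
}
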