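#' Log-scale abundance matrix with an imputation mask
#'
#' Container for a normalized, log10-transformed sample-by-taxon matrix
#' together with a logical mask marking the entries scheduled for imputation.
#' Created by [log_transform()]; most users never construct one directly.
#'
#' @param values numeric matrix, samples in rows, taxa in columns, on the
#'   log10 scale.
#' @param missing_mask logical matrix of the same dimension; `TRUE` marks an
#'   entry to be imputed.
#' @param offset pseudo-count added before taking log10 (must be > 1 so
#'   transformed values stay strictly positive).
#' @param library_size common library size the counts were scaled to.
#' @return An object of class `"log_matrix"`: a list with elements `values`,
#'   `missing_mask`, `offset` and `library_size`.
#' @export
log_matrix <- function(values, missing_mask = NULL, offset = 1.01,
                       library_size = 1e6) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(missing_mask)) {
    missing_mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  stopifnot(is.logical(missing_mask), all(dim(missing_mask) == dim(values)))
  if (offset <= 1) stop("offset must be > 1 to guarantee positive log values")
  if (library_size <= 0) stop("library_size must be positive")
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values, missing_mask = missing_mask,
                 offset = offset, library_size = library_size),
            class = "log_matrix")
}

#' @export
print.log_matrix <- function(x, ...) {
  cat(sprintf("log_matrix: %d samples x %d taxa (offset %g, library size %g)\n",
              nrow(x$values), ncol(x$values), x$offset, x$library_size))
  cat(sprintf("  entries marked for imputation: %d (%.1f%%)\n",
              sum(x$missing_mask), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.log_matrix <- function(x) dim(x$values)

# floor of the transformed scale: value a zero count maps to
log_floor <- function(x) log10(x$offset)

validate_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) stop("count matrix contains negative entries")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  counts
}

#' Scale each sample to a common library size
#'
#' Divides every row (sample) by its total and multiplies by `library_size`,
#' so that all samples become comparable regardless of sequencing effort.
#' Zeros stay zero; a sample with zero total is a data error and is rejected.
#'
#' @param counts non-negative numeric matrix, samples in rows, taxa in
#'   columns (a data.frame is coerced).
#' @param library_size target row total, default `1e6`.
#' @return The normalized matrix (double precision) with attribute
#'   `library_size`.
#' @examples
#' m <- matrix(c(1, 1, 3, 1), 2, 2)
#' rowSums(normalize_counts(m))
#' @export
normalize_counts <- function(counts, library_size = 1e6) {
  counts <- validate_counts(counts)
  if (library_size <= 0) stop("library_size must be positive")
  totals <- rowSums(counts)
  bad <- which(totals <= 0)
  if (length(bad) > 0)
    stop("zero library size for sample: ",
         paste(rownames(counts)[bad], collapse = ", "))
  out <- counts * (library_size / totals)
  storage.mode(out) <- "double"
  attr(out, "library_size") <- library_size
  attr(out, "original_totals") <- totals
  out
}

#' Log10-transform a normalized count matrix
#'
#' Applies `log10(x + offset)` entry-wise. The offset must exceed 1 so every
#' transformed value is strictly positive, in particular a zero count maps to
#' `log10(offset) > 0`.
#'
#' @param normalized output of [normalize_counts()] (or any non-negative
#'   matrix on the same scale).
#' @param offset pseudo-count, default 1.01.
#' @param library_size recorded library size; taken from the attribute left
#'   by [normalize_counts()] when present.
#' @return A [log_matrix()] with an all-`FALSE` mask.
#' @export
log_transform <- function(normalized, offset = 1.01, library_size = NULL) {
  if (offset <= 1)
    stop("offset must be > 1: positivity guarantee broken otherwise")
  if (is.null(library_size)) {
    library_size <- attr(normalized, "library_size")
    if (is.null(library_size)) library_size <- 1e6
  }
  totals <- attr(normalized, "original_totals")
  if (any(normalized < 0)) stop("normalized matrix has negative entries")
  lm <- log_matrix(log10(unclass(normalized) + offset), NULL, offset,
                   library_size)
  attr(lm, "original_totals") <- totals
  lm
}

#' Mark entries to be imputed
#'
#' Sets the missing-entry mask of a [log_matrix()]. Only zero-count entries
#' (value exactly `log10(offset)`) may be flagged: a non-zero observation is
#' never an imputation target.
#'
#' @param x a `log_matrix`.
#' @param flags logical matrix, `TRUE` = impute this entry.
#' @return `x` with `missing_mask` replaced. Stored values are untouched.
#' @export
mark_missing <- function(x, flags) {
  stopifnot(inherits(x, "log_matrix"), is.logical(flags),
            all(dim(flags) == dim(x$values)))
  is_zero <- abs(x$values - log_floor(x)) < 1e-12
  offending <- flags & !is_zero
  if (any(offending)) {
    idx <- which(offending, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "cannot flag non-zero entry (sample %s, taxon %s) for imputation",
      rownames(x$values)[idx[1]] %||% idx[1],
      colnames(x$values)[idx[2]] %||% idx[2]))
  }
  x$missing_mask <- flags
  dimnames(x$missing_mask) <- dimnames(x$values)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a log-scale matrix back to counts
#'
#' Inverts [log_transform()]: `max(0, 10^value - offset)`, optionally
#' rescaled from the common library size back to each sample's original
#' total.
#'
#' @param x a `log_matrix` (typically with imputed values filled in).
#' @param original_totals per-sample positive totals; defaults to the totals
#'   recorded by [normalize_counts()] when available, else no rescaling.
#' @return Numeric matrix of (generally non-integer) counts.
#' @export
inverse_transform <- function(x, original_totals = NULL) {
  stopifnot(inherits(x, "log_matrix"))
  if (is.null(original_totals)) original_totals <- attr(x, "original_totals")
  out <- 10^x$values - x$offset
  out[out < 0] <- 0
  if (!is.null(original_totals)) {
    stopifnot(length(original_totals) == nrow(out), all(original_totals > 0))
    out <- out * (original_totals / x$library_size)
  }
  out
}
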