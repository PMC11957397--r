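# Synthetic-data generators for benchmarking the imputation pipeline, a
# zero-inflation mechanism with a calibrated abundance-dependent dropout
# model, robustness perturbations, and the evaluation metrics.

shift_positive <- function(vals, offset, margin = 0.1) {
  floorv <- log10(offset)
  if (min(vals) <= floorv + 1e-9) vals <- vals + (floorv + margin - min(vals))
  vals
}

#' Simulate a complete log-abundance matrix from a low-rank model
#'
#' Draws sample and taxon latent matrices with i.i.d. standard normal
#' entries, forms their product plus Gaussian noise, and affinely rescales
#' to a realistic log10-abundance location/spread; entries are shifted to
#' stay strictly above `log10(offset)`.
#'
#' @param n_samples,n_taxa matrix dimensions.
#' @param latent_dim true latent dimension.
#' @param noise_sd observation noise sd before rescaling.
#' @param target_mean,target_sd location and spread on the log10 scale.
#' @param offset pseudo-count, default 1.01.
#' @param seed optional integer seed.
#' @return A [log_matrix()] with no missing entries.
#' @export
simulate_complete_pmf <- function(n_samples = 50, n_taxa = 100,
                                  latent_dim = 3, noise_sd = 0.3,
                                  target_mean = 3, target_sd = 1,
                                  offset = 1.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(stats::rnorm(n_samples * latent_dim), n_samples, latent_dim)
  T_ <- matrix(stats::rnorm(n_taxa * latent_dim), n_taxa, latent_dim)
  Y <- tcrossprod(S, T_) +
    matrix(stats::rnorm(n_samples * n_taxa, 0, noise_sd), n_samples, n_taxa)
  Y <- target_mean + target_sd * (Y - mean(Y)) / stats::sd(Y)
  Y <- shift_positive(Y, offset)
  dimnames(Y) <- list(paste0("sample", seq_len(n_samples)),
                      paste0("taxon", seq_len(n_taxa)))
  log_matrix(Y, NULL, offset)
}

#' Simulate a complete matrix from a sample/taxon linear model
#'
#' Each entry is a weighted combination of the same sample's other taxa and
#' the same taxon's other samples, plus noise: the taxon weight vector has a
#' zero entry for its own taxon and the sample weight vector a zero entry
#' for its own sample, so no entry depends on its own seed value.
#'
#' @param n_samples,n_taxa dimensions.
#' @param n_weights number of non-zero weights per row/column (sparsity).
#' @param noise_sd noise sd.
#' @param target_mean,target_sd,offset as in [simulate_complete_pmf()].
#' @param seed optional integer seed.
#' @return A [log_matrix()] with no missing entries.
#' @export
simulate_complete_linear <- function(n_samples = 50, n_taxa = 100,
                                     n_weights = 5, noise_sd = 0.3,
                                     target_mean = 3, target_sd = 1,
                                     offset = 1.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y0 <- matrix(stats::rnorm(n_samples * n_taxa, target_mean, target_sd),
               n_samples, n_taxa)
  alpha <- matrix(0, n_taxa, n_taxa)   # column j: weights over other taxa
  beta <- matrix(0, n_samples, n_samples)
  for (j in seq_len(n_taxa)) {
    pick <- sample(setdiff(seq_len(n_taxa), j), min(n_weights, n_taxa - 1))
    w <- stats::runif(length(pick))
    alpha[pick, j] <- 0.5 * w / sum(w)
  }
  for (i in seq_len(n_samples)) {
    pick <- sample(setdiff(seq_len(n_samples), i),
                   min(n_weights, n_samples - 1))
    w <- stats::runif(length(pick))
    beta[pick, i] <- 0.5 * w / sum(w)
  }
  eps <- matrix(stats::rnorm(n_samples * n_taxa, 0, noise_sd),
                n_samples, n_taxa)
  Y <- Y0 %*% alpha + t(crossprod(Y0, beta)) + eps
  Y <- shift_positive(Y, offset)
  dimnames(Y) <- list(paste0("sample", seq_len(n_samples)),
                      paste0("taxon", seq_len(n_taxa)))
  log_matrix(Y, NULL, offset)
}

#' Complete a template matrix by resampling from per-taxon non-zero moments
#'
#' Semi-simulation: zero (or masked) entries of a template are replaced by
#' draws from a normal distribution with that taxon's observed non-zero
#' mean and sd, clamped below at `log10(offset)`. A taxon with fewer than
#' two non-zero values falls back to the global moments with a warning.
#'
#' @param template a [log_matrix()] (or plain matrix on the log10 scale).
#' @param offset pseudo-count, used when `template` is a plain matrix.
#' @param seed optional integer seed.
#' @return A [log_matrix()] with no missing entries.
#' @export
simulate_complete_semi <- function(template, offset = 1.01, seed = NULL) {
  if (!inherits(template, "log_matrix"))
    template <- log_matrix(template, NULL, offset)
  if (!is.null(seed)) set.seed(seed)
  Y <- template$values
  floorv <- log_floor(template)
  is_zero <- abs(Y - floorv) < 1e-12 | template$missing_mask
  nz <- Y[!is_zero]
  if (length(nz) < 2) stop("template has fewer than two non-zero entries")
  gm <- mean(nz); gs <- stats::sd(nz)
  for (j in seq_len(ncol(Y))) {
    zj <- is_zero[, j]
    if (!any(zj)) next
    obs <- Y[!zj, j]
    if (length(obs) < 2) {
      warning("taxon ", colnames(Y)[j] %||% j,
              ": fewer than two non-zero values, using global moments")
      m <- gm; s <- gs
    } else {
      m <- mean(obs); s <- stats::sd(obs)
    }
    Y[zj, j] <- pmax(stats::rnorm(sum(zj), m, s), floorv)
  }
  log_matrix(Y, NULL, template$offset, template$library_size)
}

#' Zero-inflate a complete matrix with abundance-dependent dropout
#'
#' Each entry is independently dropped (set to `log10(offset)`) with
#' probability `plogis(a - b * y)`: low-abundance entries drop out more
#' often when `b > 0`; `b = 0` gives uniform binomial dropout. The
#' intercept `a` is calibrated by bisection so the expected zero fraction
#' matches `target_zero_fraction`.
#'
#' @param complete a [log_matrix()] with no zeros.
#' @param target_zero_fraction desired zero proportion in (0, 1).
#' @param b non-negative abundance-dependence slope, default 1.
#' @param seed optional integer seed.
#' @return List with `zi` (the zero-inflated `log_matrix`) and `truth_mask`
#'   (logical matrix of dropped entries).
#' @export
inflate_zeros <- function(complete, target_zero_fraction = 0.7, b = 1,
                          seed = NULL) {
  stopifnot(inherits(complete, "log_matrix"), b >= 0)
  if (target_zero_fraction <= 0 || target_zero_fraction >= 1)
    stop("target_zero_fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  Y <- complete$values
  frac <- function(a) mean(stats::plogis(a - b * Y))
  lo <- -50; hi <- 50 + b * max(abs(Y))
  if (frac(lo) > target_zero_fraction || frac(hi) < target_zero_fraction)
    stop("target zero fraction unattainable for this matrix")
  a <- (lo + hi) / 2
  for (i in 1:100) {
    a <- (lo + hi) / 2
    if (abs(frac(a) - target_zero_fraction) < 1e-6) break
    if (frac(a) < target_zero_fraction) lo <- a else hi <- a
  }
  pi_drop <- stats::plogis(a - b * Y)
  drop_mask <- matrix(stats::runif(length(Y)) < pi_drop, nrow(Y), ncol(Y),
                      dimnames = dimnames(Y))
  zi <- complete
  zi$values[drop_mask] <- log_floor(complete)
  list(zi = zi, truth_mask = drop_mask,
       zero_fraction_achieved = mean(drop_mask))
}

#' Resample a count matrix to a fixed sequencing depth
#'
#' Per sample, draws `depth` reads from a multinomial with probabilities
#' proportional to the sample's counts.
#'
#' @param counts non-negative count matrix, samples in rows.
#' @param depth reads per sample.
#' @param seed optional integer seed.
#' @return Integer count matrix with every row summing to `depth`.
#' @export
adjust_depth <- function(counts, depth, seed = NULL) {
  counts <- validate_counts(counts)
  stopifnot(depth >= 1)
  if (any(rowSums(counts) <= 0))
    stop("empty sample: cannot resample a sample with zero total")
  if (!is.null(seed)) set.seed(seed)
  out <- t(apply(counts, 1, function(row)
    stats::rmultinom(1, size = depth, prob = row)[, 1]))
  dimnames(out) <- dimnames(counts)
  out
}

#' Append synthetic outlier samples
#'
#' Each appended sample assigns the matrix maximum value to the taxa in the
#' lowest quartile of mean abundance and the zero-count floor
#' `log10(offset)` to all other taxa — an adversarial inversion of the
#' abundance profile used to probe robustness.
#'
#' @param x a [log_matrix()].
#' @param k number of outlier samples to append.
#' @param seed optional integer seed (the construction is deterministic;
#'   accepted for interface symmetry).
#' @return A [log_matrix()] with `k` extra rows named `outlier<i>`.
#' @export
inject_outliers <- function(x, k, seed = NULL) {
  stopifnot(inherits(x, "log_matrix"), k >= 0)
  if (k == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  col_mean <- colMeans(x$values)
  low <- col_mean <= stats::quantile(col_mean, 0.25)
  row <- ifelse(low, max(x$values), log_floor(x))
  extra <- matrix(rep(row, each = k), k, ncol(x$values),
                  dimnames = list(paste0("outlier", seq_len(k)),
                                  colnames(x$values)))
  vals <- rbind(x$values, extra)
  mask <- rbind(x$missing_mask,
                matrix(FALSE, k, ncol(x$values)))
  rownames(mask) <- rownames(vals)
  log_matrix(vals, mask, x$offset, x$library_size)
}

#' Wasserstein-1 distance between two empirical distributions
#'
#' Exact earth-mover's distance in one dimension, computed as the integral
#' of the absolute difference of the two empirical quantile functions.
#'
#' @param x,y numeric samples (lengths may differ).
#' @return Non-negative scalar.
#' @export
wasserstein1 <- function(x, y) {
  x <- sort(x); y <- sort(y)
  n <- length(x); m <- length(y)
  stopifnot(n > 0, m > 0)
  p <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  w <- diff(c(0, p))
  qx <- x[pmin(n, ceiling(p * n - 1e-9))]
  qy <- y[pmin(m, ceiling(p * m - 1e-9))]
  sum(w * abs(qx - qy))
}

#' Benchmark an imputed matrix against the complete truth
#'
#' Computes the four benchmarking metrics: (1) MSE between imputed and
#' complete values over the dropped entries; (2) mean across taxa of the
#' Pearson correlation between imputed and complete columns (constant
#' columns excluded with a warning); (3) the Wasserstein-1 distance between
#' the per-taxon mean/sd-ratio distributions of the imputed and complete
#' matrices; (4) the raw per-taxon (mean, sd) pairs for plotting.
#'
#' @param imputed,complete [log_matrix()] objects (or plain matrices) of
#'   identical shape.
#' @param truth_mask logical matrix of entries that were dropped and
#'   imputed.
#' @return Object of class `"benchmark_report"` with elements `mse`,
#'   `mean_pearson`, `wasserstein_mean_sd`, `mean_sd_pairs`,
#'   `zero_fraction_achieved`.
#' @export
evaluate <- function(imputed, complete, truth_mask) {
  vi <- if (inherits(imputed, "log_matrix")) imputed$values else imputed
  vc <- if (inherits(complete, "log_matrix")) complete$values else complete
  stopifnot(all(dim(vi) == dim(vc)), all(dim(truth_mask) == dim(vi)))
  mse <- mean((vi[truth_mask] - vc[truth_mask])^2)
  cors <- rep(NA_real_, ncol(vi))
  for (j in seq_len(ncol(vi))) {
    if (stats::sd(vi[, j]) < 1e-12 || stats::sd(vc[, j]) < 1e-12) next
    cors[j] <- stats::cor(vi[, j], vc[, j])
  }
  if (anyNA(cors))
    warning(sum(is.na(cors)), " constant taxa excluded from the Pearson mean")
  pairs <- data.frame(
    taxon = colnames(vi) %||% as.character(seq_len(ncol(vi))),
    mean_imputed = colMeans(vi), sd_imputed = apply(vi, 2, stats::sd),
    mean_complete = colMeans(vc), sd_complete = apply(vc, 2, stats::sd),
    row.names = NULL)
  ratio <- function(m, s) m / pmax(s, 1e-12)
  w1 <- wasserstein1(ratio(pairs$mean_imputed, pairs$sd_imputed),
                     ratio(pairs$mean_complete, pairs$sd_complete))
  structure(list(mse = mse, mean_pearson = mean(cors, na.rm = TRUE),
                 wasserstein_mean_sd = w1, mean_sd_pairs = pairs,
                 zero_fraction_achieved = mean(truth_mask)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "benchmark_report (zero fraction %.3f)\n  MSE on dropped entries: %.4f\n  mean per-taxon Pearson: %.4f\n  Wasserstein-1 (mean/sd): %.4f\n",
    x$zero_fraction_achieved, x$mse, x$mean_pearson, x$wasserstein_mean_sd))
  invisible(x)
}
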