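#' Candidate hyperparameter grid for cross-validated tuning
#'
#' @param latent_dim,n_samples,burn_in,thin,lambda_s,lambda_t candidate
#'   values (vectors); the grid is their Cartesian product.
#' @param n_folds number of cross-validation folds, default 10.
#' @param n_repeats repetitions of the whole CV loop, default 1.
#' @param seed integer seed controlling fold assignment and chains.
#' @return Object of class `"tuning_grid"`.
#' @export
tuning_grid <- function(latent_dim = 10, n_samples = 200, burn_in = 50,
                        thin = 2, lambda_s = 1, lambda_t = 1,
                        n_folds = 10, n_repeats = 1, seed = 1) {
  grid <- expand.grid(latent_dim = latent_dim, n_samples = n_samples,
                      burn_in = burn_in, thin = thin, lambda_s = lambda_s,
                      lambda_t = lambda_t, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty tuning grid")
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(grid = grid, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = seed),
            class = "tuning_grid")
}

#' Assign observed entries to cross-validation folds
#'
#' Entries (not samples) are partitioned uniformly at random into
#' `n_folds` disjoint, near-equal sets; deterministic given `seed`.
#'
#' @param observed_entries integer vector of entry indices (column-major
#'   positions in the matrix).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold labels aligned with `observed_entries`.
#' @export
make_folds <- function(observed_entries, n_folds, seed = 1) {
  n <- length(observed_entries)
  if (n < n_folds)
    stop("too few observed entries (", n, ") for ", n_folds, " folds")
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Cross-validated hyperparameter selection
#'
#' For every configuration in the grid and every fold, hides that fold's
#' observed entries (adding them to the missing mask, so they are excluded
#' from the level aggregates as well), runs the sampler, and scores RMSE on
#' the hidden entries. Entries already flagged as missing are never used
#' for scoring. The best configuration minimizes mean RMSE; ties break
#' toward smaller `latent_dim`, then fewer `n_samples`.
#'
#' @param x taxon-level [log_matrix()].
#' @param hierarchy optional `"phylo_hierarchy"`.
#' @param grid a [tuning_grid()].
#' @param n_levels passed to [run_chain()].
#' @return Object of class `"tuning_report"`: `results` (per-config mean/sd
#'   RMSE and failure count), `best_config` (row of the grid), `folds`.
#' @export
cross_validate <- function(x, hierarchy = NULL, grid = tuning_grid(),
                           n_levels = NULL) {
  stopifnot(inherits(x, "log_matrix"), inherits(grid, "tuning_grid"))
  observed <- which(!x$missing_mask)
  folds <- make_folds(observed, grid$n_folds, seed = grid$seed)
  g <- grid$grid
  res <- data.frame(g, mean_rmse = NA_real_, sd_rmse = NA_real_,
                    n_failed = 0L)
  counter <- 0
  for (ci in seq_len(nrow(g))) {
    rmses <- c()
    failed <- 0L
    for (rep in seq_len(grid$n_repeats)) {
      for (f in seq_len(grid$n_folds)) {
        counter <- counter + 1
        hidden <- observed[folds == f]
        xm <- x
        xm$missing_mask[hidden] <- TRUE
        cfg <- engine_config(
          latent_dim = g$latent_dim[ci], n_samples = g$n_samples[ci],
          burn_in = g$burn_in[ci], thin = g$thin[ci],
          lambda_s = g$lambda_s[ci], lambda_t = g$lambda_t[ci],
          seed = (grid$seed * 1009L + counter) %% .Machine$integer.max)
        r <- tryCatch({
          chain <- run_chain(xm, hierarchy, cfg, n_levels = n_levels)
          imp <- impute(chain, xm)
          sqrt(mean((imp$imputed$values[hidden] - x$values[hidden])^2))
        }, error = function(e) NA_real_)
        if (is.na(r)) failed <- failed + 1L else rmses <- c(rmses, r)
      }
    }
    res$mean_rmse[ci] <- mean(rmses)
    res$sd_rmse[ci] <- stats::sd(rmses)
    res$n_failed[ci] <- failed
  }
  ord <- order(res$mean_rmse, res$latent_dim, res$n_samples)
  structure(list(results = res, best_index = ord[1],
                 best_config = g[ord[1], , drop = FALSE], folds = folds,
                 grid = grid),
            class = "tuning_report")
}

#' @export
print.tuning_report <- function(x, ...) {
  cat(sprintf("tuning_report: %d configurations x %d folds\n",
              nrow(x$results), x$grid$n_folds))
  print(x$results, row.names = FALSE)
  cat("best configuration (row", x$best_index, "): mean RMSE",
      signif(x$results$mean_rmse[x$best_index], 5), "\n")
  invisible(x)
}
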