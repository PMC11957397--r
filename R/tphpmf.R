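#' Control parameters for [tphpmf()]
#'
#' @param latent_dim,sigma2,lambda_s,lambda_t,n_samples,burn_in,thin Gibbs
#'   sampler settings, see [engine_config()].
#' @param n_levels number of hierarchy layers (1-4); `NULL` = all available.
#' @param em_tol,em_max_iter EM settings for the mixture fits.
#' @param abundance_threshold,filter_confidence prevalence-screen settings.
#' @param lrt_alpha,e_threshold zero-flagging thresholds.
#' @return A list of class `"tphpmf_control"`.
#' @export
tphpmf_control <- function(latent_dim = 10, sigma2 = 1, lambda_s = 1,
                           lambda_t = 1, n_samples = 200, burn_in = 50,
                           thin = 2, n_levels = NULL, em_tol = 1e-6,
                           em_max_iter = 100, abundance_threshold = 0,
                           filter_confidence = 0.95, lrt_alpha = 0.05,
                           e_threshold = 0.5) {
  structure(as.list(environment()), class = "tphpmf_control")
}

# derive reproducible per-stage seeds from one user seed
expand_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(flagging = 11L, engine = 23L, simulate = 37L, tuning = 53L)
  as.integer((as.double(seed) * 48271 + offsets[[stage]]) %% 2147483647)
}

#' Impute non-biological zeros in a microbiome count matrix
#'
#' The full pipeline: counts are scaled to a common library size and
#' log10-transformed; zeros likely to be technical dropouts are flagged by
#' a per-taxon gamma-normal mixture (EM fit, LRT screen, posterior
#' membership >= `e_threshold`); a three-level phylogenetic hierarchy is
#' built from taxon distances by complete-linkage clustering; and flagged
#' entries are imputed by the posterior mean of a hierarchical Bayesian
#' probabilistic matrix factorization sampled by Gibbs. Zeros judged
#' biological are left untouched.
#'
#' @param counts non-negative count matrix, samples in rows, taxa in
#'   columns.
#' @param covariates optional per-sample covariate data.frame.
#' @param tree optional phylogenetic tree (`ape::phylo`, newick string or
#'   file) covering the taxa; used to compute patristic distances.
#' @param distances optional precomputed symmetric taxon distance matrix
#'   (overrides `tree`). With neither, the engine falls back to a
#'   single-level plain factorization with a warning.
#' @param cut_heights optional three increasing dendrogram cut heights;
#'   default: quantiles `cut_quantiles` of the pairwise distances.
#' @param cut_quantiles quantile probabilities for the default heights.
#' @param library_size,offset preprocessing constants (defaults 1e6, 1.01).
#' @param control a [tphpmf_control()] list.
#' @param seed integer seed; one seed drives flagging and sampling through
#'   deterministic per-stage substreams.
#' @return An object of class `"tphpmf"` with the imputed [log_matrix()],
#'   per-entry posterior sds, the flag report, the hierarchy, sampler
#'   diagnostics, and the resolved configuration. Use [fitted()] for the
#'   imputed matrix and [plot()] for convergence traces.
#' @examples
#' \donttest{
#' sim <- simulate_complete_pmf(30, 40, seed = 1)
#' zi <- inflate_zeros(sim, 0.6, seed = 2)
#' counts <- round(inverse_transform(zi$zi))
#' fit <- tphpmf(counts, seed = 3,
#'               control = tphpmf_control(latent_dim = 5, n_samples = 60,
#'                                        burn_in = 20))
#' fit
#' }
#' @export
tphpmf <- function(counts, covariates = NULL, tree = NULL, distances = NULL,
                   cut_heights = NULL, cut_quantiles = c(0.25, 0.5, 0.75),
                   library_size = 1e6, offset = 1.01,
                   control = tphpmf_control(), seed = NULL) {
  cl <- match.call()
  stopifnot(inherits(control, "tphpmf_control"))
  normalized <- normalize_counts(counts, library_size)
  x <- log_transform(normalized, offset)

  flag_seed <- expand_seed(seed, "flagging")
  if (!is.null(flag_seed)) set.seed(flag_seed)
  report <- flag_nonbiological_zeros(
    x, covariates,
    abundance_threshold = control$abundance_threshold,
    confidence = control$filter_confidence,
    lrt_alpha = control$lrt_alpha, e_threshold = control$e_threshold,
    em_tol = control$em_tol, em_max_iter = control$em_max_iter)
  x <- mark_missing(x, report$flags)

  hierarchy <- NULL
  if (is.null(distances) && !is.null(tree)) distances <- distances_from_tree(tree)
  if (!is.null(distances)) {
    ids <- colnames(x$values)
    if (!all(ids %in% rownames(distances)))
      stop("distance matrix is missing taxa: ",
           paste(utils::head(setdiff(ids, rownames(distances))), collapse = ", "))
    D <- distances[ids, ids]
    if (is.null(cut_heights)) cut_heights <- default_cut_heights(D, cut_quantiles)
    hierarchy <- build_hierarchy(D, cut_heights)
  } else {
    warning("no tree or distance matrix supplied: ",
            "running a single-level factorization without phylogenetic priors")
  }

  cfg <- engine_config(latent_dim = control$latent_dim,
                       sigma2 = control$sigma2, lambda_s = control$lambda_s,
                       lambda_t = control$lambda_t,
                       n_samples = control$n_samples,
                       burn_in = control$burn_in, thin = control$thin,
                       seed = expand_seed(seed, "engine"))
  chain <- run_chain(x, hierarchy, cfg, n_levels = control$n_levels)
  result <- impute(chain, x)

  structure(list(imputed = result$imputed,
                 posterior_mean = result$posterior_mean,
                 posterior_sd = result$posterior_sd,
                 n_draws_used = result$n_draws_used,
                 flags = report$flags, flag_report = report,
                 hierarchy = hierarchy, diagnostics = chain$diagnostics,
                 engine_config = cfg, control = control, seed = seed,
                 library_size = library_size, offset = offset,
                 original_totals = attr(normalized, "original_totals"),
                 call = cl),
            class = "tphpmf")
}

#' @export
print.tphpmf <- function(x, ...) {
  d <- dim(x$imputed$values)
  cat("Phylogeny-aware probabilistic matrix factorization imputation\n")
  cat(sprintf("  %d samples x %d taxa; %d entries imputed (%.1f%% of matrix)\n",
              d[1], d[2], sum(x$flags), 100 * mean(x$flags)))
  cat(sprintf("  hierarchy: %s; latent dim %d; %d posterior draws\n",
              if (is.null(x$hierarchy)) "none (single level)" else
                sprintf("%d levels", ncol(x$diagnostics)),
              x$engine_config$latent_dim, x$n_draws_used))
  invisible(x)
}

#' @export
summary.tphpmf <- function(object, ...) {
  rep <- object$flag_report
  zeros <- sum(abs(object$imputed$values - log10(object$offset)) < 1e-12) +
    sum(object$flags)
  out <- list(
    dim = dim(object$imputed$values),
    n_zero = zeros,
    n_flagged = sum(object$flags),
    n_kept_taxa = length(rep$kept_taxa),
    n_lrt_pass = sum(rep$lrt_pvalues <= object$control$lrt_alpha,
                     na.rm = TRUE),
    imputed_range = if (any(object$flags))
      range(object$imputed$values[object$flags]) else c(NA, NA),
    mean_posterior_sd = mean(object$posterior_sd, na.rm = TRUE),
    final_objective = object$diagnostics[nrow(object$diagnostics), ],
    config = object$engine_config)
  class(out) <- "summary.tphpmf"
  out
}

#' @export
print.summary.tphpmf <- function(x, ...) {
  cat(sprintf("tphpmf fit: %d samples x %d taxa\n", x$dim[1], x$dim[2]))
  cat(sprintf("  zero entries: %d, flagged non-biological and imputed: %d\n",
              x$n_zero, x$n_flagged))
  cat(sprintf("  taxa kept by prevalence screen: %d; passing LRT: %d\n",
              x$n_kept_taxa, x$n_lrt_pass))
  if (!is.na(x$imputed_range[1]))
    cat(sprintf("  imputed values in [%.3f, %.3f] (log10), mean posterior sd %.3f\n",
                x$imputed_range[1], x$imputed_range[2], x$mean_posterior_sd))
  cat("  final per-level objective:",
      paste(signif(x$final_objective, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Imputed abundance matrix of a fitted model
#'
#' @param object a `"tphpmf"` fit.
#' @param scale `"log10"` (default) for the transformed scale the model
#'   works on, or `"counts"` to back-transform to the original count scale.
#' @param ... unused.
#' @return Numeric matrix.
#' @export
fitted.tphpmf <- function(object, scale = c("log10", "counts"), ...) {
  scale <- match.arg(scale)
  if (scale == "log10") return(object$imputed$values)
  lm2 <- object$imputed
  attr(lm2, "original_totals") <- object$original_totals
  inverse_transform(lm2)
}

#' Residuals on observed entries
#'
#' Difference between observed log10 abundances and the model's low-rank
#' posterior-mean reconstruction, on non-imputed entries ( `NA` on imputed
#' ones). Useful as a lack-of-fit diagnostic.
#'
#' @param object a `"tphpmf"` fit.
#' @param ... unused.
#' @return Numeric matrix.
#' @export
residuals.tphpmf <- function(object, ...) {
  r <- object$imputed$values - object$posterior_mean
  r[object$flags] <- NA_real_
  r
}

#' Convergence diagnostics plot
#'
#' Plots the per-level regularized squared loss against the sweep index;
#' the traces should fall then stabilize.
#'
#' @param x a `"tphpmf"` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tphpmf <- function(x, ...) {
  graphics::matplot(x$diagnostics, type = "l", lty = 1,
                    xlab = "Gibbs sweep", ylab = "objective E",
                    main = "Sampler convergence by hierarchy level", ...)
  graphics::legend("topright", legend = colnames(x$diagnostics),
                   col = seq_len(ncol(x$diagnostics)), lty = 1, bty = "n")
  invisible(x)
}
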