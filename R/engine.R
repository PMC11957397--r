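#' Sampler configuration for the hierarchical factorization engine
#'
#' @param latent_dim latent dimension D of the sample and taxon vectors.
#' @param sigma2 observation noise variance on the log10 scale.
#' @param lambda_s,lambda_t ridge couplings for the sample and taxon chains;
#'   the prior variances are `sigma_s2 = sigma2 / lambda_s` and
#'   `sigma_t2 = sigma2 / lambda_t`.
#' @param n_samples total Gibbs sweeps.
#' @param burn_in initial sweeps discarded.
#' @param thin gap between retained sweeps.
#' @param seed optional integer seed; `run_chain()` seeds R's RNG with it.
#' @return An object of class `"engine_config"`.
#' @export
engine_config <- function(latent_dim = 10, sigma2 = 1, lambda_s = 1,
                          lambda_t = 1, n_samples = 200, burn_in = 50,
                          thin = 2, seed = NULL) {
  stopifnot(latent_dim >= 1, sigma2 > 0, lambda_s > 0, lambda_t > 0,
            n_samples >= 1, burn_in >= 0, burn_in < n_samples, thin >= 1)
  structure(list(latent_dim = as.integer(latent_dim), sigma2 = sigma2,
                 lambda_s = lambda_s, lambda_t = lambda_t,
                 sigma_s2 = sigma2 / lambda_s, sigma_t2 = sigma2 / lambda_t,
                 n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed),
            class = "engine_config")
}

# Layer bookkeeping for the engine. Level 1 is the coarsest ("F"); level H
# is the taxon layer holding the matrix being imputed. With a hierarchy the
# default is H = 4 (F, G, S, taxa); without one, H = 1 (plain low-rank
# factorization).
engine_structure <- function(hierarchy = NULL, n_levels = NULL,
                             n_taxa = NULL) {
  if (is.null(hierarchy)) {
    stopifnot(!is.null(n_taxa))
    return(list(H = 1L, M = n_taxa,
                parent_t = list(rep(0L, n_taxa)),
                children_t = list(rep(list(integer(0)), n_taxa)),
                levels = "taxa"))
  }
  stopifnot(inherits(hierarchy, "phylo_hierarchy"))
  if (is.null(n_levels)) n_levels <- 4L
  stopifnot(n_levels >= 1, n_levels <= 4)
  n_taxa <- length(hierarchy$taxon_ids)
  if (n_levels == 1L) return(engine_structure(NULL, n_taxa = n_taxa))
  prior_levels <- utils::tail(c("F", "G", "S"), n_levels - 1)
  n_cl <- vapply(hierarchy$assignment, max, integer(1))
  M <- c(unname(n_cl[prior_levels]), n_taxa)
  H <- length(M)
  parent_t <- vector("list", H)
  children_t <- vector("list", H)
  # taxon layer parents: the S (or finest retained) cluster of each taxon
  parent_t[[H]] <- unname(hierarchy$assignment[[prior_levels[H - 1]]])
  children_t[[H]] <- rep(list(integer(0)), n_taxa)
  for (h in seq_len(H - 1)) {
    lev <- prior_levels[h]
    parent_t[[h]] <- if (h == 1) rep(0L, M[1]) else {
      unname(hierarchy$parent[[prior_levels[h]]])
    }
    children_t[[h]] <- if (lev == "S") {
      unname(hierarchy$children$S)
    } else {
      unname(hierarchy$children[[lev]])
    }
  }
  list(H = H, M = M, parent_t = parent_t, children_t = children_t,
       levels = c(prior_levels, "taxa"))
}

# Per-level data matrices and observation indicators. `x` is the taxon-level
# log_matrix; coarser levels are aggregated from the normalized counts with
# the same mask.
build_data_levels <- function(x, hierarchy = NULL, struct = NULL) {
  if (is.null(struct)) struct <- engine_structure(hierarchy,
                                                  n_taxa = ncol(x$values))
  H <- struct$H
  data <- vector("list", H)
  data[[H]] <- list(y = x$values, delta = 1 - x$missing_mask)
  if (H > 1) {
    normalized <- 10^x$values - x$offset
    normalized[normalized < 0] <- 0
    for (h in seq_len(H - 1)) {
      agg <- aggregate_matrix(normalized, hierarchy, struct$levels[h],
                              mask = x$missing_mask, offset = x$offset)
      data[[h]] <- list(y = agg$values, delta = 1 - agg$missing_mask)
    }
  }
  data
}

#' Initialize the latent state
#'
#' Latent vectors are drawn i.i.d. from their zero-mean Gaussian priors
#' (`N(0, sigma_s2 I)` for sample vectors, `N(0, sigma_t2 I)` for taxon or
#' cluster vectors) using R's RNG, so the draw is deterministic given a
#' seed.
#'
#' @param config an [engine_config()].
#' @param n_rows number of samples N.
#' @param m_levels integer vector: number of taxa/clusters per level,
#'   coarsest first.
#' @return A latent state: list with `S` and `T`, each a list of per-level
#'   matrices (rows = samples or taxa, columns = latent dimensions).
#' @export
init_state <- function(config, n_rows, m_levels) {
  D <- config$latent_dim
  S <- lapply(m_levels, function(m)
    matrix(stats::rnorm(n_rows * D, 0, sqrt(config$sigma_s2)), n_rows, D))
  T_ <- lapply(m_levels, function(m)
    matrix(stats::rnorm(m * D, 0, sqrt(config$sigma_t2)), m, D))
  list(S = S, T = T_)
}

# Full-conditional natural parameters for taxon/cluster vector t_m^h:
# precision and linear term b (mean = solve(precision, b)). Derived from the
# joint posterior: data term over observed entries of column m at level h,
# prior pull toward the parent vector, and pulls from each child at the
# finer level.
conditional_moments_t <- function(m, h, state, data, struct, config) {
  D <- config$latent_dim
  H <- struct$H
  kids <- if (h < H) struct$children_t[[h]][[m]] else integer(0)
  prec <- diag(D) * ((1 + length(kids)) / config$sigma_t2)
  b <- numeric(D)
  del <- data[[h]]$delta[, m]
  obs <- which(del > 0)
  if (length(obs)) {
    Sobs <- state$S[[h]][obs, , drop = FALSE]
    prec <- prec + crossprod(Sobs) / config$sigma2
    b <- b + drop(crossprod(Sobs, data[[h]]$y[obs, m])) / config$sigma2
  }
  par <- if (h > 1) state$T[[h - 1]][struct$parent_t[[h]][m], ] else numeric(D)
  kid_sum <- if (length(kids)) {
    colSums(state$T[[h + 1]][kids, , drop = FALSE])
  } else numeric(D)
  b <- b + (par + kid_sum) / config$sigma_t2
  list(precision = prec, b = b, mean = drop(solve(prec, b)))
}

# Full-conditional natural parameters for sample vector s_n^h: data term
# over observed entries of row n, chain pull toward s_n^{h-1} (zero at the
# root) and s_n^{h+1} (when a finer level exists).
conditional_moments_s <- function(n, h, state, data, struct, config) {
  D <- config$latent_dim
  H <- struct$H
  prec <- diag(D) * ((1 + (h < H)) / config$sigma_s2)
  b <- numeric(D)
  del <- data[[h]]$delta[n, ]
  obs <- which(del > 0)
  if (length(obs)) {
    Tobs <- state$T[[h]][obs, , drop = FALSE]
    prec <- prec + crossprod(Tobs) / config$sigma2
    b <- b + drop(crossprod(Tobs, data[[h]]$y[n, obs])) / config$sigma2
  }
  par <- if (h > 1) state$S[[h - 1]][n, ] else numeric(D)
  nxt <- if (h < H) state$S[[h + 1]][n, ] else numeric(D)
  b <- b + (par + nxt) / config$sigma_s2
  list(precision = prec, b = b, mean = drop(solve(prec, b)))
}

# draw from N(solve(prec, b), solve(prec)) via the upper Cholesky factor;
# consumes exactly D standard normals (same order as the C++ core)
draw_gaussian <- function(prec, b) {
  U <- tryCatch(chol(prec), error = function(e)
    chol(prec + diag(1e-10, nrow(prec))))
  mn <- backsolve(U, backsolve(U, b, transpose = TRUE))
  drop(mn + backsolve(U, stats::rnorm(length(b))))
}

#' Draw one taxon/cluster latent vector from its full conditional
#' @inheritParams objective
#' @param m taxon/cluster index at level `h`.
#' @param h hierarchy level (1 = coarsest).
#' @return Sampled latent vector of length `latent_dim`.
#' @export
conditional_update_t <- function(m, h, state, data, struct, config) {
  cm <- conditional_moments_t(m, h, state, data, struct, config)
  draw_gaussian(cm$precision, cm$b)
}

#' Draw one sample latent vector from its full conditional
#' @inheritParams objective
#' @param n sample index.
#' @param h hierarchy level (1 = coarsest).
#' @return Sampled latent vector of length `latent_dim`.
#' @export
conditional_update_s <- function(n, h, state, data, struct, config) {
  cm <- conditional_moments_s(n, h, state, data, struct, config)
  draw_gaussian(cm$precision, cm$b)
}

gibbs_half_sweep <- function(state, data, struct, config, levels) {
  N <- nrow(data[[1]]$y)
  for (h in levels) {
    for (m in seq_len(struct$M[h])) {
      state$T[[h]][m, ] <- conditional_update_t(m, h, state, data, struct,
                                                config)
    }
    for (n in seq_len(N)) {
      state$S[[h]][n, ] <- conditional_update_s(n, h, state, data, struct,
                                                config)
    }
  }
  state
}

#' One full Gibbs sweep (reference implementation)
#'
#' Visits the levels top-down (coarsest to finest), updating all taxon
#' vectors then all sample vectors at each level, then bottom-up. Updates
#' are sequential: every draw conditions on the newest values. The fast
#' compiled core in [run_chain()] replicates this draw order exactly.
#'
#' @param state latent state (see [init_state()]).
#' @param data per-level data as built internally from a `log_matrix`.
#' @param struct engine structure (internal).
#' @param config an [engine_config()].
#' @return Updated state.
#' @export
gibbs_sweep <- function(state, data, struct, config) {
  state <- gibbs_half_sweep(state, data, struct, config, seq_len(struct$H))
  gibbs_half_sweep(state, data, struct, config, rev(seq_len(struct$H)))
}

#' Per-level regularized squared loss
#'
#' Evaluates, for each level h, the objective whose negative gradient the
#' Gibbs full conditionals are derived from: the masked squared
#' reconstruction error plus ridge couplings of each latent vector to its
#' parent (zero at the root) and its children at the finer level, weighted
#' by `lambda_t` and `lambda_s`.
#'
#' @param state latent state.
#' @param data per-level data list.
#' @param struct engine structure.
#' @param config an [engine_config()].
#' @return Numeric vector of length H.
#' @export
objective <- function(state, data, struct, config) {
  H <- struct$H
  E <- numeric(H)
  N <- nrow(data[[1]]$y)
  for (h in seq_len(H)) {
    R <- (data[[h]]$y - tcrossprod(state$S[[h]], state$T[[h]])) *
      data[[h]]$delta
    E[h] <- sum(R^2)
    Th <- state$T[[h]]
    Tpar <- if (h > 1) {
      state$T[[h - 1]][struct$parent_t[[h]], , drop = FALSE]
    } else {
      matrix(0, struct$M[h], config$latent_dim)
    }
    E[h] <- E[h] + config$lambda_t * sum((Th - Tpar)^2)
    if (h < H) {
      for (m in seq_len(struct$M[h])) {
        kids <- struct$children_t[[h]][[m]]
        if (length(kids)) {
          diffs <- sweep(state$T[[h + 1]][kids, , drop = FALSE], 2, Th[m, ])
          E[h] <- E[h] + config$lambda_t * sum(diffs^2)
        }
      }
    }
    Sh <- state$S[[h]]
    Spar <- if (h > 1) state$S[[h - 1]] else matrix(0, N, config$latent_dim)
    E[h] <- E[h] + config$lambda_s * sum((Sh - Spar)^2)
    if (h < H) {
      E[h] <- E[h] + config$lambda_s * sum((Sh - state$S[[h + 1]])^2)
    }
  }
  E
}

#' Run the Gibbs sampler
#'
#' Runs `n_samples` full sweeps from a fresh (or supplied) initial state,
#' retaining post-burn-in states every `thin` sweeps, and recording the
#' per-level objective after every sweep as a convergence diagnostic.
#'
#' @param x taxon-level [log_matrix()] whose masked entries are to be
#'   imputed.
#' @param hierarchy optional `"phylo_hierarchy"`; without one the engine
#'   runs a single-level (plain low-rank) factorization.
#' @param config an [engine_config()].
#' @param n_levels number of layers to use (1 to 4, default all available).
#' @param engine `"cpp"` (compiled core, default) or `"r"` (reference
#'   implementation; identical draws, much slower).
#' @param init optional initial state.
#' @return An object of class `"gibbs_chain"`: `retained_states`,
#'   `diagnostics` (n_samples x H objective matrix), `config`, `struct`.
#' @export
run_chain <- function(x, hierarchy = NULL, config = engine_config(),
                      n_levels = NULL, engine = c("cpp", "r"), init = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(x, "log_matrix"), inherits(config, "engine_config"))
  struct <- engine_structure(hierarchy, n_levels, n_taxa = ncol(x$values))
  data <- build_data_levels(x, hierarchy, struct)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init)) init <- init_state(config, nrow(x$values), struct$M)
  if (engine == "cpp") {
    res <- gibbs_run_cpp(
      lapply(data, `[[`, "y"),
      lapply(data, function(d) unname(d$delta * 1.0)),
      lapply(struct$parent_t, function(p) as.integer(p) - 1L),
      lapply(struct$children_t, function(ch)
        lapply(ch, function(k) as.integer(k) - 1L)),
      init$S, init$T,
      config$sigma2, config$sigma_s2, config$sigma_t2,
      config$n_samples, config$burn_in, config$thin)
    retained <- res$retained
    diagnostics <- res$objective
  } else {
    state <- init
    retained <- list()
    diagnostics <- matrix(NA_real_, config$n_samples, struct$H)
    for (i in seq_len(config$n_samples)) {
      state <- gibbs_sweep(state, data, struct, config)
      diagnostics[i, ] <- objective(state, data, struct, config)
      if (i > config$burn_in && (i - config$burn_in) %% config$thin == 0) {
        retained[[length(retained) + 1]] <- state
      }
    }
  }
  colnames(diagnostics) <- struct$levels
  structure(list(retained_states = retained, diagnostics = diagnostics,
                 config = config, struct = struct),
            class = "gibbs_chain")
}

#' @export
print.gibbs_chain <- function(x, ...) {
  cat(sprintf(
    "gibbs_chain: %d retained states (of %d sweeps, burn-in %d, thin %d), H = %d levels\n",
    length(x$retained_states), x$config$n_samples, x$config$burn_in,
    x$config$thin, x$struct$H))
  invisible(x)
}

#' Posterior-mean imputation from a Gibbs chain
#'
#' For every flagged entry of the finest-level matrix, the imputed value is
#' the average over retained draws of the inner product of the sample and
#' taxon latent vectors, with the across-draw standard deviation as an
#' uncertainty estimate. Imputed values are clamped below at
#' `log10(offset)` so back-transformation can never produce a negative
#' count. Non-flagged entries are returned untouched.
#'
#' @param chain a `"gibbs_chain"`.
#' @param x the taxon-level [log_matrix()] the chain was run on.
#' @param flags logical matrix of entries to impute; defaults to
#'   `x$missing_mask`.
#' @return An object of class `"imputation_result"`: `imputed` (a
#'   `log_matrix` with the mask cleared on imputed entries),
#'   `posterior_sd`, `n_draws_used`.
#' @export
impute <- function(chain, x, flags = NULL) {
  stopifnot(inherits(chain, "gibbs_chain"), inherits(x, "log_matrix"))
  if (is.null(flags)) flags <- x$missing_mask
  K <- length(chain$retained_states)
  if (K == 0) stop("empty chain: no retained states to impute from")
  H <- chain$struct$H
  acc <- 0
  acc2 <- 0
  for (st in chain$retained_states) {
    P <- tcrossprod(st$S[[H]], st$T[[H]])
    acc <- acc + P
    acc2 <- acc2 + P^2
  }
  post_mean <- acc / K
  post_var <- if (K > 1) pmax(0, (acc2 - K * post_mean^2) / (K - 1)) else
    matrix(0, nrow(post_mean), ncol(post_mean))
  out <- x
  out$values[flags] <- pmax(post_mean[flags], log_floor(x))
  out$missing_mask[flags] <- FALSE
  sd_mat <- matrix(NA_real_, nrow(flags), ncol(flags),
                   dimnames = dimnames(x$values))
  sd_mat[flags] <- sqrt(post_var[flags])
  dimnames(post_mean) <- dimnames(x$values)
  structure(list(imputed = out, posterior_sd = sd_mat,
                 posterior_mean = post_mean, n_draws_used = K),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  n_imp <- sum(!is.na(x$posterior_sd))
  cat(sprintf(
    "imputation_result: %d entries imputed from %d posterior draws\n",
    n_imp, x$n_draws_used))
  invisible(x)
}
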