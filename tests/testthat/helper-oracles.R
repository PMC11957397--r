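# Shared fixtures and independent oracles used across the suite.

# 4-leaf balanced tree, unit branches: patristic distances are path sums
balanced_tree_newick <- "((A:1,B:1):1,(C:1,D:1):1);"

# 5-taxon distance matrix whose complete-linkage dendrogram was traced by
# hand: merges at heights 1 (A,B), 2 (D,E), 5 (AB+C), 9.5 (ABC+DE)
hand_distance_matrix <- function() {
  ids <- c("A", "B", "C", "D", "E")
  D <- matrix(0, 5, 5, dimnames = list(ids, ids))
  D["A", "B"] <- 1
  D["A", "C"] <- 4;   D["B", "C"] <- 5
  D["D", "E"] <- 2
  D["A", "D"] <- 8;   D["A", "E"] <- 9
  D["B", "D"] <- 8.5; D["B", "E"] <- 9.5
  D["C", "D"] <- 7;   D["C", "E"] <- 7.5
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

# random distance matrix from random points in R^3 (valid metric)
random_distance_matrix <- function(m, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(m * 3), m, 3)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("taxon", seq_len(m)), paste0("taxon", seq_len(m)))
  D
}

# small zero-inflated count fixture with a matching random tree
make_fixture <- function(n = 30, m = 40, zero_fraction = 0.6, seed = 1) {
  complete <- simulate_complete_pmf(n, m, latent_dim = 3, seed = seed)
  zi <- inflate_zeros(complete, zero_fraction, seed = seed + 1000)
  counts <- round(inverse_transform(zi$zi))
  set.seed(seed + 2000)
  tree <- ape::rtree(m, tip.label = sample(colnames(counts)))
  list(complete = complete, zi = zi$zi, truth_mask = zi$truth_mask,
       counts = counts, tree = ape::write.tree(tree))
}

# --- independent plain-PMF Gibbs oracle (single level, zero-mean priors) ---
# Deliberately written differently from the package core: covariance-form
# draws, per-entry loops, no shared helpers.
pmf_gibbs_oracle <- function(Y, delta, D, sigma2, sigma_s2, sigma_t2,
                             n_iter, burn_in) {
  N <- nrow(Y); M <- ncol(Y)
  S <- matrix(0, N, D); T_ <- matrix(0, M, D)
  acc <- matrix(0, N, M); kept <- 0
  for (it in seq_len(n_iter)) {
    for (m in seq_len(M)) {
      A <- diag(D) / sigma_t2
      b <- rep(0, D)
      for (n in seq_len(N)) {
        if (delta[n, m] > 0) {
          A <- A + tcrossprod(S[n, ]) / sigma2
          b <- b + Y[n, m] * S[n, ] / sigma2
        }
      }
      V <- solve(A)
      T_[m, ] <- drop(V %*% b) + drop(t(chol(V)) %*% rnorm(D))
    }
    for (n in seq_len(N)) {
      A <- diag(D) / sigma_s2
      b <- rep(0, D)
      for (m in seq_len(M)) {
        if (delta[n, m] > 0) {
          A <- A + tcrossprod(T_[m, ]) / sigma2
          b <- b + Y[n, m] * T_[m, ] / sigma2
        }
      }
      V <- solve(A)
      S[n, ] <- drop(V %*% b) + drop(t(chol(V)) %*% rnorm(D))
    }
    if (it > burn_in) {
      acc <- acc + tcrossprod(S, T_)
      kept <- kept + 1
    }
  }
  acc / kept
}

# --- semi-analytic posterior mean for the 3x3, D = 1, H = 1 case ---------
# Integrates the sample latents over a dense grid; the taxon latents are
# marginalized in closed form (1-D Gaussian integrals), so
# E[s_n t_m | Y] = E_s[ s_n * mu_{t_m}(s) ] under the exact posterior.
pmf_posterior_mean_grid <- function(Y, delta, sigma2, sigma_s2, sigma_t2,
                                    target_n, target_m,
                                    grid = seq(-5, 5, length.out = 121)) {
  stopifnot(nrow(Y) == 3, ncol(Y) == 3)
  G <- as.matrix(expand.grid(s1 = grid, s2 = grid, s3 = grid))
  logw <- -rowSums(G^2) / (2 * sigma_s2)
  mu_target <- numeric(nrow(G))
  for (m in 1:3) {
    obs <- which(delta[, m] > 0)
    if (length(obs) == 0) next
    Sobs <- G[, obs, drop = FALSE]
    lam <- 1 / sigma_t2 + rowSums(Sobs^2) / sigma2
    B <- drop(Sobs %*% Y[obs, m]) / sigma2
    logw <- logw - sum(Y[obs, m]^2) / (2 * sigma2) - 0.5 * log(lam) +
      B^2 / (2 * lam)
    if (m == target_m) mu_target <- B / lam
  }
  w <- exp(logw - max(logw))
  sum(w * G[, target_n] * mu_target) / sum(w)
}

# batch-means Monte-Carlo standard error for an autocorrelated chain
batch_se <- function(draws, n_batch = 20) {
  k <- floor(length(draws) / n_batch)
  bm <- colMeans(matrix(draws[seq_len(k * n_batch)], nrow = k))
  sd(bm) / sqrt(n_batch)
}

# finite-difference gradient of a scalar function at x
fd_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# engine fixture shared by the engine and acceptance suites
make_engine_case <- function(seed = 1, n = 6, m = 8, latent_dim = 2,
                             zero_frac = 0.3, n_levels = NULL) {
  Dm <- random_distance_matrix(m, seed)
  hier <- build_hierarchy(Dm)
  complete <- simulate_complete_pmf(n, m, latent_dim = latent_dim,
                                    seed = seed)
  zi <- inflate_zeros(complete, zero_frac, seed = seed + 1)
  x <- mark_missing(zi$zi, zi$truth_mask)
  struct <- tphpmf:::engine_structure(hier, n_levels,
                                      n_taxa = ncol(x$values))
  data <- tphpmf:::build_data_levels(x, hier, struct)
  list(x = x, hier = hier, struct = struct, data = data,
       complete = complete, truth = zi$truth_mask)
}
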