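# Engine internals exercised through tphpmf::: where not exported.


test_that("full conditionals match the finite-difference gradient of E^h", {
  case <- make_engine_case(seed = 5)
  cfg <- engine_config(latent_dim = 2, sigma2 = 0.5, lambda_s = 2,
                       lambda_t = 0.8, n_samples = 2, burn_in = 0, thin = 1)
  set.seed(99)
  state <- init_state(cfg, nrow(case$x$values), case$struct$M)
  H <- case$struct$H
  for (h in c(1, 2, H)) {
    m <- min(2, case$struct$M[h])
    cm <- tphpmf:::conditional_moments_t(m, h, state, case$data,
                                         case$struct, cfg)
    f <- function(tv) {
      st <- state
      st$T[[h]][m, ] <- tv
      objective(st, case$data, case$struct, cfg)[h]
    }
    t0 <- state$T[[h]][m, ]
    analytic <- 2 * cfg$sigma2 * (cm$precision %*% t0 - cm$b)
    expect_equal(fd_gradient(f, t0), drop(analytic), tolerance = 1e-5)
    # the conditional mean is the stationary (ridge) solution of E^h
    expect_lt(max(abs(fd_gradient(f, cm$mean))), 1e-4)

    n_i <- 3
    cs <- tphpmf:::conditional_moments_s(n_i, h, state, case$data,
                                         case$struct, cfg)
    g <- function(sv) {
      st <- state
      st$S[[h]][n_i, ] <- sv
      objective(st, case$data, case$struct, cfg)[h]
    }
    s0 <- state$S[[h]][n_i, ]
    analytic_s <- 2 * cfg$sigma2 * (cs$precision %*% s0 - cs$b)
    expect_equal(fd_gradient(g, s0), drop(analytic_s), tolerance = 1e-5)
    expect_lt(max(abs(fd_gradient(g, cs$mean))), 1e-4)
  }
})

test_that("closed-form 1-D conditionals are reproduced", {
  # one observation y, s = 1, sigma2 = sigma_t2 = 1, no parent/children:
  # posterior mean y/2, variance 1/2
  y <- 1.7
  x <- log_matrix(matrix(y, 1, 1))
  cfg <- engine_config(latent_dim = 1, sigma2 = 1, lambda_s = 1,
                       lambda_t = 1, n_samples = 2, burn_in = 0)
  struct <- tphpmf:::engine_structure(NULL, n_taxa = 1)
  data <- tphpmf:::build_data_levels(x, NULL, struct)
  state <- list(S = list(matrix(1, 1, 1)), T = list(matrix(0, 1, 1)))
  cm <- tphpmf:::conditional_moments_t(1, 1, state, data, struct, cfg)
  expect_equal(cm$mean, y / 2)
  expect_equal(drop(cm$precision), 2)  # variance 1/2

  # no data: conditional reduces to the prior N(0, sigma_t2)
  x2 <- mark_missing(log_matrix(matrix(log10(1.01), 1, 1)),
                     matrix(TRUE, 1, 1))
  data2 <- tphpmf:::build_data_levels(x2, NULL, struct)
  cm2 <- tphpmf:::conditional_moments_t(1, 1, state, data2, struct, cfg)
  expect_equal(cm2$mean, 0)
  expect_equal(drop(cm2$precision), 1 / cfg$sigma_t2)
})

test_that("interior sample vectors with no data average their neighbours", {
  case <- make_engine_case(seed = 7)
  cfg <- engine_config(latent_dim = 2, sigma2 = 1, lambda_s = 1,
                       lambda_t = 1, n_samples = 2, burn_in = 0)
  # wipe all observations at an interior level
  data <- case$data
  h <- 2
  data[[h]]$delta[,] <- 0
  set.seed(11)
  state <- init_state(cfg, nrow(case$x$values), case$struct$M)
  cs <- tphpmf:::conditional_moments_s(1, h, state, data, case$struct, cfg)
  expect_equal(cs$mean,
               (state$S[[h - 1]][1, ] + state$S[[h + 1]][1, ]) / 2)
  expect_equal(diag(cs$precision), rep(2 / cfg$sigma_s2, 2))
})

test_that("compiled and reference sweeps produce identical draws", {
  case <- make_engine_case(seed = 3)
  cfg <- engine_config(latent_dim = 2, n_samples = 3, burn_in = 0, thin = 1,
                       seed = 421)
  ch_cpp <- run_chain(case$x, case$hier, cfg, engine = "cpp")
  ch_r <- run_chain(case$x, case$hier, cfg, engine = "r")
  expect_equal(ch_cpp$retained_states[[3]]$S, ch_r$retained_states[[3]]$S,
               tolerance = 1e-10)
  expect_equal(ch_cpp$retained_states[[3]]$T, ch_r$retained_states[[3]]$T,
               tolerance = 1e-10)
  expect_equal(ch_cpp$diagnostics, ch_r$diagnostics, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("retention arithmetic and determinism hold", {
  case <- make_engine_case(seed = 2)
  cfg <- engine_config(latent_dim = 2, n_samples = 10, burn_in = 4,
                       thin = 2, seed = 7)
  ch <- run_chain(case$x, case$hier, cfg)
  expect_length(ch$retained_states, 3)

  for (spec in list(c(20, 5, 3), c(7, 0, 1), c(15, 14, 4))) {
    cfgi <- engine_config(latent_dim = 1, n_samples = spec[1],
                          burn_in = spec[2], thin = spec[3], seed = 1)
    chi <- run_chain(case$x, NULL, cfgi)
    expect_length(chi$retained_states,
                  floor((spec[1] - spec[2]) / spec[3]))
  }

  ch2 <- run_chain(case$x, case$hier, cfg)
  expect_identical(ch$retained_states, ch2$retained_states)  # same seed
})

test_that("with no data the chain reproduces the hierarchical prior", {
  # all entries missing: marginal variance of a level-h latent coordinate
  # composes the chain of Gaussians: h * sigma_t2 (resp. h * sigma_s2)
  m <- 6
  Dm <- random_distance_matrix(m, 31)
  hier <- build_hierarchy(Dm)
  vals <- matrix(log10(1.01), 4, m,
                 dimnames = list(paste0("s", 1:4), rownames(Dm)))
  x <- mark_missing(log_matrix(vals), matrix(TRUE, 4, m))
  cfg <- engine_config(latent_dim = 2, sigma2 = 1, lambda_s = 1 / 0.8,
                       lambda_t = 1 / 0.5, n_samples = 3000, burn_in = 500,
                       thin = 1, seed = 13)
  ch <- run_chain(x, hier, cfg)
  H <- ch$struct$H
  for (h in c(1, H)) {
    t_draws <- vapply(ch$retained_states, function(st) st$T[[h]][1, 1],
                      numeric(1))
    s_draws <- vapply(ch$retained_states, function(st) st$S[[h]][1, 1],
                      numeric(1))
    expect_lt(abs(var(t_draws) - h * cfg$sigma_t2) / (h * cfg$sigma_t2),
              0.35)
    expect_lt(abs(var(s_draws) - h * cfg$sigma_s2) / (h * cfg$sigma_s2),
              0.35)
    expect_lt(abs(mean(t_draws)), 3 * batch_se(t_draws) + 0.05)
  }
})

test_that("posterior mean of a missing entry matches dense integration", {
  # 3x3, D = 1, H = 1: taxon latents integrated analytically, sample
  # latents on a dense grid; the Gibbs estimate must agree within MC error
  set.seed(55)
  Y <- matrix(c(1.2, 0.8, 1.9,
                0.9, 1.1, 1.5,
                1.6, 1.4, 0.0), 3, 3, byrow = TRUE)
  delta <- matrix(1, 3, 3); delta[3, 3] <- 0
  sigma2 <- 0.25
  truth <- pmf_posterior_mean_grid(Y, delta, sigma2, 1, 1, 3, 3,
                                   grid = seq(-5, 5, length.out = 81))
  x <- log_matrix(Y, delta == 0)
  cfg <- engine_config(latent_dim = 1, sigma2 = sigma2, lambda_s = sigma2,
                       lambda_t = sigma2, n_samples = 8000, burn_in = 1000,
                       thin = 2, seed = 17)
  ch <- run_chain(x, NULL, cfg)
  prods <- vapply(ch$retained_states,
                  function(st) st$S[[1]][3, ] %*% st$T[[1]][3, ],
                  numeric(1))
  se <- batch_se(prods)
  expect_lt(abs(mean(prods) - truth), 3 * se + 0.01)
})

test_that("single-level engine matches an independent plain-PMF oracle", {
  set.seed(88)
  n <- 8; m <- 10; d <- 2
  S0 <- matrix(rnorm(n * d), n, d); T0 <- matrix(rnorm(m * d), m, d)
  Y <- tcrossprod(S0, T0) + matrix(rnorm(n * m, 0, 0.3), n, m)
  delta <- matrix(rbinom(n * m, 1, 0.75), n, m)
  sigma2 <- 0.09
  x <- log_matrix(Y, delta == 0)
  cfg <- engine_config(latent_dim = d, sigma2 = sigma2, lambda_s = sigma2,
                       lambda_t = sigma2, n_samples = 4000, burn_in = 500,
                       thin = 1, seed = 91)
  ch <- run_chain(x, NULL, cfg)
  H <- 1
  prods <- sapply(ch$retained_states,
                  function(st) tcrossprod(st$S[[H]], st$T[[H]])[delta == 0])
  engine_mean <- rowMeans(prods)
  ses <- apply(prods, 1, batch_se)

  set.seed(92)
  oracle_mean <- pmf_gibbs_oracle(Y, delta, d, sigma2, 1, 1,
                                  n_iter = 4000, burn_in = 500)[delta == 0]
  tol <- 3 * sqrt(2) * ses + 0.02
  expect_gt(mean(abs(engine_mean - oracle_mean) <= tol), 0.9)
  expect_gt(cor(engine_mean, oracle_mean), 0.99)
})

test_that("imputation recovers simulated low-rank data", {
  complete <- simulate_complete_pmf(40, 60, latent_dim = 3, noise_sd = 0.2,
                                    seed = 201)
  zi <- inflate_zeros(complete, 0.7, seed = 202)
  x <- mark_missing(zi$zi, zi$truth_mask)
  cfg <- engine_config(latent_dim = 5, n_samples = 120, burn_in = 40,
                       thin = 2, seed = 203)
  ch <- run_chain(x, NULL, cfg)
  res <- impute(ch, x)
  truth <- complete$values[zi$truth_mask]
  mse_imp <- mean((res$imputed$values[zi$truth_mask] - truth)^2)
  mse_fill <- mean((log10(1.01) - truth)^2)
  expect_lt(mse_imp, mse_fill / 2)
  # untouched entries identical, imputed entries above the floor
  expect_identical(res$imputed$values[!zi$truth_mask],
                   x$values[!zi$truth_mask])
  expect_true(all(res$imputed$values >= log10(1.01) - 1e-12))
  expect_false(any(res$imputed$missing_mask))
})

test_that("more observed data never hurts reconstruction (within noise)", {
  complete <- simulate_complete_pmf(30, 40, latent_dim = 3, noise_sd = 0.2,
                                    seed = 301)
  mses <- vapply(c(0.7, 0.5, 0.1), function(zf) {
    zi <- inflate_zeros(complete, zf, b = 0, seed = 302)
    x <- mark_missing(zi$zi, zi$truth_mask)
    cfg <- engine_config(latent_dim = 5, n_samples = 100, burn_in = 30,
                         thin = 2, seed = 303)
    res <- impute(run_chain(x, NULL, cfg), x)
    mean((res$imputed$values[zi$truth_mask] -
            complete$values[zi$truth_mask])^2)
  }, numeric(1))
  # observed fraction rises 30% -> 50% -> 90%; allow 10% noise slack
  expect_lt(mses[2], mses[1] * 1.1)
  expect_lt(mses[3], mses[2] * 1.1)
})

test_that("chains from different seeds agree on posterior means", {
  case <- make_engine_case(seed = 9, n = 10, m = 12, zero_frac = 0.4)
  run_one <- function(seed) {
    cfg <- engine_config(latent_dim = 2, n_samples = 2000, burn_in = 400,
                         thin = 1, seed = seed)
    ch <- run_chain(case$x, case$hier, cfg)
    H <- ch$struct$H
    prods <- sapply(ch$retained_states, function(st)
      tcrossprod(st$S[[H]], st$T[[H]])[case$truth])
    list(mean = rowMeans(prods), se = apply(prods, 1, batch_se))
  }
  a <- run_one(1001); b <- run_one(2002)
  tol <- 3 * sqrt(a$se^2 + b$se^2) + 0.02
  expect_gt(mean(abs(a$mean - b$mean) <= tol), 0.9)
})

test_that("objective evaluates the printed loss in degenerate cases", {
  x_all_missing <- mark_missing(log_matrix(matrix(log10(1.01), 2, 2)),
                                matrix(TRUE, 2, 2))
  struct <- tphpmf:::engine_structure(NULL, n_taxa = 2)
  data <- tphpmf:::build_data_levels(x_all_missing, NULL, struct)
  cfg <- engine_config(latent_dim = 2, n_samples = 2, burn_in = 0)
  zero_state <- list(S = list(matrix(0, 2, 2)), T = list(matrix(0, 2, 2)))
  expect_equal(objective(zero_state, data, struct, cfg), 0)

  y <- 2.3
  x_one <- log_matrix(matrix(y, 1, 1))
  struct1 <- tphpmf:::engine_structure(NULL, n_taxa = 1)
  data1 <- tphpmf:::build_data_levels(x_one, NULL, struct1)
  zs <- list(S = list(matrix(0, 1, 2)), T = list(matrix(0, 1, 2)))
  expect_equal(objective(zs, data1, struct1, cfg), y^2)
})

test_that("impute handles single-state chains and empty flag sets", {
  case <- make_engine_case(seed = 12)
  cfg <- engine_config(latent_dim = 2, n_samples = 1, burn_in = 0, thin = 1,
                       seed = 5)
  ch <- run_chain(case$x, case$hier, cfg)
  expect_length(ch$retained_states, 1)
  res <- impute(ch, case$x)
  st <- ch$retained_states[[1]]
  H <- ch$struct$H
  pred <- tcrossprod(st$S[[H]], st$T[[H]])
  flagged <- case$x$missing_mask
  expect_equal(res$imputed$values[flagged],
               pmax(pred[flagged], log10(1.01)))

  no_flags <- case$x
  no_flags$missing_mask[] <- FALSE
  res2 <- impute(ch, no_flags)
  expect_identical(res2$imputed$values, no_flags$values)

  empty <- ch; empty$retained_states <- list()
  expect_error(impute(empty, case$x), "empty chain")
})

test_that("init_state is seed-deterministic with prior-scale draws", {
  cfg <- engine_config(latent_dim = 3, lambda_s = 4, lambda_t = 0.25,
                       n_samples = 2, burn_in = 0)
  set.seed(1); a <- init_state(cfg, 5, c(2, 4))
  set.seed(1); b <- init_state(cfg, 5, c(2, 4))
  expect_identical(a, b)
  set.seed(2); big <- init_state(cfg, 2500, c(2000))
  expect_lt(abs(sd(big$S[[1]]) - sqrt(cfg$sigma_s2)) / sqrt(cfg$sigma_s2),
            0.1)
  expect_lt(abs(sd(big$T[[1]]) - sqrt(cfg$sigma_t2)) / sqrt(cfg$sigma_t2),
            0.1)
})
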