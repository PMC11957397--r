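test_that("low-rank generator has the advertised spectral structure", {
  sim <- simulate_complete_pmf(40, 50, latent_dim = 3, noise_sd = 0,
                               seed = 31)
  expect_true(all(sim$values > log10(1.01)))
  # noiseless product is rank 3; the affine rescale adds at most rank 1
  sv <- svd(sim$values)$d
  expect_lt(sv[5] / sv[1], 1e-10)
  sv_centered <- svd(scale(sim$values, scale = FALSE))$d
  expect_lt(sv_centered[4] / sv_centered[1], 1e-10)

  expect_identical(simulate_complete_pmf(10, 12, seed = 5)$values,
                   simulate_complete_pmf(10, 12, seed = 5)$values)
  with_noise <- simulate_complete_pmf(200, 100, latent_dim = 3,
                                      noise_sd = 0.2, seed = 32)
  ev <- svd(scale(with_noise$values, scale = FALSE))$d^2
  expect_gt(sum(ev[1:3]) / sum(ev), 0.9)  # 3 dominant directions
})

test_that("linear generator excludes self-weights and reproduces", {
  sim <- simulate_complete_linear(20, 25, seed = 41)
  expect_true(all(sim$values > log10(1.01)))
  expect_identical(sim$values, simulate_complete_linear(20, 25, seed = 41)$values)

  # entry (i, j) has zero partial dependence on its own seed value:
  # regenerate with the seed matrix perturbed only at (i, j)
  gen <- function(bump) {
    set.seed(42)
    n <- 10; m <- 12
    Y0 <- matrix(rnorm(n * m, 3, 1), n, m)
    Y0[4, 7] <- Y0[4, 7] + bump
    alpha <- matrix(0, m, m); beta <- matrix(0, n, n)
    for (j in seq_len(m)) {
      pick <- sample(setdiff(seq_len(m), j), 3)
      w <- runif(3); alpha[pick, j] <- 0.5 * w / sum(w)
    }
    for (i in seq_len(n)) {
      pick <- sample(setdiff(seq_len(n), i), 3)
      w <- runif(3); beta[pick, i] <- 0.5 * w / sum(w)
    }
    (Y0 %*% alpha + t(crossprod(Y0, beta)))[4, 7]
  }
  expect_equal(gen(0), gen(10))  # same draws, bumped seed entry: no effect
})

test_that("semi-simulation fills zeros from per-taxon non-zero moments", {
  base <- simulate_complete_pmf(30, 10, seed = 51)
  expect_identical(simulate_complete_semi(base, seed = 52)$values,
                   base$values)  # no zeros: unchanged

  vals <- base$values
  vals[1:10, 1] <- log10(1.01)  # knock out a third of taxon 1
  templ <- log_matrix(vals)
  out <- simulate_complete_semi(templ, seed = 53)
  expect_true(all(out$values > log10(1.01) - 1e-12))
  expect_identical(out$values[-(1:10), 1], vals[-(1:10), 1])

  # constant non-zero values: replacements equal that constant
  cvals <- matrix(2.5, 20, 3)
  cvals[1:5, 2] <- log10(1.01)
  cout <- simulate_complete_semi(log_matrix(cvals), seed = 54)
  expect_equal(cout$values[1:5, 2], rep(2.5, 5))

  # moment matching at large n
  big <- matrix(rnorm(20000, 3, 0.7), 10000, 2)
  big[1:5000, 1] <- log10(1.01)
  bout <- simulate_complete_semi(log_matrix(big), seed = 55)
  filled <- bout$values[1:5000, 1]
  src <- big[5001:10000, 1]
  expect_lt(abs(mean(filled) - mean(src)), 0.05)
  expect_lt(abs(sd(filled) - sd(src)) / sd(src), 0.05)
})

test_that("zero inflation calibrates to the target fraction", {
  complete <- simulate_complete_pmf(100, 150, seed = 61)
  zi <- inflate_zeros(complete, 0.7, seed = 62)
  expect_gt(zi$zero_fraction_achieved, 0.66)
  expect_lt(zi$zero_fraction_achieved, 0.74)
  # truth mask records exactly the dropped entries
  dropped <- zi$zi$values == log10(1.01)
  expect_true(all(zi$truth_mask == dropped))

  # b = 0: uniform dropout, binomial concentration around the target
  zi0 <- inflate_zeros(complete, 0.5, b = 0, seed = 63)
  n <- length(complete$values)
  expect_lt(abs(zi0$zero_fraction_achieved - 0.5),
            2 * sqrt(0.25 / n) + 0.01)

  # b > 0: low-abundance entries drop out more often
  zi1 <- inflate_zeros(complete, 0.5, b = 2, seed = 64)
  dropped_mean <- mean(complete$values[zi1$truth_mask])
  kept_mean <- mean(complete$values[!zi1$truth_mask])
  expect_lt(dropped_mean, kept_mean)

  expect_error(inflate_zeros(complete, 1.2), "target_zero_fraction")
})

test_that("depth adjustment resamples to exact row totals", {
  set.seed(71)
  counts <- matrix(rpois(20 * 30, 50), 20, 30)
  for (depth in c(1000, 2000, 5000, 10000)) {
    sub <- adjust_depth(counts, depth, seed = 72)
    expect_equal(unname(rowSums(sub)), rep(depth, 20))
  }
  # expected proportions preserved
  deep <- adjust_depth(counts, 1e5, seed = 73)
  p_true <- counts[1, ] / sum(counts[1, ])
  expect_lt(max(abs(deep[1, ] / 1e5 - p_true)), 0.01)
  expect_identical(adjust_depth(counts, 500, seed = 74),
                   adjust_depth(counts, 500, seed = 74))
  expect_error(adjust_depth(matrix(0, 1, 3), 100), "empty sample")
})

test_that("outlier injection appends inverted-profile samples", {
  sim <- simulate_complete_pmf(15, 20, seed = 81)
  expect_identical(inject_outliers(sim, 0), sim)
  out <- inject_outliers(sim, 2, seed = 82)
  expect_equal(nrow(out$values), 17)
  for (k in 16:17) {
    expect_length(unique(out$values[k, ]), 2)
    expect_setequal(unique(out$values[k, ]),
                    c(max(sim$values), log10(1.01)))
  }
})

test_that("Wasserstein-1 matches closed forms and an external oracle", {
  expect_equal(wasserstein1(c(0, 1), c(0, 1)), 0)
  expect_equal(wasserstein1(0, 1), 1)
  # frozen from scipy.stats.wasserstein_distance
  expect_equal(wasserstein1(c(0.2, 1.5, 3.1, 4.0), c(0.5, 0.9, 2.2)), 1.15,
               tolerance = 1e-12)
  # translation by c shifts W1 by exactly |c|
  set.seed(83)
  x <- rnorm(40); y <- rnorm(25)
  expect_equal(wasserstein1(x + 2, x), 2)
  expect_gte(wasserstein1(x, y), 0)
})

test_that("evaluation metrics behave on identity and shift cases", {
  sim <- simulate_complete_pmf(20, 25, seed = 91)
  mask <- matrix(FALSE, 20, 25); mask[1:5, ] <- TRUE
  perfect <- evaluate(sim, sim, mask)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mean_pearson, 1)
  expect_equal(perfect$wasserstein_mean_sd, 0)

  shifted <- sim
  shifted$values[mask] <- shifted$values[mask] + 0.3
  rep <- evaluate(shifted, sim, mask)
  expect_equal(rep$mse, 0.09, tolerance = 1e-12)

  const <- sim
  const$values[, 1] <- 1
  expect_warning(evaluate(const, sim, mask), "constant")
})
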