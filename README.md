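# tphpmf

Imputation of non-biological zeros in microbiome count matrices by
phylogeny-aware hierarchical Bayesian probabilistic matrix factorization.

## The problem

Sample-by-taxon count matrices from 16S or shotgun metagenomic sequencing
are typically 60–90% zeros. Some of those zeros are biological (the taxon
really is absent); many are technical — limited sequencing depth, DNA
extraction or PCR artifacts. Treating technical dropouts as genuine
absences biases downstream analyses (differential abundance, taxon-taxon
correlation, disease prediction). This package (a) decides which zeros are
technical, and (b) replaces only those with model-based estimates, leaving
biological zeros untouched.

## The model

**Preprocessing.** Counts `O` are scaled so every sample sums to 10^6 and
log-transformed, `Y_ij = log10(O^N_ij + 1.01)`; the offset 1.01 keeps every
value strictly positive (a zero count maps to `log10(1.01)`).

**Which zeros are technical?** Taxa absent essentially everywhere are
screened out by a one-sided binomial (Wilson) test and never imputed. For
each remaining taxon `j` the abundances follow a two-component mixture

    Y_ij ~ p_j Gamma(alpha_j, beta_j) + (1 - p_j) N(x_i' gamma_j, sigma_j^2)

where the gamma component captures the dropout mass near the zero floor and
the normal regression (on optional sample covariates `x_i`) the genuine
abundances. The fit is by EM with exact weighted M-steps; a likelihood
ratio test against the normal-only model screens out taxa with no evidence
of a dropout component. A zero entry is flagged as non-biological when its
posterior probability of coming from the gamma component is at least 0.5.

**Imputation.** Taxa are organized into a three-level hierarchy ("S", "G",
"F") by complete-linkage clustering of patristic distances from a
phylogenetic tree. Each sample and each taxon (at each level `h`) carries a
latent vector; observations satisfy `Y^h_nm ~ N(s_n^h' t_m^h, sigma^2)`,
and each latent vector's prior is centred on its parent at the adjacent
coarser level (`N(t_p(m)^{h-1}, sigma_t^2 I)`, root prior zero). A Gibbs
sampler with exact Gaussian full conditionals sweeps the hierarchy top-down
and bottom-up; flagged entries are imputed by the posterior mean of
`s_n' t_m` at the taxon level, clamped below at `log10(1.01)`.

The sampler's inner loop is compiled (RcppArmadillo); a pure-R reference
implementation with identical draws backs it in the test suite.

## Worked example

Simulate a complete low-rank abundance matrix, knock ~70% of entries down
to zero with a binomial dropout, and recover them:

```r
library(tphpmf)
set.seed(1)
complete <- simulate_complete_pmf(n_samples = 40, n_taxa = 60,
                                  latent_dim = 3, seed = 1)
zi     <- inflate_zeros(complete, target_zero_fraction = 0.7, b = 0, seed = 2)
counts <- round(inverse_transform(zi$zi))
tree   <- ape::write.tree(ape::rtree(60, tip.label = colnames(counts)))

fit <- tphpmf(counts, tree = tree, seed = 3)
fit
#> Phylogeny-aware probabilistic matrix factorization imputation
#>   40 samples x 60 taxa; 1663 entries imputed (69.3% of matrix)
#>   hierarchy: 4 levels; latent dim 10; 75 posterior draws

evaluate(fit$imputed, complete, zi$truth_mask)
#> benchmark_report (zero fraction 0.693)
#>   MSE on dropped entries: 3.2567
#>   mean per-taxon Pearson: 0.4353
#>   Wasserstein-1 (mean/sd): 3.4474

evaluate(zi$zi, complete, zi$truth_mask)$mse  # zero-fill baseline
#> [1] 28.7514
```

The imputation cuts the reconstruction error on the dropped entries by
roughly a factor of nine relative to leaving the zeros in place, while the
mean per-taxon Pearson correlation with the complete data rises well above
the zero-filled baseline. `fitted(fit)` returns the imputed matrix on the
log10 scale (`scale = "counts"` back-transforms), `summary(fit)` reports
the flagging and sampler diagnostics, and `plot(fit)` shows the per-level
objective traces.

Real data enter through `read_count_matrix()`, `read_covariates()` and
either a newick tree or a distance matrix; `run_impute(config)` (or the
CLI script in `inst/cli/tphpmf.R`) runs the whole pipeline from a YAML
config and writes the imputed matrix, posterior standard deviations, flag
mask, diagnostics, and a reproducibility manifest. Hyperparameters
(latent dimension, sampler length, ridge couplings, cut heights) are tuned
by entry-masking cross-validation via `tuning_grid()` / `cross_validate()`.

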