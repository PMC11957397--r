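---
title: "Methods: phylogeny-aware imputation of microbiome zeros"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-aware imputation of microbiome zeros}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model the package implements, the
choices that were genuinely open when building it, and what the synthetic
benchmarks do and do not demonstrate.

## Pipeline overview

Given a sample-by-taxon count matrix, the pipeline is:

1. **Normalize and transform.** Each sample is scaled to a common library
   size (default $10^6$) and entries become $Y_{ij} = \log_{10}(O^N_{ij} +
   1.01)$. The pseudo-count must exceed 1 so transformed values are
   strictly positive; a raw zero maps to the floor $\log_{10}(1.01)
   \approx 0.0043$.
2. **Flag non-biological zeros** (gamma-normal mixture, below).
3. **Build the phylogenetic hierarchy** (complete linkage, three cuts).
4. **Impute flagged entries** by Gibbs sampling a hierarchical Bayesian
   probabilistic matrix factorization and averaging posterior draws.

Only entries that are zero in the raw counts are ever altered, and only
when both the likelihood-ratio screen and the posterior-membership rule
agree the zero looks technical.

## The zero-identification model

A taxon absent in (essentially) every sample carries no information for a
mixture fit; the prevalence screen keeps taxon $j$ only when the one-sided
Wilson 95% lower confidence bound for the proportion of samples with
abundance above the threshold (default: any non-zero count) is strictly
positive. The Wilson dialect is used because it is stable at small $n$ and
never produces negative bounds; note its lower bound is positive exactly
when at least one sample is positive, so at the default threshold the
screen reduces to a presence requirement — the confidence level matters
once `abundance_threshold` is raised.

For each retained taxon the log abundances follow
$$Y_{ij} \sim p_j\,\Gamma(\alpha_j, \beta_j) + (1 - p_j)\,
N(x_i^\top \gamma_j, \sigma_j^2),$$
fitted by EM. The M-step maximizers are exact: the mixing weight is the
mean responsibility, the normal part is responsibility-weighted least
squares, and the gamma part is the responsibility-weighted MLE obtained by
Newton iteration on the profile digamma equation $\log\alpha -
\psi(\alpha) = \log \bar y_r - \overline{\log y}_r$ (method-of-moments
initialization). Exact conditional maximization guarantees the
observed-data log-likelihood is non-decreasing, which the tests assert at
tolerance $10^{-8}$ on every iteration.

Three guard rails deal with degenerate fits:

* a (near-)constant column is an error — there is nothing to fit;
* if EM lands on a local mode below the null's likelihood, the fit
  collapses to the null (this also keeps the LRT statistic non-negative);
* **parsimony collapse:** when the LRT finds no support for the mixture
  (p > 0.05 by default), the reported estimate collapses to the null with
  $p_j = 0$. The mixture is not identified on one-component data — a
  high-shape gamma can mimic a normal, leaving the likelihood flat in
  $p_j$ — so the EM estimate of $p_j$ on such taxa reflects its
  initialization, not the data. Collapsing is conservative for flagging:
  an unsupported mixture flags nothing.

The LRT compares the mixture to the normal-regression-only null with a
$\chi^2_3$ reference (the three extra parameters $p_j, \alpha_j,
\beta_j$). The null lies on the boundary $p_j = 0$, so the reference is
approximate and conservative; the suite checks empirically that the
fraction of pure-normal taxa with $p \le 0.05$ stays below 0.10. A zero
entry of an LRT-passing taxon is flagged when its posterior membership in
the gamma component, computed in log space, is at least 0.5.

Covariates, when supplied, enter the normal component standardized
(continuous) or one-hot encoded with the first level dropped
(categorical); without metadata the regression is intercept-only.

## The hierarchy

Patristic distances (path sums of branch lengths, via `ape`) or a
user-supplied distance matrix feed one complete-linkage dendrogram, cut at
three increasing heights to give nested partitions S (finest), G, F
(coarsest). Default heights are the 25/50/75% quantiles of the
off-diagonal distances — the paperless choice that adapts to the scale of
any tree — and are exposed as hyperparameters because real datasets differ
in distance dispersion. Cluster ids are deterministic (numbered by
smallest member index), so identical inputs give identical hierarchies.

The engine runs over $H = 4$ layers: the taxon layer (the matrix being
imputed) plus S, G, F as prior layers. Coarser-level matrices $Y^h$
aggregate member taxa by **summing normalized counts before the log
transform** — abundances are additive under taxonomic coarsening, whereas
log abundances are not. An aggregated entry is missing only when every
member entry is missing; during cross-validation, hidden entries are
excluded from the sums so no held-out information leaks into coarser
levels. With no tree or distances the engine degrades to $H = 1$, a plain
probabilistic matrix factorization, with a warning.

## The sampler

With $\delta^h_{nm}$ indicating observed entries, the posterior couples
each latent vector to its data, its parent at the coarser level (root
priors are zero), and its children at the finer level. The full
conditional of a taxon vector $t_m^h$ is Gaussian with precision
$$\Lambda = \tfrac{1}{\sigma^2} \textstyle\sum_n \delta^h_{nm} s_n^h
s_n^{h\top} + \tfrac{1}{\sigma_t^2}\bigl(1 + |c(m)|\,\mathbb{1}[h < H]
\bigr) I$$
and mean $\Lambda^{-1}\bigl[\tfrac{1}{\sigma^2}\sum_n \delta^h_{nm}
y^h_{nm} s^h_n + \tfrac{1}{\sigma_t^2}(t^{h-1}_{p(m)} + \sum_{m' \in c(m)}
t^{h+1}_{m'})\bigr]$; sample vectors are analogous with exactly one
"child" (the same sample at the finer level). Two independent oracles
verify the derivation in the tests: the finite-difference gradient of the
per-level regularized loss $E^h$ vanishes at the conditional mean
(tolerance $10^{-5}$), and on a $3{\times}3$, $D=1$ problem the chain's
posterior mean of a missing entry matches semi-analytic dense integration
within Monte-Carlo error.

One sweep visits levels coarsest to finest and back, updating all taxon
vectors then all sample vectors per level, sequentially (each draw
conditions on the newest values; within-level order is ascending index).
Draws use Cholesky factors of the precision with a $10^{-10}$ jitter
retry; the compiled core consumes R's RNG in exactly the same order as the
reference R implementation, so the two are interchangeable and the whole
pipeline is bit-reproducible from one seed (expanded into per-stage
substreams, so changing one stage never perturbs another's randomness).

Defaults: latent dimension $D = 10$, $\sigma^2 = 1$, $\lambda_s =
\lambda_t = 1$ (i.e. $\sigma_s^2 = \sigma_t^2 = 1$), 200 sweeps, burn-in
50, thinning 2 (75 retained draws). $\sigma^2, \sigma_s^2, \sigma_t^2$
are fixed hyperparameters, tunable by cross-validation, not resampled in
the Gibbs loop. Imputation uses the finest level only: the imputed value
is the across-draw mean of $s_n^\top t_m$, clamped below at
$\log_{10}(1.01)$ so back-transformation cannot produce negative counts;
the across-draw sd is reported as an uncertainty measure. The imputed
matrix is returned on the $\log_{10}$ scale by default (the scale all
benchmark errors are computed on); `fitted(fit, scale = "counts")`
back-transforms.

## Hyperparameter tuning

`cross_validate()` hides random entry folds (default 10; entries, not
samples, because the estimand is entry reconstruction), reruns the
sampler, and scores RMSE on the hidden entries; grid search keeps the
selection deterministic, and ties break toward the smaller latent
dimension and fewer sweeps. Already-missing entries are never hidden or
scored. An optional `n_repeats` repeats the whole loop, reflecting the
two possible readings of a "number of cross-validations" default of 10.

## What the synthetic benchmarks emulate

Three generators mirror the benchmark designs:

1. **Low-rank:** $Y = ST^\top + \varepsilon$ with i.i.d. standard normal
   latents, affinely rescaled to mean 3, sd 1 on the $\log_{10}$ scale —
   typical of normalized abundance data — and shifted strictly above the
   zero floor.
2. **Linear:** each entry a sparse weighted combination of the same
   sample's other taxa and the same taxon's other samples (self-weights
   are structurally zero), plus noise.
3. **Semi-simulation:** zeros of a template matrix replaced by per-taxon
   normal draws with that taxon's observed non-zero moments (global
   moments as the small-sample fallback), truncated at the floor.

Zero inflation drops each entry independently with probability
$\operatorname{logit}^{-1}(a - b\,y_{ij})$; the intercept is calibrated by
bisection to the target zero fraction (60–80% is the realistic sweep).
The slope defaults to $b = 1$ — dropout should hit low abundances harder —
with $b = 0$ the pure-binomial special case. The acceptance benchmarks
use $b = 0$: the zero-proportion sweep is defined by a binomial mechanism,
and under $b > 0$ the *zero-fill baseline* becomes artificially
rank-informative (low values map to the floor in order), which distorts
the baseline comparison rather than the method. Robustness probes:
multinomial resampling to fixed sequencing depths (1000–10000 reads), and
appended outlier samples whose abundance profile is inverted (maximum
value on the lowest-quartile taxa, floor elsewhere).

Metrics: MSE over the dropped entries, mean per-taxon Pearson correlation
between imputed and complete columns (constant columns excluded with a
warning), and the exact one-dimensional Wasserstein-1 distance between the
per-taxon mean/sd-ratio distributions (the raw (mean, sd) pairs are also
returned, so the ratio-vs-pair ambiguity of "mean/sd distribution" stays
inspectable).

These generators reproduce the statistical structure the method exploits —
low-rank signal, taxon-taxon linear dependence, abundance-dependent
dropout — but not everything in real data: no compositionality artifacts,
no batch effects, and a random phylogeny unrelated to the latent structure
(so passing benchmarks show robustness to an uninformative tree, not the
gain from an informative one). Problem sizes are kept modest (50 samples
× 100 taxa for the design benchmarks, 40 × 80 for robustness, 3–5
replicates) — comfortably representative while keeping the whole suite in
the tens of seconds.

## Numerical choices and limitations

* EM: tolerance $10^{-6}$ on the log-likelihood, at most 100 iterations;
  non-convergence is a warning, not an error, and per-taxon failures skip
  the taxon rather than aborting the run.
* Mixture densities and posterior memberships are computed in log space;
  $e_{ij}$ is invariant to common scaling of the two densities.
* The LRT's $\chi^2_3$ null is approximate (boundary non-regularity); it
  is a screen, not an inferential claim.
* Cut heights collapse to an error when all pairwise distances are equal
  (fewer than three distinct scales exist); supply explicit heights.
* The linkage tie-break follows `stats::hclust`; cluster ids are made
  deterministic by renumbering.
* Imputation variance from the chain understates total uncertainty (it
  ignores hyperparameter and flagging uncertainty).
* The sampler's cost per sweep is linear in observed entries times $D^2$;
  the compiled core handles thousands of taxa in seconds, but the
  all-levels state is kept densely, so extremely large matrices (say
  $>10^5$ taxa) would need a sparse refactor.
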