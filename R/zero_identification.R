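#' One-sided Wilson lower confidence bound for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param confidence one-sided confidence level, default 0.95.
#' @return Lower bound(s) of the one-sided Wilson score interval; vectorized
#'   over `k`.
#' @export
wilson_lower_bound <- function(k, n, confidence = 0.95) {
  stopifnot(n > 0, all(k >= 0), all(k <= n), confidence > 0, confidence < 1)
  z <- stats::qnorm(confidence)
  phat <- k / n
  centre <- phat + z^2 / (2 * n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  (centre - half) / (1 + z^2 / n)
}

#' Screen taxa by prevalence with a one-sided binomial test
#'
#' A taxon is retained for mixture fitting and imputation when the lower
#' bound of the one-sided Wilson confidence interval for the proportion of
#' samples in which its abundance exceeds `abundance_threshold` is strictly
#' positive. Taxa absent (at or below the threshold) in every sample are
#' dropped; their zeros are treated as biological and left untouched.
#'
#' @param x a [log_matrix()].
#' @param abundance_threshold normalized-abundance threshold an entry must
#'   exceed to count as "present"; default 0 (any non-zero count).
#' @param confidence one-sided confidence level, default 0.95.
#' @return Character vector of retained taxon ids.
#' @export
filter_taxa_binomial <- function(x, abundance_threshold = 0,
                                 confidence = 0.95) {
  stopifnot(inherits(x, "log_matrix"))
  cutoff <- log10(abundance_threshold + x$offset) + 1e-12
  present <- x$values > cutoff & !x$missing_mask
  k <- colSums(present)
  lb <- wilson_lower_bound(k, nrow(x$values), confidence)
  colnames(x$values)[lb > 0]
}

# ---- gamma-normal mixture ----------------------------------------------

# weighted gamma MLE: solve log(a) - digamma(a) = s by Newton on the profile
solve_gamma_shape <- function(s, init = NULL) {
  if (!is.finite(s) || s <= 1e-12) return(1e6)  # near-degenerate: huge shape
  a <- if (is.null(init) || !is.finite(init) || init <= 0) {
    (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  } else init
  for (i in 1:50) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * (1 + a)) { a <- a_new; break }
    a <- a_new
  }
  min(max(a, 1e-8), 1e8)
}

# observed-data log-likelihood and responsibilities, computed in log space
mixture_estep <- function(y, p, alpha, beta, mu, sigma) {
  la <- log(p) + stats::dgamma(y, shape = alpha, rate = beta, log = TRUE)
  lb <- log1p(-p) + stats::dnorm(y, mean = mu, sd = sigma, log = TRUE)
  m <- pmax(la, lb)
  ll_i <- m + log(exp(la - m) + exp(lb - m))
  list(r = exp(la - ll_i), loglik = sum(ll_i))
}

#' Fit a gamma-normal mixture to one taxon's log abundances
#'
#' Models each log10 abundance as drawn with probability `p` from a gamma
#' component (capturing the near-zero technical-dropout mass) and with
#' probability `1 - p` from a normal regression on sample covariates
#' (capturing genuine biological abundance). Fitted by EM; the M-step uses
#' exact responsibility-weighted maximizers (weighted least squares for the
#' normal part, profile-Newton gamma MLE), so the observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param y strictly positive numeric vector (one column of a `log_matrix`).
#' @param X design matrix with leading intercept column; `NULL` for
#'   intercept-only.
#' @param tol convergence tolerance on the log-likelihood, default 1e-6.
#' @param max_iter maximum EM iterations, default 100.
#' @param collapse_alpha when the LRT p-value exceeds this level the mixture
#'   is unsupported by the data (on such data the gamma component is not
#'   identified: a high-shape gamma can mimic the normal), and the reported
#'   point estimate collapses to the parsimonious null: `p = 0` with the
#'   null regression coefficients. Set to `NA` to disable.
#' @return An object of class `"mixture_fit"`: mixing weight `p`, gamma
#'   shape/rate `alpha`, `beta`, regression coefficients `gamma_coef`,
#'   residual sd `sigma`, `loglik_mixture`, `loglik_null` (normal regression
#'   alone), `lrt_pvalue`, `converged`, `n_iter` and the likelihood trace.
#' @export
fit_gamma_normal_mixture <- function(y, X = NULL, tol = 1e-6,
                                     max_iter = 100, collapse_alpha = 0.05) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("y must be finite")
  if (any(y <= 0)) stop("y must be strictly positive")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  stopifnot(is.matrix(X), nrow(X) == n)
  q <- ncol(X)
  if (n < q + 3) stop("need at least q + 3 observations to fit the mixture")
  if (stats::sd(y) < 1e-10) stop("degenerate column: y is (near) constant")

  # null model: normal regression only
  null_fit <- stats::lm.fit(X, y)
  res0 <- null_fit$residuals
  sigma2_0 <- max(mean(res0^2), 1e-12)
  loglik_null <- sum(stats::dnorm(y, y - res0, sqrt(sigma2_0), log = TRUE))

  # initialization: low quartile seeds the gamma component
  split <- stats::quantile(y, 0.25, names = FALSE)
  low <- y <= split
  if (sum(low) < 2) low <- y <= sort(y)[2]
  if (sum(!low) < q + 2) low <- y <= sort(y)[max(2, n - q - 2)]
  m0 <- mean(y[low]); v0 <- max(stats::var(y[low]), 1e-6)
  alpha <- max(m0^2 / v0, 1e-3)
  beta <- alpha / m0
  hi_fit <- stats::lm.fit(X[!low, , drop = FALSE], y[!low])
  gamma_coef <- ifelse(is.na(hi_fit$coefficients), 0, hi_fit$coefficients)
  mu <- drop(X %*% gamma_coef)
  sigma <- max(sqrt(mean((y[!low] - mu[!low])^2)), 1e-3)
  p <- min(max(mean(low), 0.05), 0.95)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    es <- mixture_estep(y, p, alpha, beta, mu, sigma)
    r <- es$r
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) && abs(es$loglik - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    # M-step
    p <- min(max(mean(r), 1e-10), 1 - 1e-10)
    w <- 1 - r
    if (sum(w) > 1e-8) {
      wls <- stats::lm.wfit(X, y, w)
      gamma_coef <- ifelse(is.na(wls$coefficients), 0, wls$coefficients)
      mu <- drop(X %*% gamma_coef)
      sigma <- max(sqrt(sum(w * (y - mu)^2) / sum(w)), 1e-6)
    }
    sr <- sum(r)
    if (sr > 1e-8) {
      mg <- sum(r * y) / sr
      s_stat <- log(mg) - sum(r * log(y)) / sr
      alpha <- solve_gamma_shape(s_stat, init = alpha)
      beta <- alpha / mg
    }
  }
  es <- mixture_estep(y, p, alpha, beta, mu, sigma)
  loglik_mixture <- es$loglik
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")

  # guard against a local mode worse than the null: collapse to the null
  if (loglik_mixture < loglik_null - 1e-8) {
    p <- 1e-10
    gamma_coef <- ifelse(is.na(null_fit$coefficients), 0,
                         null_fit$coefficients)
    mu <- drop(X %*% gamma_coef)
    sigma <- sqrt(sigma2_0)
    loglik_mixture <- mixture_estep(y, p, alpha, beta, mu, sigma)$loglik
  }

  fit <- structure(list(
    taxon_id = NA_character_, p = p, alpha = alpha, beta = beta,
    gamma_coef = gamma_coef, sigma = sigma,
    loglik_mixture = loglik_mixture, loglik_null = loglik_null,
    lrt_pvalue = NA_real_, converged = converged, n_iter = iter,
    loglik_trace = trace), class = "mixture_fit")
  fit$lrt_pvalue <- likelihood_ratio_test(fit)
  if (!is.na(collapse_alpha) && fit$lrt_pvalue > collapse_alpha) {
    fit$p <- 0
    fit$gamma_coef <- ifelse(is.na(null_fit$coefficients), 0,
                             null_fit$coefficients)
    fit$sigma <- sqrt(sigma2_0)
  }
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "gamma-normal mixture fit%s\n  p = %.3f, gamma(shape %.3g, rate %.3g), sigma = %.3g\n",
    if (is.na(x$taxon_id)) "" else paste0(" [", x$taxon_id, "]"),
    x$p, x$alpha, x$beta, x$sigma))
  cat(sprintf("  loglik %.4f (null %.4f), LRT p = %.3g, %s in %d iterations\n",
              x$loglik_mixture, x$loglik_null, x$lrt_pvalue,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Likelihood ratio test of the mixture against the normal regression
#'
#' The statistic `2 * (loglik_mixture - loglik_null)` is referred to a
#' chi-square distribution with 3 degrees of freedom (the extra parameters
#' `p`, `alpha`, `beta`). The null sits on the boundary `p = 0`, so the
#' chi-square reference is approximate (conservative); it is used only as a
#' screen.
#'
#' @param fit a `"mixture_fit"`.
#' @param df degrees of freedom, default 3.
#' @return p-value in `[0, 1]`.
#' @export
likelihood_ratio_test <- function(fit, df = 3) {
  stat <- 2 * (fit$loglik_mixture - fit$loglik_null)
  if (stat < -1e-6)
    stop("mixture log-likelihood below null beyond tolerance: inconsistent fits")
  stat <- max(stat, 0)
  min(max(stats::pchisq(stat, df = df, lower.tail = FALSE), 0), 1)
}

#' Posterior probability of the gamma (dropout) component
#'
#' Computes, entry by entry, the posterior probability that an observation
#' came from the gamma component of a fitted mixture. Evaluated in log space
#' so extreme densities do not underflow.
#'
#' @param fit a `"mixture_fit"`.
#' @param y numeric vector of log-scale abundances.
#' @param X design matrix matching `y` (rows); `NULL` for intercept-only.
#' @return Numeric vector of posterior memberships in `[0, 1]`.
#' @export
posterior_membership <- function(fit, y, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), length(fit$gamma_coef))
  stopifnot(nrow(X) == length(y), ncol(X) == length(fit$gamma_coef))
  if (fit$p <= 0) return(rep(0, length(y)))
  if (fit$p >= 1) return(rep(1, length(y)))
  mu <- drop(X %*% fit$gamma_coef)
  la <- log(fit$p) +
    stats::dgamma(y, shape = fit$alpha, rate = fit$beta, log = TRUE)
  lb <- log1p(-fit$p) + stats::dnorm(y, mu, fit$sigma, log = TRUE)
  if (any(!is.finite(la) & !is.finite(lb)))
    stop("numerical underflow: both component densities vanish")
  1 / (1 + exp(lb - la))
}

# build an intercept + standardized-covariate design from a covariate table
build_design <- function(covariates, sample_ids) {
  n <- length(sample_ids)
  if (is.null(covariates))
    return(matrix(1, n, 1, dimnames = list(sample_ids, "(Intercept)")))
  covariates <- as.data.frame(covariates)
  if (!is.null(rownames(covariates)) &&
      all(sample_ids %in% rownames(covariates))) {
    covariates <- covariates[sample_ids, , drop = FALSE]
  } else if (nrow(covariates) != n) {
    stop("covariate table does not match the samples")
  }
  cols <- list(`(Intercept)` = rep(1, n))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      if (!is.finite(s) || s < 1e-12) {
        warning("dropping constant covariate '", nm, "'")
        next
      }
      cols[[nm]] <- (v - mean(v)) / s
    } else {
      f <- as.factor(v)
      if (nlevels(f) < 2) { warning("dropping constant covariate '", nm, "'"); next }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(f)[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- sample_ids
  out
}

#' Flag non-biological zeros
#'
#' Runs the full zero-identification stage: prevalence screen
#' ([filter_taxa_binomial()]), per-taxon gamma-normal mixture EM fit, LRT
#' screen, and posterior-membership thresholding. Only zero-count entries of
#' taxa that pass both screens and whose posterior membership in the gamma
#' component is at least `e_threshold` are flagged for imputation; all other
#' zeros are considered biological and left alone.
#'
#' @param x a [log_matrix()].
#' @param covariates optional per-sample covariate data.frame (rownames =
#'   sample ids); continuous columns are standardized, categorical columns
#'   one-hot encoded with the first level dropped.
#' @param abundance_threshold,confidence passed to [filter_taxa_binomial()].
#' @param lrt_alpha LRT significance threshold, default 0.05.
#' @param e_threshold posterior-membership threshold, default 0.5.
#' @param em_tol,em_max_iter EM controls.
#' @return An object of class `"zero_flag_report"` with elements
#'   `kept_taxa`, `e` (posterior-membership matrix, `NA` for unfitted taxa),
#'   `flags` (logical matrix), `fits` (per-taxon `mixture_fit`s) and
#'   `lrt_pvalues`. A taxon whose fit fails is skipped with a warning.
#' @export
flag_nonbiological_zeros <- function(x, covariates = NULL,
                                     abundance_threshold = 0,
                                     confidence = 0.95,
                                     lrt_alpha = 0.05, e_threshold = 0.5,
                                     em_tol = 1e-6, em_max_iter = 100) {
  stopifnot(inherits(x, "log_matrix"))
  Y <- x$values
  X <- build_design(covariates, rownames(Y))
  kept <- filter_taxa_binomial(x, abundance_threshold, confidence)
  e <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  flags <- matrix(FALSE, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  is_zero <- abs(Y - log_floor(x)) < 1e-12
  fits <- list()
  lrt <- stats::setNames(rep(NA_real_, length(kept)), kept)
  for (taxon in kept) {
    fit <- tryCatch(
      fit_gamma_normal_mixture(Y[, taxon], X, tol = em_tol,
                               max_iter = em_max_iter),
      error = function(err) {
        warning("taxon '", taxon, "' skipped: ", conditionMessage(err),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    fit$taxon_id <- taxon
    fits[[taxon]] <- fit
    lrt[taxon] <- fit$lrt_pvalue
    e[, taxon] <- posterior_membership(fit, Y[, taxon], X)
    if (fit$lrt_pvalue <= lrt_alpha) {
      flags[, taxon] <- e[, taxon] >= e_threshold & is_zero[, taxon]
    }
  }
  structure(list(kept_taxa = kept, e = e, flags = flags, fits = fits,
                 lrt_pvalues = lrt),
            class = "zero_flag_report")
}

#' @export
print.zero_flag_report <- function(x, ...) {
  cat(sprintf(
    "zero_flag_report: %d taxa kept by the prevalence screen, %d fitted\n",
    length(x$kept_taxa), length(x$fits)))
  cat(sprintf("  taxa passing the LRT screen (p <= 0.05): %d\n",
              sum(x$lrt_pvalues <= 0.05, na.rm = TRUE)))
  cat(sprintf("  entries flagged for imputation: %d\n", sum(x$flags)))
  invisible(x)
}
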