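#' Run the Bayes-factor / Spearman association across variables and runs
#'
#' Treats each accession as sampled from its own subpopulation: the
#' populations x loci frequency matrix is the transposed call matrix with
#' missing calls mean-imputed. For each environmental variable and each of
#' `n_runs` seeded runs, computes per-locus Bayes factors (under the supplied
#' covariance model, or the identity "null model" when `omega = NULL`) and
#' the Spearman correlation; medians across runs are reported per
#' (locus, variable) pair. Under the covariance model the rank correlation is
#' computed on structure-standardized residual frequencies (and the whitened
#' environment), so that rho, like the Bayes factor, measures association
#' beyond shared drift; the null model uses the raw frequencies.
#'
#' @param G a [genotype_matrix()] (accessions x loci).
#' @param env_mat standardised accession x variable matrix
#'   (see [standardize_env()]).
#' @param omega accession-level covariance matrix with rows/columns aligned
#'   to the rows of `G` (note [estimate_omega()] orders populations by sorted
#'   label), or `NULL` for the structure-uncorrected null model.
#' @param n_runs number of seeded runs (default 5).
#' @param seed_base run `r` uses seed `seed_base + r`.
#' @param ... passed to [eaa_bayes_factors()] (`n_draws`, `prior_halfwidth`, ...).
#' @return an `eaa_result`: list with `bf` (loci x variables x runs array),
#'   `rho` (loci x variables), `bf_median`, `model`, `n_runs`.
#' @export
run_association <- function(G, env_mat, omega = NULL, n_runs = 5L,
                            seed_base = 100L, ...) {
  env_mat <- as.matrix(env_mat)
  stopifnot(nrow(env_mat) == nrow(G))
  P <- nrow(G)
  freqs <- matrix(as.numeric(G), P, ncol(G),
                  dimnames = list(rownames(G), colnames(G)))
  # mean-impute missing calls at frequency level
  if (anyNA(freqs)) {
    lm_ <- colMeans(freqs, na.rm = TRUE)
    idx <- which(is.na(freqs), arr.ind = TRUE)
    freqs[idx] <- lm_[idx[, 2]]
  }
  model <- if (is.null(omega)) "null" else "covariance"
  if (is.null(omega)) omega <- null_omega(P)
  L <- ncol(G); V <- ncol(env_mat)
  bf <- array(NA_real_, dim = c(L, V, n_runs),
              dimnames = list(colnames(G), colnames(env_mat), NULL))
  rho <- matrix(NA_real_, L, V, dimnames = list(colnames(G), colnames(env_mat)))
  std <- if (model == "covariance") eaa_standardized_freqs(freqs, omega)
  for (v in seq_len(V)) {
    e <- env_mat[, v]
    for (r in seq_len(n_runs)) {
      bf[, v, r] <- eaa_bayes_factors(freqs, e, omega, seed = seed_base + r, ...)
    }
    if (model == "covariance") {
      # rank correlation on structure-standardized frequencies
      ew <- std$whiten_env(e)
      rho[, v] <- apply(std$resid, 2, spearman_env, env = ew)
    } else {
      rho[, v] <- apply(freqs, 2, spearman_env, env = e)
    }
  }
  structure(list(bf = bf, rho = rho,
                 bf_median = apply(bf, c(1, 2), stats::median),
                 model = model, n_runs = n_runs, seed_base = seed_base),
            class = "eaa_result")
}

#' Consensus hits across runs
#'
#' A (locus, variable) pair is a consensus hit when its median Bayes factor
#' lies in the top `1 - bf_quantile` of the distribution pooled across all
#' variables, and its absolute Spearman correlation lies in the pooled top
#' `1 - rho_quantile` in every run. (With the deterministic rank correlation
#' used here, the per-run rho criterion reduces to a single pooled test;
#' the per-run structure is kept for interface compatibility with samplers
#' whose correlations vary across runs.)
#'
#' @param result an `eaa_result` from [run_association()].
#' @param bf_quantile,rho_quantile pooled quantile thresholds (default 0.99).
#' @param variables optional subset of variable names entering the pooled
#'   distributions and eligible as hits.
#' @return data frame of hits: `locus`, `variable`, `bf_median`, `rho_median`.
#' @export
consensus_hits <- function(result, bf_quantile = 0.99, rho_quantile = 0.99,
                           variables = NULL) {
  bfm <- result$bf_median
  # per-run rho (loci x variables x runs) when available, else the single
  # deterministic matrix replicated
  rho_runs <- result$rho_runs %||%
    array(result$rho, dim = c(dim(result$rho), 1L),
          dimnames = c(dimnames(result$rho), list(NULL)))
  rho <- result$rho
  if (!is.null(variables)) {
    bfm <- bfm[, variables, drop = FALSE]
    rho <- rho[, variables, drop = FALSE]
    rho_runs <- rho_runs[, variables, , drop = FALSE]
  }
  hit <- top_fraction(bfm, 1 - bf_quantile)
  for (r in seq_len(dim(rho_runs)[3])) {
    rr <- matrix(rho_runs[, , r, drop = FALSE][, , 1], nrow = nrow(bfm))
    hit <- hit & top_fraction(abs(rr), 1 - rho_quantile)
  }
  idx <- which(hit, arr.ind = TRUE)
  data.frame(locus = rownames(bfm)[idx[, 1]],
             variable = colnames(bfm)[idx[, 2]],
             bf_median = bfm[idx],
             rho_median = rho[idx])
}

# logical mask of the top `frac` fraction of x (average ranks, so wide ties
# below the cutoff never flood the selection)
top_fraction <- function(x, frac) {
  n_ok <- sum(!is.na(x))
  r <- rank(-as.vector(x), ties.method = "average", na.last = "keep")
  out <- !is.na(r) & r <= ceiling(frac * n_ok)
  dim(out) <- dim(x)
  out
}

#' Empirical dummy-based threshold
#'
#' Percentile of the statistic's distribution over the dummy (spatially
#' correlated but truly null) variables; the default 99.99th percentile
#' gives a stringent empirical significance cutoff.
#'
#' @param dummy_values numeric vector of the statistic computed for all
#'   loci x dummy variables.
#' @param percentile percentile in (0, 100\] (default 99.99).
#' @return scalar threshold.
#' @export
dummy_threshold <- function(dummy_values, percentile = 99.99) {
  dummy_values <- dummy_values[is.finite(dummy_values)]
  if (length(dummy_values) < 1e4) {
    warning("fewer than 10,000 dummy values; threshold has a wide confidence interval")
  }
  stats::quantile(dummy_values, percentile / 100, names = FALSE)
}

# seeded randomized truncated SVD (range finder + one power iteration)
randomized_svd <- function(x, k, seed, oversample = 10L, power_iter = 3L) {
  set.seed(seed)
  L <- ncol(x)
  test <- matrix(stats::rnorm(L * (k + oversample)), L)
  y <- x %*% test
  q <- qr.Q(qr(y))
  for (i in seq_len(power_iter)) {
    q <- qr.Q(qr(x %*% crossprod(x, q)))
  }
  b <- crossprod(q, x)
  s <- svd(b, nu = k, nv = 0)
  list(u = q %*% s$u, d = s$d[seq_len(k)])
}

#' Latent-factor association z-scores
#'
#' Per run: estimates `k` latent factors of the centred genotype matrix by a
#' seeded randomized truncated SVD (runs differ through the random range
#' finder, mimicking independently started solvers), then regresses each
#' locus on the environment adjusted for the factors and returns the
#' environmental-effect z-score. `k = 0` reduces to simple regression.
#'
#' @param G complete (imputed) [genotype_matrix()].
#' @param env standardised environment per accession.
#' @param k number of latent factors (default 6); must be < accessions.
#' @param n_runs number of runs (default 5).
#' @param seed_base run `r` uses seed `seed_base + r`.
#' @return loci x runs matrix of z-scores.
#' @export
latent_factor_assoc <- function(G, env, k = 6L, n_runs = 5L, seed_base = 200L) {
  if (anyNA(G)) stop("G must be imputed (no missing calls)")
  n <- nrow(G)
  if (k >= n) stop("k must be smaller than the number of accessions")
  x <- scale(matrix(as.numeric(G), n, ncol(G)), scale = FALSE)
  z <- matrix(NA_real_, ncol(G), n_runs,
              dimnames = list(colnames(G), NULL))
  for (r in seq_len(n_runs)) {
    if (k > 0) {
      fac <- randomized_svd(x, k, seed = seed_base + r)$u
      m <- cbind(1, env, fac)
    } else {
      m <- cbind(1, env)
    }
    z[, r] <- regression_z(m, x, coef_index = 2L)
  }
  z
}

# z (t) statistic of one coefficient for every response column of y
regression_z <- function(m, y, coef_index) {
  qr_m <- qr(m)
  coef <- qr.coef(qr_m, y)
  res <- y - m %*% coef
  df <- nrow(m) - ncol(m)
  sigma2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qr_m))
  se <- sqrt(sigma2 * xtxi[coef_index, coef_index])
  out <- coef[coef_index, ] / se
  out[se == 0] <- NA_real_
  out
}

#' Fisher-Stouffer combination of z-scores across runs
#'
#' `z_comb = sum(z_i) / sqrt(m)` with a two-sided normal p-value; combining
#' `m` identical runs leaves the z-score unchanged.
#'
#' @param z matrix (loci x runs) or vector of z-scores.
#' @return data frame with `z` and `p` per locus.
#' @export
combine_fisher_stouffer <- function(z) {
  z <- as.matrix(z)
  m <- ncol(z)
  zc <- rowSums(z) / sqrt(m)
  data.frame(z = zc, p = 2 * stats::pnorm(-abs(zc)), row.names = rownames(z))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted q-values and a significance mask at the chosen FDR level.
#'
#' @param p vector of p-values.
#' @param Q FDR level (default 0.01).
#' @return data frame with `p`, `q`, `significant`.
#' @export
bh_fdr <- function(p, Q = 0.01) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = !is.na(q) & q <= Q)
}

#' Pearson correlation between Bayes factors and XtX
#'
#' Diagnostic for whether a variable's associations coincide with
#' population-differentiation outliers; reported per variable alongside the
#' dummy-variable baseline.
#'
#' @param bf per-locus Bayes factors for one variable.
#' @param xtx_values per-locus XtX (shared locus set and order).
#' @return Pearson r, or `NA` when either side has zero variance.
#' @export
bf_xtx_correlation <- function(bf, xtx_values) {
  ok <- is.finite(bf) & is.finite(xtx_values)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(bf[ok]) == 0 || stats::sd(xtx_values[ok]) == 0) return(NA_real_)
  stats::cor(bf[ok], xtx_values[ok])
}
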