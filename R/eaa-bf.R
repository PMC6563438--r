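#' Standardize an environment matrix
#'
#' Column-wise centring and scaling to unit standard deviation. Constant
#' columns are an error (they carry no gradient and break the scaling).
#'
#' @param x site/accession x variable matrix or data frame.
#' @return numeric matrix with attribute `standardized = TRUE`.
#' @export
standardize_env <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

#' Bayes factors for allele-frequency/environment association
#'
#' Hierarchical model in the allele-frequency covariance tradition: observed
#' population frequencies are modelled as
#' `p_hat ~ N(eps * 1 + beta * e, eps(1-eps) (Omega + diag(1/n)))`,
#' where `Omega` captures shared drift, `diag(1/n)` binomial sampling noise,
#' `eps` the latent ancestral frequency and `e` the standardised environment.
#' The Bayes factor compares the environmental-effect model (beta integrated
#' over a symmetric uniform prior, evaluated on a fixed grid) against the
#' neutral model (beta = 0). Uncertainty in `eps` is integrated by seeded
#' Monte Carlo draws from its profile posterior, so results are deterministic
#' per seed and vary across seeds like independent MCMC runs.
#'
#' Monomorphic loci get BF = 1 (flagged via the `monomorphic` attribute).
#'
#' @param freqs populations x loci matrix of observed allele frequencies
#'   (accessions-as-populations: the transposed call matrix, missing calls
#'   mean-imputed).
#' @param env standardised environment value per population.
#' @param omega P x P covariance matrix (identity for the null model).
#' @param sizes haploid sample size per population (default 1).
#' @param prior_halfwidth half-width of the uniform beta prior (default 0.3).
#' @param grid_points odd number of beta grid points (default 61).
#' @param n_draws Monte Carlo draws for the ancestral frequency (default 50).
#' @param seed integer seed (one "run").
#' @param ridge ridge for the covariance factorisation.
#' @return numeric vector of Bayes factors per locus, with attribute
#'   `monomorphic` (logical per locus).
#' @export
eaa_bayes_factors <- function(freqs, env, omega, sizes = 1,
                              prior_halfwidth = 0.3, grid_points = 61L,
                              n_draws = 50L, seed = 1L, ridge = 1e-6) {
  P <- nrow(freqs)
  L <- ncol(freqs)
  stopifnot(length(env) == P, nrow(omega) == P, grid_points >= 3)
  sizes <- rep_len(sizes, P)
  sigma <- omega + diag(1 / sizes + ridge, P)
  U <- chol(sigma)
  wh <- function(m) backsolve(U, m, transpose = TRUE)   # L^{-1} m
  Yt <- wh(freqs)                    # P x L whitened frequencies
  u1 <- wh(matrix(1, P, 1))[, 1]
  ee <- wh(matrix(env, P, 1))[, 1]
  A0 <- colSums(Yt^2)
  B0 <- as.vector(crossprod(Yt, u1))
  C0 <- sum(u1^2)
  Be <- as.vector(crossprod(Yt, ee))
  Ce <- sum(ee^2)
  Cue <- sum(u1 * ee)
  mono <- apply(freqs, 2, function(x) all(x <= 0) || all(x >= 1) ||
                  stats::sd(x) == 0)
  eps_hat <- pmin(pmax(B0 / C0, 1e-3), 1 - 1e-3)
  eps_se <- sqrt(eps_hat * (1 - eps_hat) / C0)
  beta_grid <- seq(-prior_halfwidth, prior_halfwidth, length.out = grid_points)
  set.seed(seed)
  draws <- matrix(stats::rnorm(L * n_draws), L, n_draws)
  log_alt <- matrix(-Inf, L, n_draws)
  log_null <- matrix(-Inf, L, n_draws)
  for (s in seq_len(n_draws)) {
    eps <- pmin(pmax(eps_hat + eps_se * draws[, s], 1e-3), 1 - 1e-3)
    s2 <- eps * (1 - eps)
    rss0 <- A0 - 2 * eps * B0 + eps^2 * C0
    bcoef <- Be - eps * Cue            # per locus
    # log-likelihood over the beta grid: L x G
    llg <- outer(-(P / 2) * log(2 * pi * s2), rep(1, grid_points)) +
      (-(outer(rss0, rep(1, grid_points)) -
           2 * outer(bcoef, beta_grid) +
           outer(rep(1, L), beta_grid^2) * Ce) / (2 * s2))
    log_alt[, s] <- log_mean_exp_rows(llg)
    log_null[, s] <- -(P / 2) * log(2 * pi * s2) - rss0 / (2 * s2)
  }
  bf <- exp(log_mean_exp_rows(log_alt) - log_mean_exp_rows(log_null))
  bf[mono] <- 1
  names(bf) <- colnames(freqs)
  attr(bf, "monomorphic") <- mono
  bf
}

# row-wise log(mean(exp(x))) with overflow protection
log_mean_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowMeans(exp(m - mx)))
}

#' Structure-standardized residual frequencies
#'
#' Whitens the populations x loci frequency matrix by the Cholesky factor of
#' `Omega + diag(1/n)` and removes the fitted ancestral-frequency component,
#' yielding the "standardized allele frequencies" on which the covariance
#' model's rank correlations are computed. Returns the residual matrix and a
#' function that applies the same whitening to an environmental vector.
#'
#' @inheritParams eaa_bayes_factors
#' @return list with `resid` (P x L) and `whiten_env` (function).
#' @export
eaa_standardized_freqs <- function(freqs, omega, sizes = 1, ridge = 1e-6) {
  P <- nrow(freqs)
  sizes <- rep_len(sizes, P)
  U <- chol(omega + diag(1 / sizes + ridge, P))
  wh <- function(m) backsolve(U, m, transpose = TRUE)
  Yt <- wh(freqs)
  u1 <- wh(matrix(1, P, 1))[, 1]
  eps_hat <- pmin(pmax(as.vector(crossprod(Yt, u1)) / sum(u1^2), 1e-3),
                  1 - 1e-3)
  resid <- Yt - outer(u1, eps_hat)
  colnames(resid) <- colnames(freqs)
  list(resid = resid, whiten_env = function(e) wh(matrix(e, P, 1))[, 1])
}

#' Spearman correlation between locus frequencies and environment
#'
#' Rank correlation with average-rank ties; `NA` when fewer than three
#' complete pairs or either side is entirely tied.
#'
#' @param x per-population locus frequencies (or calls).
#' @param env environment values.
#' @return rho in \[-1, 1\] or `NA`.
#' @export
spearman_env <- function(x, env) {
  ok <- !is.na(x) & !is.na(env)
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; env <- env[ok]
  if (stats::sd(x) == 0 || stats::sd(env) == 0) return(NA_real_)
  stats::cor(x, env, method = "spearman")
}
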