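#' Expected heterozygosity (gene diversity)
#'
#' `H = 2 p (1 - p)` for a biallelic locus with allele frequency `p`.
#'
#' @param p allele frequency vector in \[0, 1\].
#' @return numeric vector of H values.
#' @export
expected_het <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

# per-group allele frequencies and sample sizes for one genotype matrix
pop_freqs <- function(G, groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  p <- vapply(lv, function(g) colMeans(G[groups == g, , drop = FALSE],
                                       na.rm = TRUE), numeric(ncol(G)))
  n <- vapply(lv, function(g) colSums(!is.na(G[groups == g, , drop = FALSE])),
              numeric(ncol(G)))
  list(p = t(p), n = t(n), levels = lv) # populations x loci
}

# haploid analysis-of-variance Fst (Weir-Cockerham type), ratio of sums
fst_anova <- function(p, n) {
  r <- nrow(p)
  L <- ncol(p)
  ok <- colSums(n >= 1) == r
  per_locus <- rep(NA_real_, L)
  pp <- p[, ok, drop = FALSE]; nn <- n[, ok, drop = FALSE]
  ntot <- colSums(nn)
  pbar <- colSums(nn * pp) / ntot
  nc <- (ntot - colSums(nn^2) / ntot) / (r - 1)
  msp <- colSums(nn * sweep(pp, 2, pbar)^2) / (r - 1)
  msg_den <- colSums(nn - 1)
  msg <- ifelse(msg_den > 0, colSums(nn * pp * (1 - pp)) / msg_den, 0)
  a <- (msp - msg) / nc
  b <- msg
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) return(list(fst = NA_real_, per_locus = per_locus))
  per_locus[ok] <- ifelse(a + b > 0, a / (a + b), NA_real_)
  list(fst = sum(a[poly]) / sum((a + b)[poly]), per_locus = per_locus)
}

#' Pairwise Fst between germplasm groups
#'
#' Multi-locus Fst for every pair of groups using a haploid
#' analysis-of-variance estimator of the Weir-Cockerham family (ratio of
#' sums over polymorphic loci). The diagonal reports the within-group mean
#' expected heterozygosity over loci polymorphic in the full panel.
#'
#' @param G a [genotype_matrix()].
#' @param groups group label per accession.
#' @param diag_monomorphic include within-group-monomorphic loci in the
#'   diagonal H means (default `TRUE`: all panel-polymorphic loci).
#' @return list with `matrix` (K x K; upper triangle Fst, diagonal H),
#'   `per_locus` (loci x pairs Fst) and `levels`.
#' @export
fst_pairwise <- function(G, groups, diag_monomorphic = TRUE) {
  pf <- pop_freqs(G, groups)
  lv <- pf$levels
  K <- length(lv)
  if (K < 2) stop("need at least two groups")
  out <- matrix(NA_real_, K, K, dimnames = list(lv, lv))
  overall <- colMeans(G, na.rm = TRUE)
  panel_poly <- overall > 0 & overall < 1
  per_locus <- list()
  for (i in seq_len(K)) {
    h <- expected_het(pf$p[i, ])
    keep <- if (diag_monomorphic) panel_poly else (pf$p[i, ] > 0 & pf$p[i, ] < 1)
    out[i, i] <- mean(h[keep], na.rm = TRUE)
    if (i < K) for (j in (i + 1):K) {
      f <- fst_anova(pf$p[c(i, j), , drop = FALSE], pf$n[c(i, j), , drop = FALSE])
      out[i, j] <- out[j, i] <- f$fst
      per_locus[[paste(lv[i], lv[j], sep = "_")]] <- f$per_locus
    }
  }
  list(matrix = out, per_locus = as.data.frame(per_locus), levels = lv)
}

#' Identity (null) covariance matrix
#'
#' Models the absence of covariance among population allele frequencies, for
#' structure-uncorrected ("null model") association runs.
#'
#' @param P number of populations.
#' @return P x P identity matrix.
#' @export
null_omega <- function(P) {
  stopifnot(P >= 1)
  diag(1, P)
}

#' Moment estimate of the population covariance matrix Omega
#'
#' Covariance among populations of standardised allele frequencies: per locus
#' the population frequency vector is centred at its mean and scaled by
#' `sqrt(pbar (1 - pbar))`; Omega is the average outer product over loci
#' (polymorphic loci only), element-wise averaged over `n_runs` bootstrap
#' replicates of the marker set (run 1 uses the full set), and projected to
#' the positive semi-definite cone.
#'
#' Intended for a nonredundant, low-LD marker shortlist; fewer than 30
#' markers triggers a warning.
#'
#' @param G a [genotype_matrix()], ideally restricted to a shortlist.
#' @param groups population label per accession; use accession ids for
#'   accession-level covariance.
#' @param n_runs number of averaging runs (default 1: plain moment estimate).
#' @param seed seed for the bootstrap replicates (runs > 1).
#' @return list with `omega` (P x P), `n_loci`, `n_runs`, `seed`.
#' @export
estimate_omega <- function(G, groups, n_runs = 1L, seed = 1L) {
  pf <- pop_freqs(G, groups)
  p <- pf$p
  P <- nrow(p)
  if (P < 2) stop("need at least two populations")
  pbar <- colMeans(p)
  poly <- pbar > 1e-12 & pbar < 1 - 1e-12 & !apply(p, 2, anyNA)
  if (sum(poly) < 30) warning("fewer than 30 usable markers; Omega unstable")
  z <- sweep(p[, poly, drop = FALSE], 2, pbar[poly]) /
    rep(sqrt(pbar[poly] * (1 - pbar[poly])), each = P)
  L <- ncol(z)
  one_omega <- function(idx) tcrossprod(z[, idx, drop = FALSE]) / length(idx)
  if (n_runs <= 1) {
    omega <- one_omega(seq_len(L))
  } else {
    set.seed(seed)
    mats <- vector("list", n_runs)
    mats[[1]] <- one_omega(seq_len(L))
    for (r in 2:n_runs) mats[[r]] <- one_omega(sample.int(L, L, replace = TRUE))
    omega <- Reduce(`+`, mats) / n_runs
  }
  # PSD projection (clip negative eigenvalues)
  eig <- eigen(omega, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  omega <- eig$vectors %*% (lam * t(eig$vectors))
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- list(pf$levels, pf$levels)
  list(omega = omega, n_loci = L, n_runs = n_runs, seed = seed)
}

#' Write/read Omega as a whitespace-separated square matrix
#'
#' @param omega square numeric matrix.
#' @param path file path.
#' @export
write_omega <- function(omega, path) {
  utils::write.table(format(omega, digits = 10, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_omega
#' @export
read_omega <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' XtX differentiation statistic
#'
#' Covariance-aware analogue of Fst: for a locus with per-population
#' frequencies `theta`, `XtX = c * (theta - eps)' [eps(1-eps) Omega]^{-1}
#' (theta - eps)` where `eps` is the Omega-weighted (GLS) ancestral-frequency
#' estimate and `c = P/(P-1)` accounts for the degree of freedom absorbed by
#' estimating `eps`, so that neutral loci have expectation P. Omega is
#' ridge-regularised (`1e-6 I`) before inversion.
#'
#' @param theta per-population frequency vector, or populations x loci matrix.
#' @param omega P x P covariance matrix.
#' @param ridge ridge added to Omega's diagonal (default 1e-6).
#' @return numeric XtX value(s), `NA` where the ancestral estimate is fixed.
#' @export
xtx <- function(theta, omega, ridge = 1e-6) {
  th <- if (is.matrix(theta)) theta else matrix(theta, ncol = 1)
  P <- nrow(th)
  stopifnot(nrow(omega) == P, ncol(omega) == P)
  oi <- solve(omega + diag(ridge, P))
  w <- colSums(oi)            # t(1) %*% oi
  eps <- as.vector(w %*% th) / sum(w)
  z <- sweep(th, 2, eps)
  quad <- colSums(z * (oi %*% z))
  s2 <- eps * (1 - eps)
  out <- ifelse(s2 > 0, (P / (P - 1)) * quad / s2, NA_real_)
  as.numeric(out)
}

#' Simulated-neutral (pseudo-observed data) XtX threshold
#'
#' Simulates `n_sim` neutral loci from the drift model implied by Omega and
#' the fitted ancestral-frequency spectrum, pushes them through the identical
#' estimation pipeline as the observed data, and returns the requested
#' percentile of their XtX values.
#'
#' Details: ancestral frequencies are resampled from the observed estimates
#' (histogram sampler); population deviations are multivariate normal with
#' covariance `eps(1-eps)` times Omega completed by an exchangeable
#' shared-drift component (the moment estimator is mean-centred per locus and
#' so cannot see the component shared by all populations, whose magnitude is
#' set to the mean of the contrast-space eigenvalues); frequencies are
#' clipped to \[0, 1\]; and -- crucially for calibration -- the POD set's own
#' moment covariance is re-estimated and used for the POD XtX, exactly as the
#' observed XtX uses the covariance estimated from the observed data.
#'
#' @param omega P x P covariance matrix (moment estimate from the data).
#' @param eps_obs observed ancestral-frequency estimates (one per real locus).
#' @param n_sim number of simulated loci (>= 1000).
#' @param percentile percentile of the neutral XtX distribution (default 99).
#' @param seed integer seed.
#' @return scalar threshold with attribute `pod_xtx` (the simulated values).
#' @export
pod_threshold <- function(omega, eps_obs, n_sim = 10000L, percentile = 99,
                          seed = 1L) {
  stopifnot(n_sim >= 1000)
  P <- nrow(omega)
  eps_obs <- eps_obs[is.finite(eps_obs) & eps_obs > 0 & eps_obs < 1]
  set.seed(seed)
  eps <- sample(eps_obs, n_sim, replace = TRUE)
  lam <- sum(diag(omega)) / (P - 1)
  om_full <- omega + lam * matrix(1 / P, P, P)
  eig <- eigen(om_full, symmetric = TRUE)
  rt <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), P)
  zs <- rt %*% matrix(stats::rnorm(P * n_sim), P, n_sim)
  th <- sweep(zs, 2, sqrt(eps * (1 - eps)), `*`)
  th <- sweep(th, 2, eps, `+`)
  th <- pmin(pmax(th, 0), 1)
  # re-estimate the covariance from the PODs themselves (same pipeline)
  pbar <- colMeans(th)
  poly <- pbar > 1e-9 & pbar < 1 - 1e-9
  zz <- sweep(th[, poly, drop = FALSE], 2, pbar[poly]) /
    rep(sqrt(pbar[poly] * (1 - pbar[poly])), each = P)
  om_pod <- tcrossprod(zz) / ncol(zz)
  x <- xtx(th, om_pod)
  out <- stats::quantile(x, percentile / 100, na.rm = TRUE, names = FALSE)
  attr(out, "pod_xtx") <- x
  out
}

#' Sliding-window means along the genetic map
#'
#' Centred windows of total width `width_cM` on the cumulative genetic
#' position (`[c - w/2, c + w/2)` membership), one window per marker, with
#' the mean of the per-locus values inside; windows never span chromosomes.
#' Reference percentiles of the windowed series and of the single-locus
#' values are returned for plotting threshold lines.
#'
#' @param values per-locus statistic, aligned with `map` rows.
#' @param map marker map with `chrom` and `ccM` columns.
#' @param width_cM total window width (default 4).
#' @param window_percentiles percentiles of the windowed series (default 95, 5).
#' @param snp_percentiles percentiles of the single-locus values (default 99, 1).
#' @return data frame `id`, `chrom`, `ccM`, `value`, `window_mean`, `n_in_window`,
#'   with percentile reference lines as attributes `window_ref` and `snp_ref`.
#' @export
sliding_windows <- function(values, map, width_cM = 4,
                            window_percentiles = c(95, 5),
                            snp_percentiles = c(99, 1)) {
  stopifnot(length(values) == nrow(map))
  ord <- order(map$ccM)
  map <- map[ord, ]; values <- values[ord]
  half <- width_cM / 2
  wm <- numeric(nrow(map)); nw <- integer(nrow(map))
  for (i in seq_len(nrow(map))) {
    inw <- map$chrom == map$chrom[i] &
      map$ccM >= map$ccM[i] - half & map$ccM < map$ccM[i] + half
    v <- values[inw]
    v <- v[!is.na(v)]
    nw[i] <- length(v)
    wm[i] <- if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- data.frame(id = map$id, chrom = map$chrom, ccM = map$ccM,
                    value = values, window_mean = wm, n_in_window = nw)
  attr(out, "window_ref") <- stats::quantile(wm, window_percentiles / 100,
                                             na.rm = TRUE)
  attr(out, "snp_ref") <- stats::quantile(values, snp_percentiles / 100,
                                          na.rm = TRUE)
  out
}
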