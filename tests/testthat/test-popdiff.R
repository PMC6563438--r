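test_that("expected heterozygosity has its closed form", {
  expect_equal(expected_het(0.5), 0.5)
  expect_equal(expected_het(0), 0)
  expect_equal(expected_het(0.1), 0.18)
  expect_error(expected_het(1.2))
})

test_that("pairwise Fst spans no-differentiation to fixation", {
  # identical allele frequencies in both groups: Fst near 0
  set.seed(1)
  p <- runif(300, 0.2, 0.8)
  calls <- matrix(rbinom(40 * 300, 1, rep(p, each = 40)), 40, 300,
                  dimnames = list(sprintf("a%02d", 1:40),
                                  sprintf("l%03d", 1:300)))
  G <- genotype_matrix(calls)
  f <- fst_pairwise(G, rep(c("x", "y"), each = 20))
  expect_lt(abs(f$matrix["x", "y"]), 0.05)
  # alternate fixation at every locus: Fst = 1
  fixed <- genotype_matrix(matrix(rep(c(0L, 1L), each = 10), 20, 50,
                                  dimnames = list(sprintf("a%02d", 1:20),
                                                  sprintf("l%03d", 1:50))))
  f1 <- fst_pairwise(fixed, rep(c("x", "y"), each = 10))
  expect_equal(f1$matrix["x", "y"], 1)
  # diagonal carries within-group gene diversity
  expect_equal(unname(f1$matrix["x", "x"]), 0)
  expect_error(fst_pairwise(G, rep("x", 40)), "two groups")
})

test_that("the Fst estimator recovers Balding-Nichols F across its range", {
  for (f_true in c(0.05, 0.2, 0.4)) {
    sim <- gen_structured_genotypes(80, 2000, c(40, 40), f_true,
                                    seed = round(100 * f_true))
    est <- fst_pairwise(sim$G, sim$groups)$matrix[1, 2]
    expect_lt(abs(est - f_true), 0.05)
  }
})

test_that("the null covariance model is the identity", {
  expect_identical(null_omega(3), diag(1, 3))
  path <- withr::local_tempfile()
  write_omega(null_omega(4), path)
  expect_equal(read_omega(path), diag(1, 4), ignore_attr = TRUE)
})

test_that("the moment estimator of Omega is PSD, seeded and exchangeable", {
  sim <- small_bn_sim()
  om1 <- estimate_omega(sim$G, sim$groups, n_runs = 3, seed = 5)
  om2 <- estimate_omega(sim$G, sim$groups, n_runs = 3, seed = 5)
  expect_identical(om1, om2)
  ev <- eigen(om1$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  # panmictic population split arbitrarily: off-diagonal ~ diagonal pattern
  # symmetric between the two halves (exchangeability)
  pan <- gen_structured_genotypes(80, 3000, 80L, 1e-4, seed = 6)
  omp <- estimate_omega(pan$G, rep(c("h1", "h2"), each = 40))$omega
  expect_lt(abs(omp[1, 1] - omp[2, 2]), 0.02)
  # Balding-Nichols groups: within-group variance dominates between
  omb <- estimate_omega(sim$G, sim$groups)$omega
  expect_gt(min(diag(omb)), max(omb[1, 2], 0))
  expect_warning(estimate_omega(sim$G[, 1:10], sim$groups), "30")
})

test_that("XtX behaves as a covariance-aware differentiation statistic", {
  om <- diag(c(0.3, 0.25, 0.2, 0.35))
  # no deviation from the ancestral frequency: XtX = 0
  expect_equal(xtx(rep(0.4, 4), om), 0)
  # fixed ancestral estimate: undefined
  expect_true(is.na(xtx(rep(1, 4), om)))
  # permutation invariance: relabeling populations leaves the scalar intact
  th <- c(0.1, 0.5, 0.7, 0.3)
  perm <- c(3, 1, 4, 2)
  expect_equal(xtx(th, om), xtx(th[perm], om[perm, perm]))
})

test_that("neutral XtX centres at the number of populations", {
  sim <- gen_structured_genotypes(120, 4000, rep(30L, 4), 0.25, seed = 31)
  om <- estimate_omega(sim$G, sim$groups)
  pf <- agroeaa:::pop_freqs(sim$G, sim$groups)
  x <- xtx(pf$p, om$omega)
  expect_lt(abs(mean(x, na.rm = TRUE) - 4), 0.2)
})

test_that("the POD threshold is monotone in percentile and reproducible", {
  sim <- small_bn_sim()
  om <- estimate_omega(sim$G, sim$groups)$omega
  eps <- colMeans(agroeaa:::pop_freqs(sim$G, sim$groups)$p, na.rm = TRUE)
  t95 <- pod_threshold(om, eps, n_sim = 2000, percentile = 95, seed = 1)
  t99 <- pod_threshold(om, eps, n_sim = 2000, percentile = 99, seed = 1)
  t999 <- pod_threshold(om, eps, n_sim = 2000, percentile = 99.9, seed = 1)
  expect_true(t95 < t99 && t99 < t999)
  expect_equal(as.numeric(t99),
               as.numeric(pod_threshold(om, eps, n_sim = 2000,
                                        percentile = 99, seed = 1)))
})

test_that("sliding windows average loci within 4 cM, never across chromosomes", {
  map <- marker_map(paste0("l", 1:5), c("1H", "1H", "1H", "1H", "2H"),
                    c(0, 1, 2.5, 3, 0), (1:5) * 1e6)
  vals <- c(1, 2, 3, 4, 10)
  sw <- sliding_windows(vals, map, width_cM = 4)
  # brute-force check of every window
  for (i in seq_len(nrow(sw))) {
    inw <- sw$chrom == sw$chrom[i] & sw$ccM >= sw$ccM[i] - 2 &
      sw$ccM < sw$ccM[i] + 2
    expect_equal(sw$window_mean[i], mean(sw$value[inw]))
  }
  # the isolated marker's window is its own value
  expect_equal(sw$window_mean[sw$id == "l5"], 10)
  # constant input gives constant windows
  swc <- sliding_windows(rep(7, 5), map)
  expect_true(all(swc$window_mean == 7))
  expect_length(attr(sw, "window_ref"), 2)
})
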