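test_that("environment standardization is exact and guarded", {
  out <- standardize_env(cbind(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(out[, "a"], c(-1, 0, 1), tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(sd(out[, "a"]), 1)
  # already standardized input is unchanged
  expect_equal(standardize_env(out)[, ], out[, ], tolerance = 1e-8)
  # identical columns give identical outputs
  two <- standardize_env(cbind(x = c(5, 9, 1), y = c(5, 9, 1)))
  expect_identical(two[, "x"], two[, "y"])
  expect_error(standardize_env(cbind(a = 1:3, bad = rep(2, 3))), "bad")
})

test_that("Spearman correlation handles monotone, tied and short inputs", {
  expect_equal(spearman_env(1:5, (1:5)^2), 1)
  expect_equal(spearman_env(1:5, -(1:5)), -1)
  expect_equal(spearman_env(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_env(rep(1, 5), 1:5)))
  expect_true(is.na(spearman_env(1:2, 2:1)))
})

test_that("Bayes factors are calibrated at trivial and degenerate inputs", {
  sim <- small_bn_sim()
  G <- impute_knn(sim$G)
  freqs <- matrix(as.numeric(G), nrow(G), dimnames = dimnames(G))
  om <- null_omega(nrow(G))
  # uninformative environment (all zero): beta is unidentifiable, BF = 1
  bf0 <- eaa_bayes_factors(freqs[, 1:50], rep(0, nrow(G)), om, seed = 1)
  expect_equal(as.numeric(bf0), rep(1, 50), tolerance = 1e-6,
               ignore_attr = TRUE)
  # monomorphic locus flagged with BF = 1
  freqs_m <- cbind(freqs[, 1:5], mono = rep(1, nrow(G)))
  env <- as.vector(scale(rnorm(nrow(G))))
  bfm <- eaa_bayes_factors(freqs_m, env, om, seed = 1)
  expect_equal(unname(bfm["mono"]), 1)
  expect_true(attr(bfm, "monomorphic")["mono"])
  # deterministic per seed, varying across seeds
  b1 <- eaa_bayes_factors(freqs[, 1:30], env, om, seed = 3)
  b2 <- eaa_bayes_factors(freqs[, 1:30], env, om, seed = 3)
  b3 <- eaa_bayes_factors(freqs[, 1:30], env, om, seed = 4)
  expect_identical(b1, b2)
  expect_false(identical(b1, b3))
  expect_lt(max(abs(log(b1 / b3))), 0.5)   # run-to-run MC noise is modest
})

test_that("planted clines push Bayes factors up monotonically in effect size", {
  med_bf <- vapply(c(0, 1, 2), function(beta) {
    fx <- end_to_end_fixture(seed = 31, n_acc = 80L, n_loci = 500L,
                             n_causal = 10L, beta = beta,
                             with_weather = FALSE)
    G <- impute_knn(fx$sim$G)
    freqs <- matrix(as.numeric(G), nrow(G), dimnames = dimnames(G))
    om <- estimate_omega(G, rownames(G))$omega
    bf <- eaa_bayes_factors(freqs, fx$env, om, seed = 1)
    median(bf[fx$sim$truth$causal_locus_ids])
  }, numeric(1))
  expect_true(all(diff(med_bf) > 0))
})

test_that("run_association aggregates runs and the consensus rule is strict", {
  fx <- fixture_fast()
  G <- impute_knn(maf_filter(filter_missing(fx$sim$G)))
  env <- cbind(grad = fx$env)
  res <- run_association(G, env, omega = NULL, n_runs = 3, seed_base = 7)
  expect_identical(dim(res$bf), c(ncol(G), 1L, 3L))
  expect_identical(res$model, "null")
  expect_true(all(res$bf > 0))
  expect_true(all(abs(res$rho) <= 1, na.rm = TRUE))
  # constructed consensus: one pair dominates both statistics
  L <- 100
  bfm <- matrix(1, L, 2, dimnames = list(paste0("l", 1:L), c("v1", "v2")))
  rho <- matrix(0, L, 2, dimnames = dimnames(bfm))
  bfm["l7", "v1"] <- 50
  rho["l7", "v1"] <- 0.9
  fake <- list(bf_median = bfm, rho = rho, rho_runs = NULL)
  hits <- consensus_hits(fake)
  expect_identical(hits$locus, "l7")
  expect_identical(hits$variable, "v1")
  # a pair in the top tier in 4 of 5 runs is not a hit
  rho_runs <- array(rho, dim = c(L, 2, 5), dimnames = c(dimnames(rho), NULL))
  rho_runs["l7", "v1", 5] <- 0   # drops out of the top 1% in run 5
  fake5 <- list(bf_median = bfm, rho = rho, rho_runs = rho_runs)
  expect_identical(nrow(consensus_hits(fake5)), 0L)
  # empty intersection is an empty frame, not an error
  fake_none <- list(bf_median = bfm * 0 + 1, rho = rho * 0)
  expect_identical(nrow(consensus_hits(fake_none)), 0L)
})

test_that("the dummy threshold is a guarded empirical percentile", {
  expect_warning(t1 <- dummy_threshold(rep(1, 100)), "10,000")
  expect_equal(as.numeric(t1), 1)
  set.seed(1)
  v <- rexp(2e4)
  expect_gte(suppressWarnings(dummy_threshold(v, 99.99)),
             suppressWarnings(dummy_threshold(v, 99)))
})

test_that("latent-factor association reduces to simple regression at K = 0", {
  sim <- small_bn_sim()
  G <- impute_knn(sim$G)
  set.seed(5)
  env <- as.vector(scale(rnorm(nrow(G))))
  z0 <- latent_factor_assoc(G, env, k = 0, n_runs = 1, seed_base = 1)
  # oracle: per-locus lm t statistics (monomorphic loci are NA in ours and
  # numerically meaningless in lm, so compare polymorphic loci only)
  poly <- apply(G, 2, sd) > 0
  z_lm <- apply(G[, poly], 2, function(y) {
    summary(lm(y ~ env))$coefficients["env", "t value"]
  })
  expect_equal(unname(z0[poly, 1]), unname(z_lm), tolerance = 1e-8)
  expect_true(all(is.na(z0[!poly, 1])))
  expect_error(latent_factor_assoc(G, env, k = nrow(G)), "smaller")
  expect_error(latent_factor_assoc(sim$G, env, k = 2), "imputed")
})

test_that("structure absorbs a confounded cline: |z| shrinks from K=0 to K=true", {
  fx <- fixture_fast()
  G <- impute_knn(maf_filter(filter_missing(fx$sim$G)))
  causal <- intersect(fx$sim$truth$causal_locus_ids, colnames(G))
  z0 <- latent_factor_assoc(G, fx$env, k = 0, n_runs = 1, seed_base = 3)
  zk <- latent_factor_assoc(G, fx$env, k = 4, n_runs = 1, seed_base = 3)
  expect_gt(median(abs(z0[causal, 1])), median(abs(zk[causal, 1])))
})

test_that("Fisher-Stouffer combination is scale-correct and sign-preserving", {
  # z_comb = sum(z) / sqrt(m): identical runs scale by sqrt(m)
  z <- c(-1.3, 0.4, 2.2)
  expect_equal(combine_fisher_stouffer(cbind(z, z, z))$z, sqrt(3) * z)
  expect_equal(combine_fisher_stouffer(cbind(2, -2))$z, 0)
  expect_equal(combine_fisher_stouffer(cbind(1, 2, 3))$z, 6 / sqrt(3),
               tolerance = 1e-4)
  expect_equal(combine_fisher_stouffer(matrix(0, 2, 3))$p, c(1, 1))
  # a single run passes through unchanged
  expect_equal(combine_fisher_stouffer(matrix(z, 3, 1))$z, z)
})

test_that("BH FDR reproduces the step-up rule", {
  out <- bh_fdr(c(0.001, 0.5, 0.9), Q = 0.01)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$q, p.adjust(c(0.001, 0.5, 0.9), "BH"))
  none <- bh_fdr(rep(1, 5), Q = 0.01)
  expect_false(any(none$significant))
  # mask monotone in Q
  p <- c(0.001, 0.004, 0.03, 0.2)
  m1 <- bh_fdr(p, Q = 0.01)$significant
  m2 <- bh_fdr(p, Q = 0.05)$significant
  expect_true(all(m2[m1]))
})

test_that("BF-XtX correlation matches its trivial anchors", {
  x <- rexp(100)
  expect_equal(bf_xtx_correlation(3 * x, x), 1)
  expect_true(is.na(bf_xtx_correlation(rep(1, 100), x)))
  set.seed(2)
  expect_lt(abs(bf_xtx_correlation(rexp(5000), rchisq(5000, 4))), 0.05)
})
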