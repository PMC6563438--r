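# brute-force R2 oracle: per-column OLS fits, trace of fitted variance
oracle_r2 <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xc <- scale(as.matrix(X), scale = FALSE)
  fitted <- vapply(seq_len(ncol(Yc)), function(j) {
    stats::lm.fit(cbind(1, Xc), Yc[, j])$fitted.values
  }, numeric(nrow(Yc)))
  sum(fitted^2) / sum(Yc^2)
}

test_that("RDA R2 matches its anchors and the brute-force oracle", {
  set.seed(1)
  Y <- matrix(rnorm(50 * 4), 50)
  expect_equal(rda_fit(Y, Y)$r2, 1)
  # predictors orthogonal to the response leave nothing explained
  X <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 3), 50))))[, -1]
  Yo <- qr.resid(qr(cbind(1, X)), Y)
  expect_lt(rda_fit(Yo, X)$r2, 1e-12)
  # random design: oracle equivalence to 1e-8
  X2 <- matrix(rnorm(50 * 10), 50)
  fit <- rda_fit(Y, X2)
  expect_equal(fit$r2, oracle_r2(Y, X2), tolerance = 1e-8)
  # Ezekiel adjustment
  expect_equal(fit$adj_r2, 1 - (1 - fit$r2) * 49 / (50 - 10 - 1))
  expect_lte(fit$adj_r2, fit$r2)
  # collinear predictors: warning, pseudo-inverse projection
  expect_warning(rda_fit(Y, cbind(X2, X2[, 1])), "collinear")
})

test_that("RDA agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(2)
  Y <- matrix(rnorm(40 * 3), 40)
  X <- matrix(rnorm(40 * 5), 40)
  fit <- rda_fit(Y, X)
  vfit <- vegan::rda(Y ~ X)
  expect_equal(fit$r2, unname(vfit$CCA$tot.chi / vfit$tot.chi),
               tolerance = 1e-10)
  expect_equal(fit$adj_r2, vegan::RsquareAdj(vfit)$adj.r.squared,
               tolerance = 1e-10)
})

test_that("variance partitioning satisfies its identities", {
  set.seed(3)
  n <- 60
  Y <- matrix(rnorm(n * 4), n)
  X <- matrix(rnorm(n * 3), n)
  Z <- matrix(rnorm(n * 3), n)
  part <- partial_rda(Y, X, Z)
  expect_equal(part$unique_X + part$unique_Z + part$common,
               part$total_adj_r2, tolerance = 1e-6)
  # Z empty: unique_X is the plain adjusted R2
  p0 <- partial_rda(Y, X, NULL)
  expect_equal(p0$unique_X, rda_fit(Y, X)$adj_r2)
  expect_identical(p0$common, 0)
  # X duplicated as Z: no unique contribution
  pxx <- partial_rda(Y, X, X)
  expect_equal(pxx$unique_X, 0, tolerance = 1e-10)
  # orthogonal signal blocks: each explains its share, nothing in common
  q <- sqrt(n) * qr.Q(qr(matrix(rnorm(n * 2), n)))
  Ys <- cbind(q[, 1] + 0.4 * rnorm(n), q[, 2] + 0.4 * rnorm(n))
  px <- partial_rda(Ys, q[, 1, drop = FALSE], q[, 2, drop = FALSE])
  expect_gt(px$unique_X, 0.1)
  expect_gt(px$unique_Z, 0.1)
  expect_lt(abs(px$common), 0.05)
})

test_that("the permutation test is seeded, maximal under X = Y, vegan-consistent", {
  set.seed(4)
  Y <- matrix(rnorm(30 * 2), 30)
  p_same <- rda_permutation_test(Y, Y, n_perm = 199, seed = 1)
  expect_equal(p_same$p, 1 / 200)
  expect_identical(rda_permutation_test(Y, Y[, 1], n_perm = 99, seed = 2),
                   rda_permutation_test(Y, Y[, 1], n_perm = 99, seed = 2))
  # strong true signal: small p, agreeing with vegan's anova.cca verdict
  skip_if_not_installed("vegan")
  X <- Y[, 1] + rnorm(30, 0, 0.3)
  p1 <- rda_permutation_test(Y, X, n_perm = 499, seed = 3)$p
  v <- vegan::anova.cca(vegan::rda(Y ~ X), permutations = 499)
  expect_lt(p1, 0.05)
  expect_lt(v$`Pr(>F)`[1], 0.05)
})

test_that("forward selection is deterministic and reports the dummy stop", {
  set.seed(5)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n)
  Y <- cbind(x1 + 0.3 * rnorm(n), x2 + 0.3 * rnorm(n))
  dummies <- matrix(rnorm(n * 6), n)
  cand <- cbind(x1 = x1, x2 = x2, dummies)
  colnames(cand)[3:8] <- paste0("dummy", 1:6)
  is_dummy <- c(FALSE, FALSE, rep(TRUE, 6))
  sel <- forward_select(Y, cand, is_dummy)
  expect_identical(sort(sel$selected), c("x1", "x2"))
  expect_identical(sel$stop_index, 2L)
  expect_identical(forward_select(Y, cand, is_dummy),
                   forward_select(Y, cand, is_dummy))
})
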