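test_that("plain LD r2 matches its closed-form cases", {
  x <- c(0L, 0L, 1L, 1L)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 1L - x), 1)          # complementary: r = -1
  expect_equal(ld_r2(x, c(0L, 1L, 0L, 1L)), 0)
  expect_true(is.na(ld_r2(x, c(1L, 1L, 1L, 1L))))
  # missing values restrict to the shared non-missing set
  expect_equal(ld_r2(c(x, NA), c(x, 0L)), 1)
})

test_that("structure-corrected LD removes the group component", {
  # K = 1: equals plain r2 exactly
  set.seed(1)
  x <- rbinom(40, 1, 0.5); y <- rbinom(40, 1, 0.5)
  Q1 <- matrix(1, 40, 1)
  expect_equal(ld_rs2(x, y, Q1), ld_r2(x, y))
  # both loci fully determined by a 2-group structure: no residual LD
  g <- rep(0:1, each = 20)
  Q2 <- cbind(g, 1 - g)
  expect_true(is.na(ld_rs2(g, g, Q2)) || ld_rs2(g, g, Q2) < 1e-10)
  # structure-free pair: correction changes nothing much
  expect_lt(abs(ld_rs2(x, y, Q2) - ld_r2(x, y)), 0.05)
})

test_that("corrected LD is lower than raw LD across structured pairs", {
  sim <- small_bn_sim()
  G <- impute_knn(sim$G)
  set.seed(2)
  pairs <- matrix(sample(ncol(G), 120, replace = TRUE), ncol = 2)
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  r2 <- apply(pairs, 1, function(p) ld_r2(G[, p[1]], G[, p[2]]))
  rs2 <- apply(pairs, 1, function(p) ld_rs2(G[, p[1]], G[, p[2]], sim$Q))
  ok <- !is.na(r2) & !is.na(rs2)
  expect_lte(median(rs2[ok]), median(r2[ok]))
})

test_that("the neighbourhood LD profile averages the available window", {
  calls <- matrix(rep(c(0L, 1L), each = 10), 20, 3,
                  dimnames = list(sprintf("a%02d", 1:20), c("A", "B", "C")))
  calls[1, 2] <- 1L  # perturb B so it is not identical
  G <- genotype_matrix(calls)
  map <- marker_map(c("A", "B", "C"), "1H", c(0, 5, 10), c(1, 2, 3) * 1e6)
  prof <- neighbor_ld_profile(G, map, n_side = 4)
  # middle locus averages over exactly its two flanking loci
  rAB <- ld_r2(G[, "A"], G[, "B"])
  rBC <- ld_r2(G[, "B"], G[, "C"])
  rAC <- ld_r2(G[, "A"], G[, "C"])
  expect_equal(prof$rs2_mean[prof$id == "B"], mean(c(rAB, rBC)))
  expect_equal(prof$rs2_mean[prof$id == "A"], mean(c(rAB, rAC)))
  # all-identical loci: profile of ones
  same <- genotype_matrix(matrix(rep(c(0L, 1L), each = 10), 20, 3,
                                 dimnames = dimnames(calls)))
  expect_equal(neighbor_ld_profile(same, map)$rs2_mean, rep(1, 3))
})

test_that("independent loci give a low LD profile at realistic sample size", {
  sim <- gen_structured_genotypes(135, 200, 135L, 0.2, seed = 12)
  prof <- neighbor_ld_profile(sim$G, sim$map, n_side = 4)
  expect_lt(mean(prof$rs2_mean, na.rm = TRUE), 0.1)
})

test_that("the nonredundant shortlist prunes by LD and position", {
  n <- 30
  base <- rep(c(0L, 1L), length.out = n)
  dup <- matrix(base, n, 6,
                dimnames = list(sprintf("a%02d", 1:n), paste0("l", 1:6)))
  G <- genotype_matrix(dup)
  map <- marker_map(paste0("l", 1:6), "1H", seq(0, 10, length.out = 6),
                    seq_len(6) * 1e5)
  expect_identical(shortlist_nonredundant(G, map), "l1")
  # mutually independent loci with distinct positions are all kept
  sim <- gen_structured_genotypes(120, 60, 120L, 0.2, seed = 13)
  kept <- shortlist_nonredundant(sim$G, sim$map, r2_max = 0.99)
  expect_identical(length(kept), 60L)
  # exact cM ties: first kept wins
  map_tie <- marker_map(paste0("l", 1:6), "1H", c(0, 0, 1, 1, 2, 3),
                        seq_len(6) * 1e5)
  set.seed(3)
  rnd <- genotype_matrix(matrix(rbinom(n * 6, 1, 0.5), n, 6,
                                dimnames = dimnames(dup)))
  kept_tie <- shortlist_nonredundant(rnd, map_tie, r2_max = 1.01)
  expect_identical(kept_tie, c("l1", "l3", "l5", "l6"))
  # deterministic and order-stable
  expect_identical(shortlist_nonredundant(rnd, map_tie),
                   shortlist_nonredundant(rnd, map_tie))
})
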