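years <- 12
series_a <- local({
  s <- make_const_series(-1, 9, years = years, start = 1995)
  s$pcp <- 2; s$et0 <- 1
  s
})

test_that("period aggregation follows the family rules", {
  s <- make_const_series(4, 4, years = 2, pcp = 1, et0 = 0.5)
  expect_equal(aggregate_acv(s, "pcp", "jan"), 31)
  expect_equal(aggregate_acv(s, "tmed", "jul"), 4)
  # tmin = -1 all of January -> 31 frost days
  expect_equal(aggregate_acv(series_a, "frost", "jan"), 31)
  # pcp 2, et0 1 over 30-day month -> bal = 30
  expect_equal(aggregate_acv(series_a, "bal", "apr"), 30)
  expect_equal(aggregate_acv(series_a, "tamp", "annual"), 10)
  expect_error(aggregate_acv(s, "pcp", "noperiod"), "unknown period")
})

test_that("seasonal water balance is additive over its months", {
  fx <- fixture_weather_small()
  s <- fx$weather[[1]]
  spec <- season_spec()
  win <- aggregate_acv(s, "bal", "win", spec)
  monthly <- sum(vapply(spec$win, function(m) aggregate_acv(s, "bal", m, spec),
                        numeric(1)))
  expect_equal(win, monthly, tolerance = 1e-10)
})

test_that("the default catalogue enumerates exactly 147 agroclimatic variables", {
  fx <- fixture_weather_small()
  catalogue <- fx$catalogue
  acv <- attr(catalogue, "agroclimatic")
  expect_identical(length(acv), 147L)
  expect_false(anyDuplicated(acv) > 0)
  # pfrost appears exactly once (annual scale only)
  expect_identical(sum(grepl("^pfrost", acv)), 1L)
  # family x period structure: 6 families without annual, ET_0/bal with
  expect_identical(sum(grepl("^pcp_", acv)), 16L)
  expect_identical(sum(grepl("^ET_0_", acv)), 17L)
  expect_identical(sum(grepl("^bal_", acv)), 17L)
  expect_identical(sum(grepl("^verna_", acv)), 16L)  # 12 months + 4 Nd
  # geographic columns present but not counted as agroclimatic
  expect_true(all(c("lon", "lat", "alt") %in% names(catalogue)))
  expect_false(any(c("lon", "lat", "alt") %in% acv))
  # no NaN for complete input series
  expect_false(anyNA(catalogue[, setdiff(acv, paste0("verna_", c(10, 20, 30, 40), "d"))]))
})

test_that("the analysis subset drops summer and July-October aggregates", {
  fx <- fixture_weather_small()
  sub <- analysis_subset(fx$catalogue)
  acv <- attr(sub, "agroclimatic")
  expect_false(any(grepl("_(jul|aug|sep|oct|summer)$", acv)))
  expect_true("pcp_win" %in% acv && "pfrost" %in% acv)
  expect_lt(length(acv), 147L)
})

test_that("multi-month composites follow the family aggregation rule", {
  fx <- fixture_weather_small()
  cat_ <- fx$catalogue
  comp <- acv_composites(cat_, list(pcp_mar_apr = c("pcp_mar", "pcp_apr"),
                                    tamp_jf = c("tamp_jan", "tamp_feb")))
  expect_equal(comp$pcp_mar_apr, cat_$pcp_mar + cat_$pcp_apr)
  expect_equal(comp$tamp_jf, (cat_$tamp_jan + cat_$tamp_feb) / 2)
  expect_error(acv_composites(cat_, list(x = c("pcp_mar", "nope"))), "unknown")
  sel <- acv_default_selection(cat_)
  expect_identical(ncol(sel), 20L)
  expect_identical(names(sel)[1:3], c("lon", "lat", "alt"))
})

test_that("variable clustering groups duplicates and respects k", {
  fx <- fixture_weather_small()
  m <- as.matrix(fx$catalogue[, c("tmed_jan", "tmed_feb", "pcp_aut",
                                  "pcp_win", "bal_win", "tamp_spr")])
  m <- cbind(m, tmed_jan_copy = m[, "tmed_jan"])
  cl <- cluster_variables(m, k = 3)
  expect_identical(cl$clusters[["tmed_jan"]], cl$clusters[["tmed_jan_copy"]])
  # k = number of variables -> singletons
  cl2 <- cluster_variables(m, k = ncol(m))
  expect_identical(length(unique(cl2$clusters)), ncol(m))
  # two orthogonal blocks of correlated variables split perfectly at k = 2
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40)
  blocks <- cbind(a1 = a, a2 = a + rnorm(40, 0, 0.05),
                  a3 = a + rnorm(40, 0, 0.05),
                  b1 = b, b2 = b + rnorm(40, 0, 0.05),
                  b3 = b + rnorm(40, 0, 0.05))
  cl3 <- cluster_variables(blocks, k = 2)$clusters
  expect_identical(length(unique(cl3[1:3])), 1L)
  expect_identical(length(unique(cl3[4:6])), 1L)
  expect_false(cl3[1] == cl3[4])
  # constant variable dropped with warning
  expect_warning(cluster_variables(cbind(m, const = 1), k = 3), "constant")
})

test_that("environmental PCA behaves like a correlation-matrix eigendecomposition", {
  set.seed(4)
  x <- rnorm(20)
  # two perfectly correlated variables: PC1 carries everything
  p <- pca_env(cbind(a = x, b = 2 * x + 3))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  expect_lt(p$variance_fraction[2], 1e-12)
  # fractions are sorted and sum to 1
  m <- matrix(rnorm(10 * 100), 10)
  p2 <- pca_env(m)
  expect_true(all(diff(p2$variance_fraction) <= 1e-12))
  expect_equal(sum(p2$variance_fraction), 1)
  # orthogonal-transform identity: scores %*% t(loadings) rebuilds scaled data
  rebuilt <- p2$scores %*% t(p2$loadings)
  expect_equal(rebuilt, scale(m), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_env(cbind(x, const = 1)), "constant")
})
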