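#' Simulate structured haploid genotypes (Balding-Nichols model)
#'
#' Draws ancestral allele frequencies per locus, then per-group frequencies
#' from the Balding-Nichols beta distribution
#' `Beta(p (1-F)/F, (1-p) (1-F)/F)` with the group's differentiation
#' parameter `F`, and finally haploid calls as Bernoulli draws per inbred
#' accession. Also returns a one-hot Q matrix and a marker map with monotone
#' genetic positions across 7 chromosomes.
#'
#' @param n_acc number of accessions.
#' @param n_loci number of biallelic loci.
#' @param group_sizes integer vector of group sizes summing to `n_acc`.
#' @param fst per-group differentiation in (0, 1); recycled to the number
#'   of groups.
#' @param missing_rate fraction of calls set missing uniformly at random
#'   (default 0: complete).
#' @param seed integer seed.
#' @param n_chrom number of chromosomes for the marker map (default 7).
#' @param ancestral_range range of the uniform ancestral-frequency spectrum.
#' @return list with `G` ([genotype_matrix()]), `Q` (one-hot matrix),
#'   `map` (marker map), `groups` (label per accession) and
#'   `group_freqs` (groups x loci).
#' @export
gen_structured_genotypes <- function(n_acc, n_loci, group_sizes, fst,
                                     missing_rate = 0, seed = 1L,
                                     n_chrom = 7L,
                                     ancestral_range = c(0.05, 0.95)) {
  K <- length(group_sizes)
  if (sum(group_sizes) != n_acc) stop("group sizes must sum to n_acc")
  stopifnot(n_acc >= K, K >= 1, all(fst > 0), all(fst < 1),
            missing_rate >= 0, missing_rate < 1)
  fst <- rep_len(fst, K)
  set.seed(seed)
  p_anc <- stats::runif(n_loci, ancestral_range[1], ancestral_range[2])
  pf <- matrix(NA_real_, K, n_loci)
  for (g in seq_len(K)) {
    a <- (1 - fst[g]) / fst[g]
    pf[g, ] <- stats::rbeta(n_loci, a * p_anc, a * (1 - p_anc))
  }
  groups <- rep(seq_len(K), group_sizes)
  calls <- matrix(stats::rbinom(n_acc * n_loci, 1,
                                rep(pf[groups, ], 1)),
                  n_acc, n_loci)
  if (missing_rate > 0) {
    calls[stats::runif(n_acc * n_loci) < missing_rate] <- NA_integer_
  }
  rownames(calls) <- sprintf("acc%03d", seq_len(n_acc))
  colnames(calls) <- sprintf("snp%05d", seq_len(n_loci))
  Q <- matrix(0, n_acc, K, dimnames = list(rownames(calls),
                                           paste0("Q", seq_len(K))))
  Q[cbind(seq_len(n_acc), groups)] <- 1
  chrom <- sort(rep_len(seq_len(n_chrom), n_loci))
  cM <- stats::ave(stats::runif(n_loci, 0, 150), chrom, FUN = sort)
  bp <- round(cM * 4e6 + stats::runif(n_loci, 0, 1e5))
  map <- marker_map(colnames(calls), sprintf("%dH", chrom), cM, bp)
  list(G = genotype_matrix(calls), Q = Q, map = map,
       groups = paste0("G", groups), group_freqs = pf)
}

#' Plant environmental clines at causal loci
#'
#' Re-draws the calls of the designated causal loci so that each accession's
#' allele-1 probability is `plogis(qlogis(p_group) + beta * env)`, where
#' `p_group` is its group's Balding-Nichols frequency and `env` its
#' (standardised) environmental value. Non-causal loci are untouched.
#'
#' @param sim output of [gen_structured_genotypes()].
#' @param env numeric environment per accession (standardised).
#' @param causal_ids locus ids (subset of `colnames(sim$G)`).
#' @param beta logit-scale frequency shift per 1 SD of environment.
#' @param seed integer seed.
#' @return `sim` with updated `G` and an added `truth` list
#'   (`causal_locus_ids`, `effect_sizes`, `group_assignments`, `group_fst`).
#' @export
plant_env_clines <- function(sim, env, causal_ids, beta, seed = 1L) {
  if (!is.finite(beta)) stop("beta must be finite")
  stopifnot(length(env) == nrow(sim$G))
  if (!all(causal_ids %in% colnames(sim$G))) {
    stop("causal ids must be simulated loci")
  }
  G <- sim$G
  if (length(causal_ids) > 0) {
    set.seed(seed)
    # map group labels back to rows of group_freqs
    gnum <- as.integer(sub("^G", "", sim$groups))
    for (id in causal_ids) {
      j <- match(id, colnames(G))
      p0 <- pmin(pmax(sim$group_freqs[gnum, j], 1e-4), 1 - 1e-4)
      p1 <- stats::plogis(stats::qlogis(p0) + beta * env)
      keep_na <- is.na(G[, j])
      G[, j] <- stats::rbinom(nrow(G), 1, p1)
      G[keep_na, j] <- NA_integer_
    }
  }
  sim$G <- genotype_matrix(G)
  sim$truth <- list(causal_locus_ids = as.character(causal_ids),
                    effect_sizes = rep(beta, length(causal_ids)),
                    group_assignments = sim$groups,
                    group_fst = NULL)
  sim
}

#' End-to-end synthetic fixture
#'
#' A self-consistent bundle exercising the whole pipeline at desk scale:
#' daily weather on a small grid with latitude/altitude gradients, the
#' agroclimatic catalogue at the grid cells, structured genotypes for
#' accessions assigned (with group-geography correlation) to cells, a one-hot
#' Q matrix, spatially correlated dummy variables, and truth labels for the
#' causal loci carrying a planted cline on a north--south environmental
#' gradient.
#'
#' @param seed integer seed driving every stochastic step.
#' @param n_acc,n_loci,n_causal fixture sizes (defaults 120, 3000, 20).
#' @param beta planted logit-scale effect size (default 2).
#' @param group_sizes accession group sizes; default scales the unbalanced
#'   15:10:45:50 proportions to `n_acc`.
#' @param fst per-group Balding-Nichols differentiation.
#' @param n_years years of daily weather (default 15).
#' @param grid_dim grid rows = cols (default 6).
#' @param with_weather set `FALSE` to skip weather/catalogue generation and
#'   use the raw northing gradient as the environment (faster).
#' @return list with `sim` (genotypes, Q, map, groups, truth), `env`
#'   (per-accession environment used for the cline), `sites`, `site_of_acc`,
#'   and, when `with_weather`, `weather`, `catalogue`, `env_table`
#'   (per-accession selected variables) and `dummies`.
#' @export
end_to_end_fixture <- function(seed = 1L, n_acc = 120L, n_loci = 3000L,
                               n_causal = 20L, beta = 2,
                               group_sizes = NULL,
                               fst = c(0.35, 0.4, 0.2, 0.25),
                               n_years = 15L, grid_dim = 6L,
                               with_weather = TRUE) {
  if (is.null(group_sizes)) {
    # unbalanced groups in the proportions 15:10:45:50, scaled to n_acc
    group_sizes <- round(n_acc * c(15, 10, 45, 50) / 120)
    group_sizes[4] <- n_acc - sum(group_sizes[1:3])
  }
  grid <- make_grid(grid_dim, grid_dim, cell_km = 40)
  sites <- data.frame(id = sprintf("site%02d", seq_len(nrow(grid))),
                      x = grid$x, y = grid$y)
  set.seed(seed)
  sites$alt <- pmax(0, 400 + 2.2 * sites$y + stats::rnorm(nrow(sites), 0, 150))
  sites$lon <- sites$x
  sites$lat <- sites$y
  sim <- gen_structured_genotypes(n_acc, n_loci, group_sizes, fst,
                                  missing_rate = 0.05, seed = seed + 1L)
  # groups cluster along the northing axis: group g centred at its own band
  set.seed(seed + 2L)
  K <- length(group_sizes)
  gnum <- as.integer(sub("^G", "", sim$groups))
  band <- (gnum - 0.5) / K * max(sites$y)
  yy <- band + stats::rnorm(n_acc, 0, max(sites$y) / 4)
  site_of_acc <- vapply(yy, function(v) which.min(abs(sites$y - v) +
    stats::runif(nrow(sites), 0, 1e-3)), integer(1))
  if (with_weather) {
    wp <- weather_params(n_years = n_years)
    weather <- gen_daily_weather(wp, sites, seed = seed + 3L)
    catalogue <- build_catalogue(weather, sites = sites,
                                 pfrost_min_years = min(10L, n_years))
    selection <- acv_default_selection(catalogue)
    env_table <- selection[site_of_acc, , drop = FALSE]
    rownames(env_table) <- rownames(sim$G)
    # cline on the late-frost gradient (falls back to latitude if degenerate)
    env <- if (stats::sd(env_table$pfrost) > 0) {
      as.vector(scale(env_table$pfrost))
    } else {
      as.vector(scale(env_table$lat))
    }
    model <- semivariogram_model("gaussian", nugget = 0.05, psill = 1,
                                 range = 60)
    dummies <- make_dummies(12L, grid, model, sites, seed = seed + 4L)[
      site_of_acc, , drop = FALSE]
    rownames(dummies) <- rownames(sim$G)
  } else {
    weather <- catalogue <- env_table <- dummies <- NULL
    env <- as.vector(scale(sites$y[site_of_acc]))
  }
  set.seed(seed + 6L)
  # a planted cline needs room to move: restrict causal loci to intermediate
  # frequencies (a locus near fixation cannot follow an environmental cline)
  pm <- colMeans(sim$group_freqs)
  eligible <- colnames(sim$G)[pm > 0.2 & pm < 0.8]
  causal <- sample(eligible, n_causal)
  sim <- plant_env_clines(sim, env, causal, beta, seed = seed + 5L)
  sim$truth$group_fst <- fst
  list(sim = sim, env = env, sites = sites, site_of_acc = site_of_acc,
       weather = weather, catalogue = catalogue, env_table = env_table,
       dummies = dummies, seed = seed)
}
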