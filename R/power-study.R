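#' Causal-locus recovery on the end-to-end fixture
#'
#' One replicate of the planted-cline power study: builds the seeded
#' end-to-end fixture, applies the standard filters (10% missing, MAF 0.05),
#' imputes, shortlists low-LD markers, estimates the accession-level
#' covariance matrix, runs the covariance-model association over the
#' 20-variable selection and reports which causal loci are recovered by the
#' consensus rule (pooled top-1% Bayes factor and per-run top-1% |rho|).
#'
#' @param seed fixture seed.
#' @param n_runs association runs per variable (default 3).
#' @param n_draws Monte Carlo draws per Bayes factor (default 30).
#' @param bf_quantile,rho_quantile consensus quantiles (default 0.99).
#' @param ... further arguments for [end_to_end_fixture()].
#' @return list with `recovery` (fraction of causal loci hit), `n_causal`,
#'   `hits` (consensus table) and `causal` ids.
#' @export
causal_recovery <- function(seed, n_runs = 3L, n_draws = 30L,
                            bf_quantile = 0.99, rho_quantile = 0.99, ...) {
  fx <- end_to_end_fixture(seed = seed, ...)
  G <- impute_knn(maf_filter(filter_missing(fx$sim$G, 0.10), 0.05))
  causal <- intersect(fx$sim$truth$causal_locus_ids, colnames(G))
  map <- fx$sim$map[fx$sim$map$id %in% colnames(G), ]
  shortlist <- shortlist_nonredundant(G, map)
  om <- estimate_omega(G[, shortlist, drop = FALSE], rownames(G),
                       seed = seed)$omega
  env <- standardize_env(fx$env_table)
  res <- run_association(G, env, omega = om, n_runs = n_runs,
                         seed_base = seed * 1000L, n_draws = n_draws)
  hits <- consensus_hits(res, bf_quantile, rho_quantile)
  list(recovery = mean(causal %in% hits$locus), n_causal = length(causal),
       hits = hits, causal = causal)
}
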