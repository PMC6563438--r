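#' Pipeline configuration
#'
#' Validates and bundles the thresholds, model switches and seeds used by
#' [run_pipeline()]. Defaults follow the analysis conventions: 10% missing
#' ceiling, MAF 0.05, LD r-squared 0.2 shortlist ceiling, top-1% consensus
#' quantiles, 99.99 dummy percentile, FDR Q = 0.01, XtX POD percentile 99.
#'
#' @param max_missing,min_maf,r2_max filtering thresholds.
#' @param bf_quantile,rho_quantile consensus quantiles.
#' @param dummy_percentile dummy-threshold percentile.
#' @param fdr_q FDR level for the latent-factor analysis.
#' @param xtx_percentile POD percentile for the XtX threshold.
#' @param k_latent latent factors (default 6).
#' @param n_runs association runs (default 5).
#' @param seed base seed.
#' @return validated list (class `pipeline_config`).
#' @export
pipeline_config <- function(max_missing = 0.10, min_maf = 0.05, r2_max = 0.2,
                            bf_quantile = 0.99, rho_quantile = 0.99,
                            dummy_percentile = 99.99, fdr_q = 0.01,
                            xtx_percentile = 99, k_latent = 6L,
                            n_runs = 5L, seed = 1L) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf < 0.5,
            r2_max > 0, r2_max <= 1,
            bf_quantile > 0, bf_quantile < 1, rho_quantile > 0,
            rho_quantile < 1, dummy_percentile > 0, dummy_percentile <= 100,
            fdr_q > 0, fdr_q <= 1, xtx_percentile > 0, xtx_percentile <= 100,
            k_latent >= 0, n_runs >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full association pipeline
#'
#' Orchestrates the analysis on in-memory inputs: missing-data and MAF
#' filters, kNN imputation, nonredundant low-LD shortlist, accession-level
#' covariance matrix, Bayes-factor association under the covariance and null
#' models with consensus and dummy-based thresholds, latent-factor
#' association with Fisher-Stouffer combination and FDR, group-level
#' differentiation scans (H, Fst, XtX with a POD threshold, structure-
#' corrected LD, 4 cM sliding windows) and RDA variance partitioning.
#' Deterministic given the config seed; every stage is logged with its
#' parameters.
#'
#' @param G a [genotype_matrix()].
#' @param map marker map for `colnames(G)`.
#' @param Q membership matrix (accessions x groups).
#' @param groups group label per accession.
#' @param env standardised accession x variable environment matrix
#'   (agroclimatic + geographic variables).
#' @param dummies standardised accession x dummy matrix.
#' @param config a [pipeline_config()].
#' @return list with `association` (covariance model), `association_null`,
#'   `consensus`, `dummy_bf_threshold`, `lfmm` (z/p/q per locus for the first
#'   env variable), `scan` (per-locus H/XtX/rs2 + windows), `xtx_threshold`,
#'   `rda` (partition env vs geography), `filtered` sizes and `log`.
#' @export
run_pipeline <- function(G, map, Q, groups, env, dummies,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(list(stage = stage), list(...))
  }
  if (is.null(G) || is.null(map) || is.null(env)) {
    stop("stage input: genotype matrix, map and environment are required")
  }

  G1 <- filter_missing(G, config$max_missing)
  note("filter_missing", max_missing = config$max_missing,
       kept = ncol(G1), dropped = ncol(G) - ncol(G1))
  G2 <- maf_filter(G1, config$min_maf)
  note("maf_filter", min_maf = config$min_maf, kept = ncol(G2))
  Gi <- impute_knn(G2)
  note("impute_knn", k = 5L)
  map2 <- map[map$id %in% colnames(G2), ]

  shortlist <- shortlist_nonredundant(G2, map2, r2_max = config$r2_max)
  note("shortlist_nonredundant", r2_max = config$r2_max,
       kept = length(shortlist))

  omega_acc <- estimate_omega(Gi[, shortlist, drop = FALSE],
                              rownames(Gi), seed = config$seed)
  note("estimate_omega", level = "accession", n_loci = omega_acc$n_loci)

  env <- as.matrix(env)
  env_all <- cbind(env, dummies)
  assoc_cov <- run_association(Gi, env_all, omega = omega_acc$omega,
                               n_runs = config$n_runs,
                               seed_base = config$seed * 1000L)
  assoc_null <- run_association(Gi, env_all, omega = NULL,
                                n_runs = config$n_runs,
                                seed_base = config$seed * 1000L)
  note("association", runs = config$n_runs, variables = ncol(env_all))

  dummy_cols <- colnames(dummies)
  dummy_thr <- dummy_threshold(as.vector(assoc_cov$bf_median[, dummy_cols]),
                               config$dummy_percentile)
  consensus <- consensus_hits(assoc_cov, config$bf_quantile,
                              config$rho_quantile,
                              variables = colnames(env))
  note("thresholds", dummy_bf_threshold = dummy_thr,
       consensus_hits = nrow(consensus))

  zmat <- latent_factor_assoc(Gi, env[, 1], k = config$k_latent,
                              n_runs = config$n_runs,
                              seed_base = config$seed * 2000L)
  comb <- combine_fisher_stouffer(zmat)
  lfmm <- cbind(comb, bh_fdr(comb$p, config$fdr_q)[, c("q", "significant")])
  note("latent_factor_assoc", k = config$k_latent,
       significant = sum(lfmm$significant))

  pf <- pop_freqs(Gi, groups)
  omega_grp <- estimate_omega(Gi[, shortlist, drop = FALSE], groups,
                              seed = config$seed)
  xtx_vals <- xtx(pf$p, omega_grp$omega)
  eps <- colMeans(pf$p)
  xtx_thr <- pod_threshold(omega_grp$omega, eps, n_sim = 5000L,
                           percentile = config$xtx_percentile,
                           seed = config$seed)
  h_vals <- expected_het(colMeans(Gi))
  ld_prof <- neighbor_ld_profile(Gi, map2, Q = Q, n_side = 4L)
  map_ord <- map2[match(ld_prof$id, map2$id), ]
  scan <- list(
    xtx = sliding_windows(xtx_vals[match(map_ord$id, colnames(Gi))], map_ord),
    het = sliding_windows(h_vals[match(map_ord$id, colnames(Gi))], map_ord),
    ld = sliding_windows(ld_prof$rs2_mean, map_ord)
  )
  note("differentiation_scan", xtx_threshold = xtx_thr)

  fst <- fst_pairwise(Gi, groups)
  rda_part <- partial_rda(Q, env[, setdiff(colnames(env),
                                           c("lon", "lat", "alt")),
                                 drop = FALSE],
                          Z = env[, intersect(c("lon", "lat", "alt"),
                                              colnames(env)), drop = FALSE])
  note("rda", total_adj_r2 = rda_part$total_adj_r2)

  list(association = assoc_cov, association_null = assoc_null,
       consensus = consensus, dummy_bf_threshold = dummy_thr,
       lfmm = lfmm, scan = scan, xtx_threshold = xtx_thr, fst = fst,
       rda = rda_part, shortlist = shortlist,
       filtered = c(input = ncol(G), after_missing = ncol(G1),
                    after_maf = ncol(G2)),
       log = log)
}

#' Candidate genomic regions around significant SNPs
#'
#' For each hit locus with a physical position, reports the `bp +/- flank`
#' window, the counts of overlapping annotation features per confidence
#' class, and the feature containing the SNP itself (gene hit), using
#' half-open interval overlap.
#'
#' @param hits character vector of locus ids.
#' @param map marker map with `bp` positions.
#' @param annotation data frame with `chrom`, `start`, `end`, `feature_id`
#'   and optionally `confidence` (e.g. from [read_annotation_gff()]).
#' @param flank half-window size in bp (default 1e6).
#' @return data frame, one row per hit locus with a position.
#' @export
candidate_regions <- function(hits, map, annotation, flank = 1e6) {
  idx <- match(hits, map$id)
  no_bp <- is.na(idx) | is.na(map$bp[idx])
  if (any(no_bp)) {
    warning(sum(no_bp), " locus/loci without physical position skipped")
  }
  hits <- hits[!no_bp]; idx <- idx[!no_bp]
  if (is.null(annotation$confidence)) annotation$confidence <- "unclassified"
  rows <- lapply(seq_along(hits), function(i) {
    ch <- map$chrom[idx[i]]; bp <- map$bp[idx[i]]
    lo <- max(0, bp - flank); hi <- bp + flank
    ann <- annotation[annotation$chrom == ch &
                        annotation$start < hi & annotation$end > lo, ,
                      drop = FALSE]
    inside <- ann[ann$start <= bp & ann$end >= bp, , drop = FALSE]
    cls <- table(factor(ann$confidence,
                        levels = unique(annotation$confidence)))
    out <- data.frame(locus = hits[i], chrom = ch, bp = bp,
                      window_start = lo, window_end = hi,
                      n_features = nrow(ann),
                      gene_hit = if (nrow(inside)) inside$feature_id[1]
                                 else NA_character_)
    for (k in names(cls)) out[[paste0("n_", k)]] <- as.integer(cls[[k]])
    out
  })
  if (length(rows) == 0) {
    return(data.frame(locus = character(0), chrom = character(0),
                      bp = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Read a GFF3 annotation into the candidate-region table format
#'
#' Thin wrapper over `rtracklayer::import`; gene-level features are kept and
#' a `confidence` column is taken from the `confidence_class` attribute when
#' present.
#'
#' @param path GFF3 file.
#' @param feature_types types to keep (default "gene").
#' @return data frame with `chrom`, `start`, `end`, `feature_id`, `confidence`.
#' @export
read_annotation_gff <- function(path, feature_types = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GFF3 annotation")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% feature_types]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   feature_id = if (!is.null(gr$ID)) gr$ID else
                     as.character(seq_along(gr)))
  df$confidence <- if (!is.null(gr$confidence_class)) {
    as.character(gr$confidence_class)
  } else "unclassified"
  df
}

#' Read a long-format daily climate CSV into per-site series
#'
#' Expects columns `site`, `date`, `tmin`, `tmax`, `pcp`, `et0`.
#'
#' @param path CSV file.
#' @return named list of daily data frames, one per site.
#' @export
read_daily_climate_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("site", "date", "tmin", "tmax", "pcp", "et0") %in% names(df)))
  split(df[, c("date", "tmin", "tmax", "pcp", "et0")], df$site)
}

#' @rdname read_daily_climate_csv
#' @param series_list named list of daily data frames.
#' @export
write_daily_climate_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(names(series_list), function(s) {
    cbind(site = s, series_list[[s]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
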