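#' Filter loci by missing-data fraction
#'
#' Removes loci whose fraction of missing calls exceeds `max_frac`
#' (strictly greater), preserving locus order.
#'
#' @param G a [genotype_matrix()].
#' @param max_frac maximum tolerated missing fraction (default 0.10).
#' @return filtered [genotype_matrix()].
#' @export
filter_missing <- function(G, max_frac = 0.10) {
  miss <- colMeans(is.na(G))
  out <- G[, miss <= max_frac, drop = FALSE]
  genotype_matrix(out)
}

#' Minor allele frequency per locus
#'
#' @param G a [genotype_matrix()].
#' @return numeric vector of MAF from non-missing calls (NA for all-missing).
#' @export
locus_maf <- function(G) {
  p <- colMeans(G, na.rm = TRUE)
  pmin(p, 1 - p)
}

#' Filter loci by minor allele frequency
#'
#' Retains loci with MAF strictly greater than `min_maf` by default
#' (the conventional "MAF > 0.05" rule); set `strict = FALSE` to retain
#' loci at the threshold.
#'
#' @param G a [genotype_matrix()].
#' @param min_maf threshold (default 0.05).
#' @param strict if `TRUE` (default) keep MAF > `min_maf`, else >=.
#' @return filtered [genotype_matrix()].
#' @export
maf_filter <- function(G, min_maf = 0.05, strict = TRUE) {
  maf <- locus_maf(G)
  keep <- if (strict) maf > min_maf else maf >= min_maf
  keep[is.na(keep)] <- FALSE
  genotype_matrix(G[, keep, drop = FALSE])
}

#' k-nearest-neighbour imputation of missing calls
#'
#' Replaces each missing call by the majority allele among the `k` accessions
#' most similar to the carrier (smallest proportion of mismatching calls over
#' shared non-missing loci) that are themselves called at the locus. Ties
#' (including the all-neighbours-missing case) fall back to the locus's
#' global major allele.
#'
#' @param G a [genotype_matrix()].
#' @param k number of neighbours (default 5).
#' @return complete [genotype_matrix()] (no missing calls).
#' @export
impute_knn <- function(G, k = 5L) {
  if (!anyNA(G)) return(G)
  if (any(colMeans(is.na(G)) == 1)) stop("locus with all calls missing")
  n <- nrow(G)
  M <- matrix(as.numeric(G), n, ncol(G))
  obs <- !is.na(M)
  M0 <- M; M0[!obs] <- 0
  # mismatch distance: Hamming count over shared observed loci
  shared <- tcrossprod(obs * 1)
  same <- tcrossprod(M0 * obs) + tcrossprod((1 - M0) * obs)
  dist_mat <- 1 - same / pmax(shared, 1)
  dist_mat[shared == 0] <- 1
  diag(dist_mat) <- Inf
  gmaj <- ifelse(colMeans(M, na.rm = TRUE) >= 0.5, 1L, 0L)
  out <- G
  for (i in seq_len(n)) {
    miss_j <- which(is.na(G[i, ]))
    if (length(miss_j) == 0) next
    ord <- order(dist_mat[i, ])
    for (j in miss_j) {
      nb <- ord[obs[ord, j]]
      nb <- nb[seq_len(min(k, length(nb)))]
      if (length(nb) == 0) {
        out[i, j] <- gmaj[j]
      } else {
        p <- mean(M[nb, j])
        out[i, j] <- if (p > 0.5) 1L else if (p < 0.5) 0L else gmaj[j]
      }
    }
  }
  genotype_matrix(out)
}
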