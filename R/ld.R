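#' Linkage disequilibrium r-squared between two loci
#'
#' Squared Pearson correlation of haploid-coded call vectors over shared
#' non-missing accessions. `NA` when either locus is monomorphic on the
#' shared set.
#'
#' @param x,y call vectors in `{0, 1, NA}`.
#' @return r-squared in \[0, 1\] or `NA`.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Structure-corrected linkage disequilibrium r_S-squared
#'
#' LD between two loci after removing the component explained by population
#' structure: both call vectors are residualised on the span of the intercept
#' and the Q-matrix membership columns, and the squared correlation of the
#' residuals is reported. With a single population (K = 1) this equals
#' [ld_r2()] exactly.
#'
#' @param x,y call vectors in `{0, 1, NA}`.
#' @param Q accession x cluster membership matrix (rows aligned with `x`).
#' @return r_S-squared in \[0, 1\], or `NA` when a residual is degenerate.
#' @export
ld_rs2 <- function(x, y, Q) {
  Q <- as.matrix(Q)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; Qo <- Q[ok, , drop = FALSE]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  X <- cbind(1, Qo)
  rx <- stats::residuals(stats::lm.fit(X, x))
  ry <- stats::residuals(stats::lm.fit(X, y))
  if (stats::sd(rx) < 1e-10 || stats::sd(ry) < 1e-10) return(NA_real_)
  stats::cor(rx, ry)^2
}

#' Per-locus neighbourhood LD profile
#'
#' For each locus, the mean structure-corrected r_S-squared against its
#' `n_side` nearest mapped neighbours on each side (map order within the
#' concatenated genome); edge loci average over the neighbours available.
#'
#' @param G a [genotype_matrix()].
#' @param map marker map (see [marker_map()]) covering `colnames(G)`.
#' @param Q membership matrix; defaults to a single population (plain r2).
#' @param n_side neighbours per side (default 4).
#' @return data frame `id`, `chrom`, `ccM`, `rs2_mean`.
#' @export
neighbor_ld_profile <- function(G, map, Q = NULL, n_side = 4L) {
  map <- map[map$id %in% colnames(G), ]
  map <- map[order(map$ccM), ]
  if (is.null(Q)) Q <- matrix(1, nrow(G), 1)
  L <- nrow(map)
  vals <- numeric(L)
  for (i in seq_len(L)) {
    nb <- setdiff(max(1, i - n_side):min(L, i + n_side), i)
    r <- vapply(nb, function(j) {
      ld_rs2(G[, map$id[i]], G[, map$id[j]], Q)
    }, numeric(1))
    vals[i] <- mean(r, na.rm = TRUE)
  }
  data.frame(id = map$id, chrom = map$chrom, ccM = map$ccM, rs2_mean = vals)
}

#' Shortlist of nonredundant, low-LD markers
#'
#' Greedy left-to-right scan along the map keeping a locus iff (a) its
#' genetic position differs from every locus already kept (first kept wins on
#' exact cM ties) and (b) its LD r-squared against all kept loci lying within
#' its `n_side`-marker window (index space, each side) stays below `r2_max`.
#' Deterministic and order-stable.
#'
#' @param G a [genotype_matrix()].
#' @param map marker map covering `colnames(G)`.
#' @param r2_max LD ceiling (default 0.2, exclusive).
#' @param n_side window half-width in markers (default 5).
#' @return character vector of kept locus ids, in map order.
#' @export
shortlist_nonredundant <- function(G, map, r2_max = 0.2, n_side = 5L) {
  map <- map[map$id %in% colnames(G), ]
  map <- map[order(map$ccM), ]
  L <- nrow(map)
  kept <- logical(L)
  kept_pos <- character(0)
  for (i in seq_len(L)) {
    pos_key <- paste(map$chrom[i], map$cM[i])
    if (pos_key %in% kept_pos) next
    win_kept <- if (i == 1) integer(0) else {
      w <- max(1, i - n_side):(i - 1)
      w[kept[w]]
    }
    ok <- TRUE
    for (j in win_kept) {
      r2 <- ld_r2(G[, map$id[i]], G[, map$id[j]])
      if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) {
      kept[i] <- TRUE
      kept_pos <- c(kept_pos, pos_key)
    }
  }
  map$id[kept]
}
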