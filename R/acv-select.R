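#' Cluster agroclimatic variables
#'
#' Groups similar variables by Ward's D2 agglomeration on the Euclidean
#' distance between variable vectors, after centring and scaling each
#' variable across sites. Constant variables are dropped with a warning.
#'
#' @param x numeric matrix or data frame, sites x variables.
#' @param k number of clusters to cut the dendrogram into (default 10).
#' @return list with `clusters` (named integer vector per variable) and
#'   `tree` (the `hclust` object).
#' @export
cluster_variables <- function(x, k = 10L) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < k) stop("fewer variables than clusters requested")
  z <- scale(m)
  tree <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  list(clusters = stats::cutree(tree, k = k), tree = tree)
}

#' Principal component analysis of environmental variables
#'
#' PCA of the scaled-and-centred site x variable matrix (equivalently, an
#' eigendecomposition of the variable correlation matrix). Rank deficiency is
#' handled by truncation to the available components.
#'
#' @param x numeric matrix or data frame, sites x variables (no constants).
#' @return list with `scores` (site x component), `loadings`
#'   (variable x component) and `variance_fraction` (per component).
#' @export
pca_env <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) < 3 && ncol(m) > 1) stop("need at least 3 sites")
  if (any(apply(m, 2, stats::sd) == 0)) stop("constant variable in PCA input")
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, variance_fraction = vf)
}
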