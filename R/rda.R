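#' Redundancy analysis
#'
#' Projects the centred response matrix `Y` (e.g. group-membership
#' probabilities) onto the column space of the centred predictors `X`.
#' `R^2` is the trace of the fitted variance over the trace of the response
#' variance; the adjusted `R^2` uses Ezekiel's formula
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)` with `p` the effective (rank-based)
#' number of predictors. Collinear predictors are tolerated through a
#' rank-revealing QR (pseudo-inverse projection) with a warning. Canonical
#' axes are the principal components of the fitted values.
#'
#' @param Y response matrix (rows = sites/accessions).
#' @param X predictor matrix (same rows).
#' @param warn_collinear warn when X is rank-deficient (default TRUE).
#' @return an `rda_result`: list with `r2`, `adj_r2`, `rank`, `n`,
#'   `site_scores`, `axis_variance`, `fitted`, `residuals`.
#' @export
rda_fit <- function(Y, X, warn_collinear = TRUE) {
  Y <- scale(as.matrix(Y), scale = FALSE)
  X <- scale(as.matrix(X), scale = FALSE)
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(Y)
  qx <- qr(X)
  p <- qx$rank
  if (warn_collinear && p < ncol(X)) {
    warning("collinear predictors: rank ", p, " < ", ncol(X),
            "; pseudo-inverse projection used")
  }
  fitted <- qr.fitted(qx, Y)
  tot <- sum(Y^2)
  r2 <- if (tot == 0) NA_real_ else sum(fitted^2) / tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  pc <- stats::prcomp(fitted, center = FALSE)
  av <- pc$sdev^2
  structure(list(r2 = r2, adj_r2 = adj, rank = p, n = n,
                 site_scores = pc$x,
                 axis_variance = if (sum(av) > 0) av / sum(av) else av,
                 fitted = fitted, residuals = Y - fitted),
            class = "rda_result")
}

#' Partial redundancy analysis and variance partitioning
#'
#' Residualises both the response and the focal predictors on the
#' conditioning set `Z` before fitting, giving the unique adjusted
#' contribution of `X`; the full partition reports `unique_X`, `unique_Z`
#' and their common fraction, which by construction sum to the adjusted
#' `R^2` of the combined model.
#'
#' @param Y response matrix.
#' @param X focal predictors.
#' @param Z conditioning predictors (`NULL` for none).
#' @return list with `unique_X`, `unique_Z`, `common`, `total_adj_r2`
#'   (combined model) and the three underlying `rda_result`s
#'   (`fit_X`, `fit_Z`, `fit_XZ`).
#' @export
partial_rda <- function(Y, X, Z = NULL) {
  if (is.null(Z) || ncol(as.matrix(Z)) == 0) {
    fit <- rda_fit(Y, X, warn_collinear = FALSE)
    return(list(unique_X = fit$adj_r2, unique_Z = 0, common = 0,
                total_adj_r2 = fit$adj_r2, fit_X = fit, fit_Z = NULL,
                fit_XZ = fit))
  }
  X <- as.matrix(X); Z <- as.matrix(Z)
  fit_X <- rda_fit(Y, X, warn_collinear = FALSE)
  fit_Z <- rda_fit(Y, Z, warn_collinear = FALSE)
  fit_XZ <- rda_fit(Y, cbind(X, Z), warn_collinear = FALSE)
  unique_X <- fit_XZ$adj_r2 - fit_Z$adj_r2
  unique_Z <- fit_XZ$adj_r2 - fit_X$adj_r2
  common <- fit_XZ$adj_r2 - unique_X - unique_Z
  if (abs(unique_X) < 1e-12) unique_X <- 0
  list(unique_X = unique_X, unique_Z = unique_Z, common = common,
       total_adj_r2 = fit_XZ$adj_r2,
       fit_X = fit_X, fit_Z = fit_Z, fit_XZ = fit_XZ)
}

#' Permutation test for (partial) RDA
#'
#' Pseudo-F test: rows of the (Z-residualised) response are permuted and the
#' constrained-variance F ratio recomputed; `p = (1 + #{F_perm >= F_obs}) /
#' (n_perm + 1)`.
#'
#' @param Y response matrix.
#' @param X focal predictors.
#' @param Z optional conditioning set.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `p`, `F_obs`, `n_perm`.
#' @export
rda_permutation_test <- function(Y, X, Z = NULL, n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 99)
  Y <- scale(as.matrix(Y), scale = FALSE)
  X <- as.matrix(X)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    qz <- qr(scale(Z, scale = FALSE))
    Y <- qr.resid(qz, Y)
    X <- qr.resid(qz, scale(X, scale = FALSE))
  }
  pseudo_f <- function(Yp) {
    qx <- qr(scale(X, scale = FALSE))
    fit <- qr.fitted(qx, scale(Yp, scale = FALSE))
    ssf <- sum(fit^2)
    ssr <- max(sum(scale(Yp, scale = FALSE)^2) - ssf, 0)
    df1 <- qx$rank
    df2 <- nrow(Yp) - df1 - 1 - (if (is.null(Z)) 0 else qr(Z)$rank)
    (ssf / df1) / (ssr / max(df2, 1))
  }
  f_obs <- pseudo_f(Y)
  set.seed(seed)
  n <- nrow(Y)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    pseudo_f(Y[sample.int(n), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  list(p = p, F_obs = f_obs, n_perm = n_perm)
}

#' Forward selection with a dummy stop rule
#'
#' Greedy forward selection of predictors by gain in adjusted `R^2` of the
#' RDA of `Y`. All candidates (real variables and flagged dummies) compete
#' at every step; selection is deterministic given the data. The reported
#' `stop_index` is the number of real variables entered before the first
#' step at which a dummy ranks best, i.e. how many variables survive the
#' "stop at the first dummy" rule.
#'
#' @param Y response matrix.
#' @param candidates data frame/matrix of candidate predictors.
#' @param is_dummy logical per candidate column.
#' @param max_steps cap on selection length (default all candidates).
#' @return list with `order` (selected names until gain stops being
#'   positive), `gains`, `stop_index`, `selected` (real variables before the
#'   first dummy).
#' @export
forward_select <- function(Y, candidates, is_dummy,
                           max_steps = ncol(candidates)) {
  cand <- as.matrix(candidates)
  stopifnot(length(is_dummy) == ncol(cand))
  nm <- colnames(cand)
  chosen <- integer(0)
  gains <- numeric(0)
  current_adj <- 0
  stop_index <- NA_integer_
  for (step in seq_len(max_steps)) {
    remaining <- setdiff(seq_len(ncol(cand)), chosen)
    if (length(remaining) == 0) break
    adj <- vapply(remaining, function(j) {
      rda_fit(Y, cand[, c(chosen, j), drop = FALSE],
              warn_collinear = FALSE)$adj_r2
    }, numeric(1))
    best <- remaining[which.max(adj)]
    gain <- max(adj) - current_adj
    if (is.na(stop_index) && is_dummy[best]) {
      stop_index <- length(chosen)
    }
    if (gain <= 0) break
    chosen <- c(chosen, best)
    gains <- c(gains, gain)
    current_adj <- max(adj)
  }
  if (is.na(stop_index)) stop_index <- sum(!is_dummy[chosen])
  list(order = nm[chosen], gains = gains, stop_index = stop_index,
       selected = nm[utils::head(chosen, stop_index)])
}
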