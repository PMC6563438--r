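#' Semivariogram model
#'
#' A parametric semivariogram `gamma(h) = nugget + psill * g(h / range)` with
#' `g` the spherical, exponential or gaussian correlation complement. Used
#' both to control the smoothness of simulated random fields and as the
#' target of empirical fits.
#'
#' @param model_type one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget non-negative nugget variance.
#' @param psill non-negative partial sill.
#' @param range range parameter (km), > 0.
#' @return object of class `semivariogram_model`.
#' @export
semivariogram_model <- function(model_type = c("gaussian", "exponential", "spherical"),
                                nugget = 0, psill = 1, range = 50) {
  model_type <- match.arg(model_type)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(model_type = model_type, nugget = nugget,
                 psill = psill, range = range),
            class = "semivariogram_model")
}

# semivariogram value at lag h (h = 0 gives 0; the nugget is the h -> 0+ limit)
sv_gamma <- function(model, h) {
  g <- switch(model$model_type,
    exponential = 1 - exp(-h / model$range),
    gaussian = 1 - exp(-(h / model$range)^2),
    spherical = ifelse(h >= model$range, 1,
                       1.5 * h / model$range - 0.5 * (h / model$range)^3))
  out <- model$nugget + model$psill * g
  out[h == 0] <- 0
  out
}

# covariance function implied by the semivariogram (sill - gamma)
sv_cov <- function(model, h) {
  sill <- model$nugget + model$psill
  ifelse(h == 0, sill, sill - sv_gamma(model, h))
}

#' Regular grid specification
#'
#' @param nrow,ncol grid dimensions.
#' @param cell_km cell size (km).
#' @param origin coordinates (km) of the first cell centre.
#' @return data frame of cell centres with columns `x`, `y` (km).
#' @export
make_grid <- function(nrow, ncol, cell_km = 5, origin = c(0, 0)) {
  stopifnot(nrow >= 1, ncol >= 1, cell_km > 0)
  expand.grid(x = origin[1] + (seq_len(ncol) - 1) * cell_km,
              y = origin[2] + (seq_len(nrow) - 1) * cell_km)
}

#' Unconditional Gaussian simulation of a random field
#'
#' Simulates one zero-mean Gaussian field on the grid whose covariance is
#' implied by the semivariogram model (sill minus semivariance), by Cholesky
#' factorisation of the dense grid covariance. The field is standardised to
#' unit variance in expectation; seeded and reproducible.
#'
#' @param grid data frame of cell centres (`x`, `y`, km), e.g. [make_grid()].
#' @param model a [semivariogram_model()].
#' @param seed integer seed.
#' @return list with `grid`, `values` (one per cell) and `seed`.
#' @export
simulate_field <- function(grid, model, seed = 1L) {
  stopifnot(nrow(grid) >= 4)
  d <- as.matrix(stats::dist(grid[, c("x", "y")]))
  sigma <- sv_cov(model, d)
  sill <- model$nugget + model$psill
  if (sill <= 0) stop("model implies zero total variance")
  ch <- tryCatch(chol(sigma + diag(1e-8 * sill, nrow(sigma))),
                 error = function(e) stop("implied covariance is not positive semi-definite"))
  set.seed(seed)
  z <- as.vector(crossprod(ch, stats::rnorm(nrow(sigma)))) / sqrt(sill)
  list(grid = grid, values = z, seed = seed)
}

#' Empirical semivariogram and weighted least-squares model fit
#'
#' Bins squared half-differences of all point pairs by lag distance and fits
#' the chosen model family by weighted least squares (Cressie weights,
#' pair counts over squared model value). Degenerate all-equal inputs return
#' a zero-sill model with a warning.
#'
#' @param values numeric vector of observations.
#' @param coords two-column matrix/data frame of coordinates (km).
#' @param model_type model family to fit.
#' @param n_bins number of lag bins up to half the maximum distance.
#' @return a [semivariogram_model()] with an `empirical` attribute
#'   (data frame of lag, gamma, n pairs).
#' @export
fit_semivariogram <- function(values, coords,
                              model_type = c("gaussian", "exponential", "spherical"),
                              n_bins = 15L) {
  model_type <- match.arg(model_type)
  stopifnot(length(values) >= 30)
  if (stats::sd(values) == 0) {
    warning("all values equal; degenerate semivariogram")
    out <- semivariogram_model(model_type, nugget = 0, psill = 0, range = 1)
    attr(out, "empirical") <- data.frame(lag = numeric(0), gamma = numeric(0),
                                         n = integer(0))
    return(out)
  }
  d <- as.matrix(stats::dist(coords))
  g <- 0.5 * outer(values, values, "-")^2
  iu <- upper.tri(d)
  dd <- d[iu]; gg <- g[iu]
  hmax <- max(dd) / 2
  keep <- dd > 0 & dd <= hmax
  dd <- dd[keep]; gg <- gg[keep]
  bins <- cut(dd, breaks = seq(0, hmax, length.out = n_bins + 1L),
              include.lowest = TRUE)
  emp <- data.frame(
    lag = as.numeric(tapply(dd, bins, mean)),
    gamma = as.numeric(tapply(gg, bins, mean)),
    n = as.integer(table(bins))
  )
  emp <- emp[emp$n > 0 & !is.na(emp$gamma), ]
  svar <- stats::var(values)
  obj <- function(par) {
    # optimizer may probe epsilon outside the box; clamp before validating
    m <- semivariogram_model(model_type, nugget = max(par[1], 0),
                             psill = max(par[2], 1e-8),
                             range = max(par[3], 1e-3))
    fit <- sv_gamma(m, emp$lag)
    sum(emp$n * (emp$gamma - fit)^2 / pmax(fit, 1e-8)^2)
  }
  init <- c(nugget = 0.1 * svar, psill = 0.9 * svar, range = hmax / 3)
  opt <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-8, 1e-3),
                      upper = c(2 * svar, 4 * svar, 4 * hmax))
  out <- semivariogram_model(model_type, nugget = opt$par[1],
                             psill = opt$par[2], range = opt$par[3])
  attr(out, "empirical") <- emp
  out
}

#' Spatially correlated dummy variables at sites
#'
#' Simulates `n` mutually independent (by seed) spatially correlated random
#' fields on the grid and extracts their values at the sites by nearest-cell
#' lookup; each column is then standardised. These dummies carry realistic
#' spatial autocorrelation but no true relationship to any genotype, so they
#' provide an empirical null for association statistics.
#'
#' @param n number of dummy variables (default 12).
#' @param grid cell-centre data frame (`x`, `y`).
#' @param model a [semivariogram_model()].
#' @param sites data frame with site coordinates `x`, `y` (km, same
#'   projection as the grid).
#' @param seed base seed; field `i` uses `seed + i`.
#' @return numeric matrix, sites x dummies, columns `dummy01`, `dummy02`, ...
#' @export
make_dummies <- function(n = 12L, grid, model, sites, seed = 1L) {
  stopifnot(n >= 1, all(c("x", "y") %in% names(sites)))
  gx <- grid$x; gy <- grid$y
  outside <- sites$x < min(gx) | sites$x > max(gx) |
             sites$y < min(gy) | sites$y > max(gy)
  if (any(outside)) {
    warning(sum(outside), " site(s) outside the grid bounding box; ",
            "nearest cell used")
  }
  nearest <- vapply(seq_len(nrow(sites)), function(i) {
    which.min((gx - sites$x[i])^2 + (gy - sites$y[i])^2)
  }, integer(1))
  cols <- vapply(seq_len(n), function(i) {
    f <- simulate_field(grid, model, seed = seed + i)
    v <- f$values[nearest]
    as.vector(scale(v))
  }, numeric(nrow(sites)))
  colnames(cols) <- sprintf("dummy%02d", seq_len(n))
  rownames(cols) <- if (!is.null(sites$id)) as.character(sites$id) else NULL
  cols
}
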