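# shared, lazily built fixtures (cached per test session)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# constant-temperature daily series over full calendar years
make_const_series <- function(tmin, tmax, years = 2, start = 2001,
                              pcp = 1, et0 = 0.5) {
  dates <- seq(as.Date(sprintf("%d-01-01", start)),
               as.Date(sprintf("%d-12-31", start + years - 1)), by = "day")
  data.frame(date = dates, tmin = tmin, tmax = tmax, pcp = pcp, et0 = et0)
}

# 30-year series whose last frost day-of-year per year is prescribed
make_frost_series <- function(last_frost_doy, start = 1981) {
  years <- seq(start, length.out = length(last_frost_doy))
  out <- lapply(seq_along(years), function(i) {
    dates <- seq(as.Date(sprintf("%d-01-01", years[i])),
                 as.Date(sprintf("%d-12-31", years[i])), by = "day")
    doy <- as.integer(format(dates, "%j"))
    tmin <- rep(5, length(dates))
    if (last_frost_doy[i] > 0) tmin[doy == last_frost_doy[i]] <- -2
    data.frame(date = dates, tmin = tmin, tmax = tmin + 10, pcp = 0, et0 = 1)
  })
  do.call(rbind, out)
}

small_bn_sim <- function() {
  cached("bn_small", gen_structured_genotypes(
    60, 400, c(30L, 30L), 0.3, missing_rate = 0.05, seed = 42))
}

fixture_fast <- function() {
  cached("fx_fast", end_to_end_fixture(seed = 11, n_acc = 80L,
                                       n_loci = 600L, n_causal = 10L,
                                       with_weather = FALSE))
}

# full-size fixture plus the standard association preprocessing, shared by
# the acceptance blocks
fixture_assoc_full <- function() {
  cached("assoc_full", {
    fx <- end_to_end_fixture(seed = 31)
    G <- impute_knn(maf_filter(filter_missing(fx$sim$G, 0.10), 0.05))
    map <- fx$sim$map[fx$sim$map$id %in% colnames(G), ]
    shortlist <- shortlist_nonredundant(G, map)
    omega <- estimate_omega(G[, shortlist, drop = FALSE], rownames(G),
                            seed = 31)$omega
    list(fx = fx, G = G, map = map, shortlist = shortlist, omega = omega)
  })
}

fixture_weather_small <- function() {
  cached("fx_weather", end_to_end_fixture(seed = 21, n_acc = 60L,
                                          n_loci = 400L, n_causal = 8L,
                                          n_years = 12L, grid_dim = 4L))
}
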