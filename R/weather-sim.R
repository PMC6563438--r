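#' Weather generator parameters
#'
#' Parameters of the minimal daily-weather model used for synthetic inputs:
#' seasonal sinusoids for mean temperature and thermal amplitude with AR(1)
#' Gaussian anomalies, an altitude lapse rate and a latitudinal gradient;
#' Bernoulli-gamma daily precipitation with per-month occurrence
#' probabilities; and a smooth non-negative seasonal curve for reference
#' evapotranspiration.
#'
#' @param n_years number of simulated years (>= 2).
#' @param tmed_mean,tmed_amplitude annual mean and seasonal amplitude of the
#'   daily mean temperature at reference altitude/latitude (degC).
#' @param tamp_mean,tamp_amplitude mean and seasonal amplitude of the diurnal
#'   temperature range (degC); the range is floored at 0 degC.
#' @param lapse_rate temperature decrease per km of altitude (degC/km).
#' @param lat_gradient temperature decrease per 100 km of northing (degC).
#' @param noise_sd standard deviation of daily temperature anomalies (degC).
#' @param ar1 AR(1) coefficient of the anomaly series, in \[0, 1).
#' @param precip_prob per-month probability of a wet day (length 12 or 1).
#' @param precip_shape,precip_scale gamma parameters of wet-day amounts (mm).
#' @param et0_mean,et0_amplitude mean and seasonal amplitude of daily
#'   reference evapotranspiration (mm/day).
#' @return list of validated parameters (class `weather_params`).
#' @export
weather_params <- function(n_years = 15L,
                           tmed_mean = 12, tmed_amplitude = 8,
                           tamp_mean = 10, tamp_amplitude = 3,
                           lapse_rate = 6.5, lat_gradient = 0.8,
                           noise_sd = 2.5, ar1 = 0.7,
                           precip_prob = c(0.30, 0.28, 0.27, 0.30, 0.26, 0.15,
                                           0.08, 0.08, 0.18, 0.30, 0.32, 0.32),
                           precip_shape = 0.7, precip_scale = 8,
                           et0_mean = 2.8, et0_amplitude = 2.2) {
  if (n_years < 2) stop("n_years must be >= 2")
  if (length(precip_prob) == 1) precip_prob <- rep(precip_prob, 12)
  stopifnot(length(precip_prob) == 12, all(precip_prob >= 0 & precip_prob <= 1),
            precip_shape > 0, precip_scale > 0, ar1 >= 0, ar1 < 1,
            noise_sd >= 0, tamp_mean >= 0, et0_mean >= et0_amplitude)
  structure(as.list(environment()), class = "weather_params")
}

#' Generate daily weather series for a set of sites
#'
#' Simulates a complete daily calendar of minimum/maximum temperature,
#' precipitation and reference evapotranspiration per site. Temperature is a
#' seasonal sinusoid (coldest mid-January) plus a shared-seed AR(1) anomaly,
#' shifted down by `lapse_rate` per km of altitude and by `lat_gradient` per
#' 100 km of northing; `tmax >= tmin` holds by construction (mean +/- half
#' the positive diurnal range). Precipitation is Bernoulli-gamma with monthly
#' occurrence; ET0 is a smooth seasonal curve, never negative.
#'
#' @param params a [weather_params()].
#' @param sites data frame with `id`, `y` (northing, km) and `alt` (m).
#' @param seed integer seed; equal seeds give bit-identical output.
#' @param start_year first calendar year (default 1991).
#' @return named list (one element per site) of daily data frames with
#'   columns `date`, `tmin`, `tmax`, `pcp`, `et0`.
#' @export
gen_daily_weather <- function(params, sites, seed = 1L, start_year = 1991L) {
  stopifnot(inherits(params, "weather_params"), nrow(sites) >= 1,
            all(c("id", "y", "alt") %in% names(sites)))
  dates <- seq(as.Date(sprintf("%04d-01-01", start_year)),
               as.Date(sprintf("%04d-12-31", start_year + params$n_years - 1L)),
               by = "day")
  doy <- as.integer(format(dates, "%j"))
  mon <- as.integer(format(dates, "%m"))
  nd <- length(dates)
  seas <- -cos(2 * pi * (doy - 15) / 365.25)   # coldest around Jan 15
  set.seed(seed)
  out <- vector("list", nrow(sites))
  names(out) <- as.character(sites$id)
  for (s in seq_len(nrow(sites))) {
    base <- params$tmed_mean + params$tmed_amplitude * seas -
      params$lapse_rate * sites$alt[s] / 1000 -
      params$lat_gradient * sites$y[s] / 100
    if (params$noise_sd > 0) {
      innov <- stats::rnorm(nd, 0, params$noise_sd * sqrt(1 - params$ar1^2))
      anom <- as.numeric(stats::filter(innov, params$ar1, method = "recursive"))
    } else {
      anom <- numeric(nd)
    }
    tmed <- base + anom
    # diurnal range: seasonal + a site continentality offset + daily noise
    site_tamp <- stats::rnorm(1, 0, 1)
    tamp <- pmax(params$tamp_mean + params$tamp_amplitude * seas + site_tamp +
                   stats::rnorm(nd, 0, params$noise_sd / 3), 0)
    if (params$tamp_mean == 0 && params$tamp_amplitude == 0) tamp <- 0
    wet <- stats::rbinom(nd, 1, params$precip_prob[mon])
    amt <- stats::rgamma(nd, shape = params$precip_shape,
                         scale = params$precip_scale)
    # atmospheric demand follows the site's temperature course
    et0 <- pmax(params$et0_mean + params$et0_amplitude * (-seas) +
                  0.06 * (tmed - params$tmed_mean), 0)
    out[[s]] <- data.frame(
      date = dates,
      tmin = tmed - tamp / 2,
      tmax = tmed + tamp / 2,
      pcp = wet * amt,
      et0 = et0
    )
  }
  out
}
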