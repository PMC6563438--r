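#' Vernalization effectiveness of a temperature
#'
#' Piecewise-linear response of winter-cereal vernalization to temperature:
#' ineffective at or below 0 degC, rising linearly to full effectiveness at
#' 4 degC, fully effective on the 4--8 degC plateau, declining linearly
#' between 8 and 15 degC, and ineffective at or above 15 degC.
#'
#' @param temp numeric vector of temperatures (degC).
#' @return numeric vector of effectiveness fractions in \[0, 1\].
#' @examples
#' vern_effectiveness(c(-3, 0, 2, 4, 8, 11.5, 15, 20))
#' @export
vern_effectiveness <- function(temp) {
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  eff <- numeric(length(temp))
  ramp_up <- temp > 0 & temp < 4
  eff[ramp_up] <- temp[ramp_up] / 4
  eff[temp >= 4 & temp <= 8] <- 1
  ramp_down <- temp > 8 & temp < 15
  eff[ramp_down] <- (15 - temp[ramp_down]) / 7
  eff
}

#' Within-day temperature samples on a sine curve
#'
#' Interpolates the daily temperature course between the minimum and maximum
#' as a sine wave, `T(h) = (tmax+tmin)/2 + (tmax-tmin)/2 * sin(2*pi*h/24 - pi/2)`,
#' sampled at `n_steps` equally spaced hours starting at h = 0 (the minimum).
#' The mean of a full cycle of samples equals `(tmin+tmax)/2` exactly.
#'
#' @param tmin,tmax daily minimum and maximum temperature (degC); `tmax >= tmin`.
#' @param n_steps number of equally spaced samples over the 24 h cycle.
#' @return numeric vector of `n_steps` temperatures in `[tmin, tmax]`.
#' @export
diurnal_sine <- function(tmin, tmax, n_steps = 24L) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  stopifnot(n_steps >= 1)
  h <- seq(0, 24, length.out = n_steps + 1L)[-(n_steps + 1L)]
  mid <- (tmax + tmin) / 2
  amp <- (tmax - tmin) / 2
  mid + amp * sin(2 * pi * h / 24 - pi / 2)
}

#' Daily vernalization fraction
#'
#' Fraction of a vernalization day contributed by one calendar day: the mean
#' vernalization effectiveness over the diurnal sine curve between `tmin`
#' and `tmax`. Vectorized over days.
#'
#' @inheritParams diurnal_sine
#' @param n_steps samples per day used for the diurnal curve (default 96,
#'   i.e. 15-minute resolution, which keeps the quadrature error of the mean
#'   effectiveness below about 3e-4).
#' @return numeric vector of daily vernalization fractions in \[0, 1\].
#' @export
daily_vernalization <- function(tmin, tmax, n_steps = 96L) {
  if (length(tmax) != length(tmin)) stop("tmin and tmax must have equal length")
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  h <- seq(0, 24, length.out = n_steps + 1L)[-(n_steps + 1L)]
  s <- sin(2 * pi * h / 24 - pi / 2)
  # days x steps matrix of within-day temperatures
  tm <- outer((tmax + tmin) / 2, rep(1, n_steps)) +
    outer((tmax - tmin) / 2, s)
  rowMeans(matrix(vern_effectiveness(as.vector(tm)), nrow = length(tmin)))
}

#' Days from sowing to accumulate N vernalization days
#'
#' For each season-year in a daily series, counts the days from the sowing
#' date (inclusive) until the cumulative daily vernalization reaches `n_vdays`,
#' and averages the count over years. Accumulation only starts after the
#' imbibition lag (default 5 days after a 15 November sowing), but the
#' reported day count runs from the sowing date itself.
#'
#' Season-years in which the target is never reached before the window end
#' (30 June by default) are dropped with a warning; if no year reaches the
#' target, `NA` is returned.
#'
#' @param series a daily climate data frame with `date`, `tmin`, `tmax`
#'   columns (complete calendar).
#' @param n_vdays target number of vernalization days; the catalogue uses
#'   10, 20, 30, 40 (other values are allowed with a warning).
#' @param spec a [season_spec()] providing the sowing date and imbibition lag.
#' @return mean number of days since sowing (scalar).
#' @export
verna_nd <- function(series, n_vdays, spec = season_spec()) {
  stopifnot(is.data.frame(series), all(c("date", "tmin", "tmax") %in% names(series)))
  if (!n_vdays %in% c(10, 20, 30, 40)) {
    warning("n_vdays outside the standard {10,20,30,40} catalogue set")
  }
  vd <- daily_vernalization(series$tmin, series$tmax)
  dates <- as.Date(series$date)
  yrs <- as.integer(format(dates, "%Y"))
  seasons <- sort(unique(yrs))
  # keep only season-years whose full sowing -> 30 June window is covered
  seasons <- seasons[vapply(seasons, function(y) {
    sow <- as.Date(sprintf("%04d-%02d-%02d", y, spec$sowing_month, spec$sowing_day))
    end <- as.Date(sprintf("%04d-06-30", y + 1L))
    min(dates) <= sow && max(dates) >= end
  }, logical(1))]
  if (length(seasons) == 0) stop("series does not span a full sowing-to-June window")
  per_year <- vapply(seasons, function(y) {
    sow <- as.Date(sprintf("%04d-%02d-%02d", y, spec$sowing_month, spec$sowing_day))
    start <- sow + spec$imbibition_days
    end <- as.Date(sprintf("%04d-06-30", y + 1L))
    idx <- which(dates >= start & dates <= end)
    cum <- cumsum(vd[idx])
    k <- which(cum >= n_vdays)[1]
    if (is.na(k)) return(NA_real_)
    # day count since sowing, inclusive of sowing day and imbibition days
    as.numeric(dates[idx[k]] - sow) + 1
  }, numeric(1))
  if (all(is.na(per_year))) {
    warning("vernalization target never reached in any season-year")
    return(NA_real_)
  }
  if (anyNA(per_year)) {
    warning(sum(is.na(per_year)), " season-year(s) never reached the target; excluded")
  }
  mean(per_year, na.rm = TRUE)
}
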