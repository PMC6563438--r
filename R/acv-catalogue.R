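MONTH_ABB <- c("jan", "feb", "mar", "apr", "may", "jun",
               "jul", "aug", "sep", "oct", "nov", "dec")

#' Season specification for the agroclimatic catalogue
#'
#' Defines the month sets used for seasonal aggregation, the sowing date and
#' the imbibition lag. Defaults: winter = DJF, autumn = SON, spring = MAM,
#' summer = JJA; sowing 15 November; 5 imbibition days. A two-month spring
#' (March--April) can be configured via `spr`.
#'
#' @param spr,aut,win,summer integer month vectors (1--12).
#' @param sowing_month,sowing_day sowing date components.
#' @param imbibition_days days between sowing and the start of vernalization
#'   accumulation (seed imbibition; vernalization acts on active tissue).
#' @return an object of class `season_spec`.
#' @export
season_spec <- function(spr = 3:5, aut = 9:11, win = c(12, 1, 2),
                        summer = 6:8, sowing_month = 11L, sowing_day = 15L,
                        imbibition_days = 5L) {
  stopifnot(all(c(spr, aut, win, summer) %in% 1:12),
            sowing_month %in% 1:12, sowing_day %in% 1:31,
            imbibition_days >= 0)
  structure(list(spr = as.integer(spr), aut = as.integer(aut),
                 win = as.integer(win), summer = as.integer(summer),
                 sowing_month = as.integer(sowing_month),
                 sowing_day = as.integer(sowing_day),
                 imbibition_days = as.integer(imbibition_days)),
            class = "season_spec")
}

#' Late-frost probability day (pfrost)
#'
#' First day of the year at which the probability of a later minimum
#' temperature below 0 degC drops to `prob` or less. With the default
#' return-period reading, `q(d)` is the fraction of years having at least one
#' frost day on or after day-of-year `d` (within the search window), and the
#' result is the smallest `d` with `q(d) <= prob`; `prob = 0.10` corresponds
#' to a one-in-ten-year return period. The pointwise alternative thresholds
#' the per-day frost frequency instead.
#'
#' @param series daily data frame with `date` and `tmin` (multi-year).
#' @param prob probability threshold (default 0.10).
#' @param window day-of-year search window, default Jan 1 -- Jun 30.
#' @param min_years minimum number of years required (default 10).
#' @param method `"return_period"` (default) or `"pointwise"`.
#' @return day-of-year (integer).
#' @export
pfrost <- function(series, prob = 0.10, window = c(1L, 181L),
                   min_years = 10L, method = c("return_period", "pointwise")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(series), all(c("date", "tmin") %in% names(series)))
  if (window[1] > window[2]) stop("empty search window")
  dates <- as.Date(series$date)
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  in_win <- doy >= window[1] & doy <= window[2]
  years <- sort(unique(yr[in_win]))
  if (length(years) < min_years) {
    stop("need at least ", min_years, " years of data for pfrost")
  }
  frost <- series$tmin < 0 & in_win
  if (method == "return_period") {
    # last frost day-of-year per year (0 when frost-free)
    lf <- vapply(years, function(y) {
      d <- doy[frost & yr == y]
      if (length(d) == 0) 0L else max(d)
    }, integer(1))
    cand <- sort(unique(c(window[1], lf + 1L)))
    cand <- cand[cand >= window[1]]
    for (d in cand) {
      if (mean(lf >= d) <= prob) return(as.integer(d))
    }
    as.integer(max(lf) + 1L)
  } else {
    for (d in window[1]:window[2]) {
      on_day <- frost & doy == d
      if (mean(vapply(years, function(y) any(on_day[yr == y]), logical(1))) <= prob) {
        return(as.integer(d))
      }
    }
    as.integer(window[2] + 1L)
  }
}

# per-(year, month) aggregates for one site's daily series
month_year_table <- function(series) {
  dates <- as.Date(series$date)
  key <- format(dates, "%Y-%m")
  mon <- as.integer(format(dates, "%m"))
  vd <- daily_vernalization(series$tmin, series$tmax)
  agg <- function(x, f) as.numeric(tapply(x, key, f))
  tab <- data.frame(
    key = sort(unique(key)),
    month = as.integer(tapply(mon, key, function(m) m[1])),
    pcp = agg(series$pcp, sum),
    tmed = agg((series$tmin + series$tmax) / 2, mean),
    tmax = agg(series$tmax, mean),
    tmin = agg(series$tmin, mean),
    tamp = agg(series$tmax - series$tmin, mean),
    frost = agg(series$tmin < 0, sum),
    verna = as.numeric(tapply(vd, key, sum)),
    ET_0 = agg(series$et0, sum)
  )
  tab$bal <- tab$pcp - tab$ET_0
  tab
}

ACV_SUM_FAMILIES <- c("pcp", "frost", "verna", "ET_0", "bal")
ACV_MEAN_FAMILIES <- c("tmed", "tmax", "tmin", "tamp")

# monthly climatology (mean across years of per-month values)
monthly_climatology <- function(myt, variable) {
  vapply(1:12, function(m) {
    v <- myt[[variable]][myt$month == m]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

#' Aggregate a daily series into one agroclimatic value
#'
#' Computes the climatological aggregate of one variable family over a month,
#' a season or the year: totals (precipitation, reference evapotranspiration,
#' potential vernalization days, frost-day counts, water balance) are summed
#' within the period and averaged across years; temperatures and thermal
#' amplitude are averaged. `bal` is cumulative `pcp` minus cumulative `et0`.
#'
#' @param series daily data frame with `date`, `tmin`, `tmax`, `pcp`, `et0`.
#' @param variable one of `pcp`, `tmed`, `tmax`, `tmin`, `tamp`, `frost`,
#'   `verna`, `ET_0`, `bal`.
#' @param period an integer month (1--12), a month abbreviation (`"jan"`),
#'   a season name (`"spr"`, `"aut"`, `"win"`, `"summer"`) or `"annual"`.
#' @param spec a [season_spec()].
#' @return scalar aggregate value.
#' @export
aggregate_acv <- function(series, variable, period, spec = season_spec()) {
  variable <- match.arg(variable, c(ACV_SUM_FAMILIES, ACV_MEAN_FAMILIES))
  myt <- month_year_table(series)
  months <- resolve_period(period, spec)
  clim <- monthly_climatology(myt, variable)[months]
  if (anyNA(clim)) stop("period not covered by the series")
  if (variable %in% ACV_SUM_FAMILIES) {
    sum(clim)
  } else {
    # day-weighted mean of monthly means
    w <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[months]
    sum(clim * w) / sum(w)
  }
}

resolve_period <- function(period, spec) {
  if (is.numeric(period)) {
    if (!all(period %in% 1:12)) stop("unknown month index")
    return(as.integer(period))
  }
  if (period %in% MONTH_ABB) return(match(period, MONTH_ABB))
  if (period == "annual") return(1:12)
  if (period %in% c("spr", "aut", "win", "summer")) return(spec[[period]])
  stop("unknown period: ", period)
}

#' Build the agroclimatic variable catalogue
#'
#' Computes, for every site, the full catalogue of named agroclimatic
#' variables from its daily series: monthly and seasonal precipitation, mean /
#' maximum / minimum temperature, thermal amplitude and frost days (6 families
#' x 16 periods); monthly potential vernalization (12); days to reach 10, 20,
#' 30 and 40 vernalization days (4); the late-frost probability day (1); and
#' monthly, seasonal and annual reference evapotranspiration and climatic
#' water balance (17 each) -- 147 variables in total, plus the geographic
#' columns `lon`, `lat`, `alt` when a site table is supplied.
#'
#' @param series_list named list of daily climate data frames, one per site.
#' @param spec a [season_spec()].
#' @param sites optional data frame with `id`, `lon`, `lat`, `alt`.
#' @param pfrost_min_years minimum years required by [pfrost()].
#' @return an `acv_catalogue`: a data frame of sites x variables with
#'   attribute `agroclimatic` naming the 147 non-geographic columns.
#' @export
build_catalogue <- function(series_list, spec = season_spec(), sites = NULL,
                            pfrost_min_years = 10L) {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  nd <- vapply(series_list, nrow, integer(1))
  if (length(unique(nd)) != 1) stop("sites must share the climatology period")
  seasons <- c("spr", "aut", "win", "summer")
  one_site <- function(series) {
    myt <- month_year_table(series)
    out <- numeric(0)
    for (fam in c("pcp", "tmed", "tmax", "tmin", "tamp", "frost")) {
      clim <- monthly_climatology(myt, fam)
      v <- vapply(c(as.list(1:12), as.list(seasons)), function(p)
        aggregate_one(clim, fam, resolve_period(p, spec)), numeric(1))
      names(v) <- paste0(fam, "_", c(MONTH_ABB, seasons))
      out <- c(out, v)
    }
    verna_clim <- monthly_climatology(myt, "verna")
    v <- verna_clim
    names(v) <- paste0("verna_", MONTH_ABB)
    out <- c(out, v)
    vn <- vapply(c(10, 20, 30, 40), function(n)
      suppressWarnings(verna_nd(series, n, spec)), numeric(1))
    names(vn) <- paste0("verna_", c(10, 20, 30, 40), "d")
    out <- c(out, vn)
    out <- c(out, pfrost = pfrost(series, min_years = pfrost_min_years))
    for (fam in c("ET_0", "bal")) {
      clim <- monthly_climatology(myt, fam)
      v <- vapply(c(as.list(1:12), as.list(seasons), list("annual")), function(p)
        aggregate_one(clim, fam, resolve_period(p, spec)), numeric(1))
      names(v) <- paste0(fam, "_", c(MONTH_ABB, seasons, "annual"))
      out <- c(out, v)
    }
    out
  }
  mat <- t(vapply(series_list, one_site, one_site(series_list[[1]])))
  cat_names <- colnames(mat)
  df <- as.data.frame(mat)
  df <- cbind(site = names(series_list), df)
  if (!is.null(sites)) {
    idx <- match(names(series_list), sites$id)
    if (anyNA(idx)) stop("site table is missing some series sites")
    df$lon <- sites$lon[idx]
    df$lat <- sites$lat[idx]
    df$alt <- sites$alt[idx]
  }
  structure(df, agroclimatic = cat_names, class = c("acv_catalogue", "data.frame"))
}

aggregate_one <- function(clim, fam, months) {
  x <- clim[months]
  if (fam %in% ACV_SUM_FAMILIES) {
    sum(x)
  } else {
    w <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[months]
    sum(x * w) / sum(w)
  }
}

#' Analysis subset of a catalogue
#'
#' Drops summer aggregates and the July--October months, which have no
#' bearing on an autumn-sown winter cereal, keeping geographic columns.
#'
#' @param catalogue an `acv_catalogue` from [build_catalogue()].
#' @return the filtered catalogue (same class).
#' @export
analysis_subset <- function(catalogue) {
  acv <- attr(catalogue, "agroclimatic")
  drop <- grepl("_(jul|aug|sep|oct|summer)$", acv)
  keep_cols <- setdiff(names(catalogue), acv[drop])
  out <- catalogue[, keep_cols, drop = FALSE]
  structure(out, agroclimatic = acv[!drop],
            class = c("acv_catalogue", "data.frame"))
}

#' Multi-month composite variables
#'
#' Builds named composites from monthly catalogue columns using the family
#' aggregation rule: totals are summed across the constituent months
#' (e.g. `pcp_mar_apr = pcp_mar + pcp_apr`), temperature-family composites are
#' averaged.
#'
#' @param catalogue an `acv_catalogue`.
#' @param groups named list; each element a character vector of catalogue
#'   column names sharing one family prefix.
#' @return data frame of composite columns (one row per site).
#' @export
acv_composites <- function(catalogue, groups) {
  out <- lapply(names(groups), function(nm) {
    cols <- groups[[nm]]
    if (!all(cols %in% names(catalogue))) {
      stop("unknown catalogue columns in composite ", nm)
    }
    fam <- sub("_.*$", "", cols[1])
    if (fam == "ET") fam <- "ET_0"
    m <- as.matrix(catalogue[, cols, drop = FALSE])
    if (fam %in% ACV_SUM_FAMILIES) rowSums(m) else rowMeans(m)
  })
  names(out) <- names(groups)
  as.data.frame(out, row.names = catalogue$site)
}

#' Default 20-variable selection
#'
#' The representative, least-redundant variable set used downstream: three
#' geographic variables plus 17 agroclimatic variables (including the
#' multi-month composites) matched to the growth phases of an autumn-sown
#' barley crop.
#'
#' @param catalogue an `acv_catalogue` built with a site table (so that
#'   `lon`, `lat`, `alt` are present).
#' @return data frame of 20 columns, rownames = sites.
#' @export
acv_default_selection <- function(catalogue) {
  comp <- acv_composites(catalogue, list(
    pcp_mar_apr = c("pcp_mar", "pcp_apr"),
    pcp_may_jun = c("pcp_may", "pcp_jun"),
    bal_mar_apr_may = c("bal_mar", "bal_apr", "bal_may"),
    verna_jan_feb = c("verna_jan", "verna_feb"),
    verna_mar_apr = c("verna_mar", "verna_apr"),
    frost_jan_feb = c("frost_jan", "frost_feb"),
    frost_apr_may = c("frost_apr", "frost_may")
  ))
  singles <- c("lon", "lat", "alt", "pcp_aut", "pcp_win", "ET_0_spr",
               "bal_aut", "bal_win", "bal_jun", "tamp_win", "tamp_spr",
               "verna_30d", "pfrost")
  if (!all(singles %in% names(catalogue))) {
    stop("catalogue lacks required columns (was it built with a site table?)")
  }
  out <- cbind(catalogue[, singles, drop = FALSE], comp)
  rownames(out) <- catalogue$site
  out[, c("lon", "lat", "alt", "pcp_aut", "pcp_win", "pcp_mar_apr",
          "pcp_may_jun", "ET_0_spr", "bal_aut", "bal_win", "bal_mar_apr_may",
          "bal_jun", "tamp_win", "tamp_spr", "verna_30d", "verna_jan_feb",
          "verna_mar_apr", "frost_jan_feb", "frost_apr_may", "pfrost")]
}
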