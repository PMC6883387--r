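#' Saturation vapor pressure (Tetens / FAO-56 form)
#'
#' Saturation vapor pressure of air at temperature `t`, using the Tetens
#' formulation adopted by FAO-56: `es = 0.6108 * exp(17.27 * t / (t + 237.3))`.
#'
#' @param t Air temperature in degrees Celsius. Vectorized.
#' @return Saturation vapor pressure in kPa.
#' @examples
#' saturation_vapor_pressure(0)    # 0.6108 kPa
#' saturation_vapor_pressure(25)   # ~3.17 kPa
#' @export
saturation_vapor_pressure <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric (degrees C)", call. = FALSE)
  }
  if (any(t <= -237.3)) {
    stop("`t` must exceed -237.3 degrees C", call. = FALSE)
  }
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Daily maximum vapor pressure deficit
#'
#' VPD_max is computed from the daily maximum air temperature and the daily
#' minimum relative humidity: `es(tmax) * (1 - rh_min/100)`. This is the
#' largest deficit the air reaches during the day (warmest, driest moment).
#'
#' @param tmax Daily maximum air temperature, degrees C.
#' @param rh_min Daily minimum relative humidity, percent in \[0, 100\].
#' @return VPD_max in kPa (0 when the air is saturated).
#' @examples
#' vpd_max(30, 40)   # ~2.55 kPa
#' vpd_max(25, 100)  # 0
#' @export
vpd_max <- function(tmax, rh_min) {
  if (!is.numeric(rh_min) || any(!is.finite(rh_min)) ||
      any(rh_min < 0) || any(rh_min > 100)) {
    stop("`rh_min` must be within [0, 100] percent", call. = FALSE)
  }
  saturation_vapor_pressure(tmax) * (1 - rh_min / 100)
}

#' FAO-56 Penman-Monteith daily reference evapotranspiration
#'
#' Computes grass reference evapotranspiration ET0 (mm d^-1) from one day of
#' standard station meteorology, following the FAO-56 daily formulation:
#' psychrometric constant from site altitude, actual vapor pressure from the
#' RHmax/RHmin pair, net shortwave radiation with albedo 0.23, net longwave
#' from the Stefan-Boltzmann term with the clear-sky ratio, soil heat flux
#' taken as zero at the daily step, and wind speed assumed measured at 2 m.
#'
#' @param tmax,tmin Daily max/min air temperature, degrees C.
#' @param rh_min,rh_max Daily min/max relative humidity, percent.
#' @param radiation Incoming global (solar) radiation, MJ m^-2 d^-1.
#' @param wind Mean wind speed at 2 m, m s^-1.
#' @param doy Day of year (1-366), used for extraterrestrial radiation.
#' @param latitude Site latitude, decimal degrees (negative = south).
#' @param altitude Site altitude, m above sea level.
#' @return ET0 in mm d^-1; tiny negative values (numerically possible on cold
#'   overcast days) are truncated to 0.
#' @export
reference_et0 <- function(tmax, tmin, rh_min, rh_max, radiation, wind,
                          doy, latitude, altitude) {
  if (any(is.na(radiation)) || any(is.na(wind))) {
    stop("missing covariate: `radiation` and `wind` are required for ET0 ",
         "(no default is substituted)", call. = FALSE)
  }
  stopifnot(is.finite(latitude), is.finite(altitude))
  if (any(!is.finite(tmax)) || any(!is.finite(tmin)) ||
      any(!is.finite(radiation)) || any(!is.finite(wind))) {
    stop("non-finite meteorology passed to reference_et0()", call. = FALSE)
  }

  tmean <- (tmax + tmin) / 2
  delta <- 4098 * saturation_vapor_pressure(tmean) / (tmean + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
  gamma <- 0.000665 * pressure

  es_mean <- (saturation_vapor_pressure(tmax) + saturation_vapor_pressure(tmin)) / 2
  ea <- (saturation_vapor_pressure(tmin) * rh_max +
           saturation_vapor_pressure(tmax) * rh_min) / 200

  # extraterrestrial and clear-sky radiation
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  rso <- (0.75 + 2e-5 * altitude) * ra

  rns <- (1 - 0.23) * radiation
  sigma <- 4.903e-9
  rel_rad <- ifelse(rso > 0, pmin(radiation / rso, 1), 0)
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel_rad - 0.35)
  rn <- rns - rnl

  et0 <- (0.408 * delta * rn +
            gamma * 900 / (tmean + 273) * wind * (es_mean - ea)) /
    (delta + gamma * (1 + 0.34 * wind))
  pmax(et0, 0)
}

#' Cumulative growing degree days
#'
#' Accumulates daily `max(0, (tmax + tmin)/2 - base)` over a contiguous daily
#' series, summed from `season_start` (default 1 April, around grapevine
#' budbreak in the northern hemisphere). Days before `season_start` contribute
#' nothing and carry a cumulative value of 0.
#'
#' @param dates Vector of `Date`s, contiguous and strictly increasing.
#' @param tmax,tmin Daily temperature extremes, degrees C.
#' @param base Base temperature, degrees C (default 0).
#' @param season_start `Date` from which accumulation starts, or `NULL` to use
#'   1 April of the year of the first date.
#' @return Numeric vector of cumulative GDD (degree C days), same length as
#'   `dates`, non-decreasing.
#' @export
growing_degree_days <- function(dates, tmax, tmin, base = 0,
                                season_start = NULL) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(tmax), length(tmax) == length(tmin))
  d <- as.integer(diff(dates))
  if (length(d) && any(d != 1L)) {
    gaps <- dates[which(d != 1L)]
    stop("date series has gaps after: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(season_start)) {
    season_start <- as.Date(paste0(format(dates[1], "%Y"), "-04-01"))
  }
  season_start <- as.Date(season_start)
  inc <- pmax(0, (tmax + tmin) / 2 - base)
  inc[dates < season_start] <- 0
  cumsum(inc)
}

#' Derive the climatic covariate table from daily weather
#'
#' Applies the per-day derivations used as model inputs -- day of year,
#' VPD_max, FAO-56 reference evapotranspiration, and cumulative growing degree
#' days from 1 April -- to a daily weather table.
#'
#' @param weather A weather data frame as returned by [read_weather_csv()] or
#'   [generate_weather_season()]: columns `date`, `tmax`, `tmin`, `rh_min`,
#'   `rh_max`, `radiation`, `wind`, `rain`.
#' @param latitude,altitude Site constants (decimal degrees, m).
#' @return A data frame with columns `date`, `doy`, `tmax`, `vpd_max`, `et0`,
#'   `gdd` (one row per input day, in date order).
#' @export
derive_climate_table <- function(weather, latitude, altitude) {
  weather <- validate_weather(weather)
  doy <- as.integer(format(weather$date, "%j"))
  out <- data.frame(
    date = weather$date,
    doy = doy,
    tmax = weather$tmax,
    vpd_max = vpd_max(weather$tmax, weather$rh_min),
    et0 = reference_et0(weather$tmax, weather$tmin, weather$rh_min,
                        weather$rh_max, weather$radiation, weather$wind,
                        doy, latitude, altitude),
    gdd = growing_degree_days(weather$date, weather$tmax, weather$tmin)
  )
  out$radiation <- weather$radiation
  out
}

#' Pearson correlation matrix of sampling-day climatic covariates
#'
#' Builds the symmetric Pearson correlation matrix over the climatic variables
#' of a set of (sampling) days, optionally masking entries whose correlation
#' test does not reach significance, the way such matrices are usually
#' reported.
#'
#' @param derived A derived-climate data frame ([derive_climate_table()]),
#'   subset to the sampling days of interest.
#' @param vars Character vector of columns to correlate.
#' @param mask_ns If `TRUE`, off-diagonal entries with p >= `alpha` are set to
#'   `NA` (printed as "ns").
#' @param alpha Significance level for the masking (default 0.05).
#' @return A symmetric numeric matrix with unit diagonal; attribute
#'   `"p_values"` carries the matrix of two-sided test p-values.
#' @export
climate_correlation_matrix <- function(derived,
                                       vars = c("tmax", "vpd_max", "et0",
                                                "radiation", "doy"),
                                       mask_ns = FALSE, alpha = 0.05) {
  miss <- setdiff(vars, names(derived))
  if (length(miss)) {
    stop("columns absent from `derived`: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(derived[vars])
  if (nrow(x) < 3) stop("need at least 3 sampling days", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s): ",
            paste(vars[sds == 0], collapse = ", "),
            "; correlations involving them are undefined (NA)")
  }
  r <- suppressWarnings(stats::cor(x))
  p <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (i == j || sds[i] == 0 || sds[j] == 0) next
      p[i, j] <- stats::cor.test(x[, i], x[, j])$p.value
    }
  }
  if (mask_ns) {
    r[!is.na(p) & p >= alpha] <- NA_real_
  }
  diag(r) <- ifelse(sds > 0, 1, NA_real_)
  attr(r, "p_values") <- p
  r
}
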