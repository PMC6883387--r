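#' Configuration of a synthetic field study
#'
#' Describes a two-season-style vineyard water-status campaign the way the
#' Bordeaux field design is structured: a set of plots differing in soil water
#' retention, a handful of two-consecutive-day measurement campaigns between
#' fruit set and maturity (DOY 159-257), predawn leaf water potential measured
#' in the night between the two days, and midday SWP generated from a chosen
#' "true" model plus homoscedastic Gaussian noise.
#'
#' Defaults mirror the published study conditions: 18 plots, 5 vines per plot,
#' sampling-day Tmax within 23.8-38.9 degrees C, PLWP within
#' \[-0.90, -0.01\] MPa, true model M5 with its published coefficients, and
#' SWP residual noise 0.164 MPa (the published training RMSE). The 0.02 MPa
#' PLWP noise is a modeling choice (no within-plot variance is published); it
#' keeps the 0.005 MPa matched-pair filter exercisable in both directions.
#'
#' @param seed Integer seed; mandatory, every stochastic stage derives its
#'   stream from it.
#' @param n_plots,n_vines_per_plot Design size (defaults 18 and 5).
#' @param campaigns Integer vector of day-1 DOYs; day 2 is the following day.
#'   All must lie within \[159, 256\].
#' @param year Calendar year used for dates (default 2018).
#' @param true_params `swp_params` of the generating model (default published
#'   M5).
#' @param noise_sd_swp,noise_sd_plwp Gaussian noise sds, MPa.
#' @param tmax_range Sampling-day Tmax range, degrees C.
#' @param plwp_range PLWP range, MPa (ordered, both <= 0).
#' @param missingness Fraction of observation rows dropped at random
#'   (in \[0, 1)).
#' @param soil_profiles Character vector (recycled over plots) of retention
#'   classes: `"free_draining"`, `"clayey"`, `"water_table"`.
#' @param latitude,altitude Site constants (Bordeaux-like defaults).
#' @return A list of class `swp_study_config`.
#' @export
synthetic_study_config <- function(seed,
                                   n_plots = 18L,
                                   n_vines_per_plot = 5L,
                                   campaigns = c(162L, 180L, 199L, 217L,
                                                 236L, 254L),
                                   year = 2018L,
                                   true_params = reference_params("M5"),
                                   noise_sd_swp = 0.164,
                                   noise_sd_plwp = 0.02,
                                   tmax_range = c(23.8, 38.9),
                                   plwp_range = c(-0.90, -0.01),
                                   missingness = 0,
                                   soil_profiles = c("free_draining",
                                                     "clayey",
                                                     "water_table"),
                                   latitude = 44.8,
                                   altitude = 20) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("`seed` is mandatory for a synthetic study", call. = FALSE)
  }
  if (any(diff(campaigns) <= 1)) {
    stop("`campaigns` (day-1 DOYs) must be strictly increasing with room ",
         "for day 2", call. = FALSE)
  }
  if (any(campaigns < 159L | campaigns > 256L)) {
    stop("campaign day-1 DOYs must lie within [159, 256]", call. = FALSE)
  }
  if (tmax_range[1] >= tmax_range[2]) {
    stop("`tmax_range` must be ordered min < max", call. = FALSE)
  }
  if (plwp_range[1] >= plwp_range[2] || plwp_range[2] > 0) {
    stop("`plwp_range` must be ordered and non-positive", call. = FALSE)
  }
  if (missingness < 0 || missingness >= 1) {
    stop("`missingness` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(true_params, "swp_params"))
  structure(list(
    seed = as.integer(seed),
    n_plots = as.integer(n_plots),
    n_vines_per_plot = as.integer(n_vines_per_plot),
    campaigns = as.integer(campaigns),
    year = as.integer(year),
    true_params = true_params,
    noise_sd_swp = noise_sd_swp,
    noise_sd_plwp = noise_sd_plwp,
    tmax_range = tmax_range,
    plwp_range = plwp_range,
    missingness = missingness,
    soil_profiles = rep_len(soil_profiles, n_plots),
    latitude = latitude,
    altitude = altitude
  ), class = "swp_study_config")
}

doy_to_date <- function(doy, year) as.Date(paste0(year, "-01-01")) + doy - 1

#' Generate a synthetic weather season
#'
#' Daily station weather from 1 April to 30 September: Tmax follows a
#' seasonal sinusoid peaking in mid-July plus an AR(1) daily anomaly; minimum
#' relative humidity is anticorrelated with Tmax; global radiation is a noisy
#' clearness fraction of extraterrestrial radiation (so it declines after
#' midsummer); rainfall is episodic (wet-day Bernoulli with exponential
#' amounts); wind is lognormal. On sampling days (both days of each campaign)
#' Tmax is clipped into the configured sampling range and the day-2 value
#' differs from day 1 by a ~3 degrees C contrast, mimicking the
#' changing-conditions design.
#'
#' @param config An [synthetic_study_config()].
#' @param seed Seed for this stage (default: the config seed).
#' @return A weather data frame (`date`, `tmax`, `tmin`, `rh_min`, `rh_max`,
#'   `radiation`, `wind`, `rain`) suitable for [derive_climate_table()].
#' @export
generate_weather_season <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "swp_study_config"))
  dates <- seq(as.Date(paste0(config$year, "-04-01")),
               as.Date(paste0(config$year, "-09-30")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  with_seed(seed, {
    base <- 21 + 9 * cos(2 * pi * (doy - 196) / 365)
    anom <- numeric(n)
    anom[1] <- stats::rnorm(1, 0, 2.5)
    innov <- stats::rnorm(n, 0, 2.5)
    for (i in 2:n) anom[i] <- 0.7 * anom[i - 1] + innov[i]
    tmax <- base + anom

    # sampling days: clip into the configured range, with an explicit
    # day-1/day-2 temperature contrast
    d1 <- match(config$campaigns, doy)
    d2 <- d1 + 1L
    if (any(is.na(d1)) || any(d2 > n)) {
      stop("campaign outside the generated weather season", call. = FALSE)
    }
    lo <- config$tmax_range[1]; hi <- config$tmax_range[2]
    tmax[d1] <- pmin(pmax(tmax[d1], lo), hi)
    tmax[d2] <- pmin(pmax(tmax[d1] + stats::rnorm(length(d1), 0, 3), lo), hi)

    spread <- pmax(stats::rnorm(n, 10, 1.5), 4)
    tmin <- tmax - spread
    rain <- ifelse(stats::runif(n) < 0.25, stats::rexp(n, rate = 1 / 6), 0)
    rh_min <- pmin(pmax(100 - 2.4 * tmax + stats::rnorm(n, 0, 6), 12), 85)
    rh_min[rain > 0] <- pmin(rh_min[rain > 0] + 10, 95)
    rh_max <- pmin(rh_min + 25 + stats::runif(n, 0, 15), 100)

    ra <- extraterrestrial_radiation(doy, config$latitude)
    kt <- pmin(pmax(stats::rnorm(n, 0.62, 0.12), 0.2), 0.78)
    kt[rain > 0] <- kt[rain > 0] * 0.6
    radiation <- ra * kt
    wind <- pmin(pmax(stats::rlnorm(n, log(2.2), 0.4), 0.3), 8)

    data.frame(date = dates, tmax = tmax, tmin = tmin,
               rh_min = rh_min, rh_max = rh_max,
               radiation = radiation, wind = wind, rain = rain)
  })
}

# FAO-56 extraterrestrial radiation, MJ m^-2 d^-1
extraterrestrial_radiation <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

soil_class_params <- function(class) {
  switch(class,
    free_draining = list(deplete = 0.0125, recharge = 0.004, floor = -0.95),
    clayey        = list(deplete = 0.0080, recharge = 0.003, floor = -0.70),
    water_table   = list(deplete = 0.0040, recharge = 0.002, floor = -0.30),
    stop("unknown soil profile `", class, "`", call. = FALSE)
  )
}

#' Generate per-plot predawn water potential trajectories
#'
#' A simple bucket-style dryness model per plot: daily PLWP decline scales
#' with an evaporative-demand proxy (Tmax above 15 degrees C) and the plot's
#' soil retention class; rainfall moves PLWP back toward 0 (field capacity);
#' water-table plots are floored at mild deficits. Daily decline never exceeds
#' ~0.02 MPa absent rain, which is what lets a single intervening-night PLWP
#' stand for both days of a campaign.
#'
#' @inheritParams generate_weather_season
#' @param weather Weather table covering all campaign dates (e.g. from
#'   [generate_weather_season()]).
#' @return Data frame with one row per plot x campaign: `plot`, `soil`,
#'   `campaign` (index), `doy_day1`, `doy_day2`, `plwp` (MPa, the
#'   intervening-night value). Attribute `"daily"` holds the full plot x day
#'   trajectory matrix.
#' @export
generate_plwp_trajectories <- function(weather, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "swp_study_config"))
  weather <- validate_weather(weather)
  doy <- as.integer(format(weather$date, "%j"))
  need <- c(config$campaigns, config$campaigns + 1L)
  if (!all(need %in% doy)) {
    stop("weather does not cover all campaign dates", call. = FALSE)
  }
  n_day <- nrow(weather)
  demand <- pmax((weather$tmax - 15) / 15, 0)
  with_seed(seed, {
    daily <- matrix(NA_real_, config$n_plots, n_day,
                    dimnames = list(paste0("P", seq_len(config$n_plots)),
                                    as.character(weather$date)))
    rate_mult <- exp(stats::rnorm(config$n_plots, 0, 0.25))
    for (p in seq_len(config$n_plots)) {
      sc <- soil_class_params(config$soil_profiles[p])
      plwp <- -0.02
      for (t in seq_len(n_day)) {
        # daily decline capped at 0.02 MPa: this is what makes the single
        # intervening-night PLWP representative of both campaign days
        plwp <- plwp - min(sc$deplete * rate_mult[p] * demand[t], 0.02)
        plwp <- plwp + sc$recharge * weather$rain[t]
        plwp <- min(max(plwp, sc$floor, config$plwp_range[1]),
                    config$plwp_range[2])
        daily[p, t] <- plwp
      }
    }
    idx1 <- match(config$campaigns, doy)
    out <- expand.grid(plot = rownames(daily),
                       campaign = seq_along(config$campaigns),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$soil <- config$soil_profiles[match(out$plot, rownames(daily))]
    out$doy_day1 <- config$campaigns[out$campaign]
    out$doy_day2 <- out$doy_day1 + 1L
    out$plwp <- daily[cbind(match(out$plot, rownames(daily)),
                            idx1[out$campaign])]
    out <- out[order(out$plot, out$campaign), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "daily") <- daily
    out
  })
}

#' Generate paired-day water potential observations
#'
#' For every plot, vine and campaign, draws a vine-level predawn value around
#' the plot trajectory (shared identically by both days of the campaign, as in
#' the field protocol where PLWP is measured once in the intervening night)
#' and generates SWP on day 1 and day 2 from the configured true model plus
#' Gaussian noise, using each day's own Tmax/DOY from the weather.
#'
#' @inheritParams generate_plwp_trajectories
#' @param trajectories Output of [generate_plwp_trajectories()].
#' @return Observation data frame: `plot`, `vine`, `cultivar`, `soil`,
#'   `campaign`, `day` (1 or 2), `date`, `doy`, `plwp`, `swp`, `tmax`,
#'   `vpd_max`, `gdd`. SWP and PLWP are never positive.
#' @export
generate_observations <- function(config, weather, trajectories,
                                  seed = config$seed + 2L) {
  stopifnot(inherits(config, "swp_study_config"))
  climate <- derive_climate_table(weather, config$latitude, config$altitude)
  cultivars <- rep_len(c("Merlot", "Cabernet-Sauvignon", "Cabernet franc"),
                       config$n_plots)
  names(cultivars) <- paste0("P", seq_len(config$n_plots))
  with_seed(seed, {
    grid <- expand.grid(
      vine = seq_len(config$n_vines_per_plot),
      row = seq_len(nrow(trajectories)),
      KEEP.OUT.ATTRS = FALSE
    )
    tr <- trajectories[grid$row, , drop = FALSE]
    n_pv <- nrow(grid)
    plwp_vine <- tr$plwp + stats::rnorm(n_pv, 0, config$noise_sd_plwp)
    plwp_vine <- pmin(pmax(plwp_vine, config$plwp_range[1]),
                      config$plwp_range[2])

    true_form <- attr(config$true_params, "form")
    one_day <- function(day) {
      doy <- if (day == 1) tr$doy_day1 else tr$doy_day2
      ci <- match(doy, climate$doy)
      clim_val <- switch(true_form$climate,
                         none = NULL,
                         tmax = climate$tmax[ci],
                         vpd_max = climate$vpd_max[ci])
      seas_val <- switch(true_form$seasonal,
                         none = NULL, doy = doy, gdd = climate$gdd[ci])
      pred <- predict_swp(config$true_params, plwp_vine,
                          climate_value = clim_val,
                          seasonal_value = seas_val)
      swp <- pred + stats::rnorm(n_pv, 0, config$noise_sd_swp)
      data.frame(
        plot = tr$plot,
        vine = paste0(tr$plot, "-V", grid$vine),
        cultivar = unname(cultivars[tr$plot]),
        soil = tr$soil,
        campaign = tr$campaign,
        day = day,
        date = doy_to_date(doy, config$year),
        doy = doy,
        plwp = plwp_vine,
        swp = pmin(swp, -0.001),
        tmax = climate$tmax[ci],
        vpd_max = climate$vpd_max[ci],
        gdd = climate$gdd[ci]
      )
    }
    obs <- rbind(one_day(1L), one_day(2L))
    obs <- obs[order(obs$plot, obs$vine, obs$campaign, obs$day), , drop = FALSE]
    rownames(obs) <- NULL
    if (config$missingness > 0) {
      obs <- obs[stats::runif(nrow(obs)) >= config$missingness, , drop = FALSE]
    }
    obs
  })
}

#' Generate a complete synthetic study bundle
#'
#' Runs the three generator stages (weather season, plot PLWP trajectories,
#' paired-day observations) and returns them together with a truth manifest
#' (generating form, coefficients, noise levels, seed) for downstream
#' recovery tests. Optionally writes the bundle to a directory as
#' `weather.csv`, `climate.csv`, `observations.csv` and `truth.json`.
#'
#' @param config An [synthetic_study_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with `weather`, `climate` (derived covariates),
#'   `observations`, `trajectories`, and `truth`.
#' @export
generate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "swp_study_config"))
  weather <- generate_weather_season(config)
  climate <- derive_climate_table(weather, config$latitude, config$altitude)
  trajectories <- generate_plwp_trajectories(weather, config)
  observations <- generate_observations(config, weather, trajectories)
  truth <- list(
    form = attr(config$true_params, "form")$id,
    seasonal = attr(config$true_params, "form")$seasonal,
    params = as.list(unclass(config$true_params)),
    noise_sd_swp = config$noise_sd_swp,
    noise_sd_plwp = config$noise_sd_plwp,
    seed = config$seed
  )
  bundle <- list(weather = weather, climate = climate,
                 observations = observations, trajectories = trajectories,
                 truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_weather_csv(weather, file.path(dir, "weather.csv"),
                      seed = config$seed)
    write_table_csv(climate, file.path(dir, "climate.csv"),
                    seed = config$seed)
    write_observations_csv(observations, file.path(dir, "observations.csv"),
                           seed = config$seed)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
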