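# column contracts for the two interchange CSVs (ISO dates, decimal point)
weather_csv_cols <- c(date = "date", tmax_c = "tmax", tmin_c = "tmin",
                      rhmin_pct = "rh_min", rhmax_pct = "rh_max",
                      radiation_mj_m2 = "radiation", wind_ms = "wind",
                      rain_mm = "rain")
obs_csv_cols <- c(plot = "plot", vine = "vine", cultivar = "cultivar",
                  date = "date", plwp_mpa = "plwp", swp_mpa = "swp")

validate_weather <- function(weather) {
  need <- unname(weather_csv_cols)
  miss <- setdiff(need, names(weather))
  if (length(miss)) {
    stop("weather table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  weather$date <- as.Date(weather$date)
  if (any(is.na(weather$date))) stop("unparseable weather dates", call. = FALSE)
  num <- setdiff(need, "date")
  for (v in num) {
    if (any(!is.finite(weather[[v]]))) {
      stop("non-finite values in weather column `", v, "`", call. = FALSE)
    }
  }
  bad <- which(weather$tmax < weather$tmin)
  if (length(bad)) stop("tmax < tmin at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  bad <- which(weather$rh_max < weather$rh_min)
  if (length(bad)) stop("rh_max < rh_min at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        call. = FALSE)
  if (any(weather$rh_min < 0 | weather$rh_max > 100)) {
    stop("relative humidity outside [0, 100]", call. = FALSE)
  }
  if (any(weather$radiation < 0) || any(weather$wind < 0) ||
      any(weather$rain < 0)) {
    stop("radiation, wind and rain must be non-negative", call. = FALSE)
  }
  weather[order(weather$date), , drop = FALSE]
}

provenance_lines <- function(seed = NULL, config_hash = NULL) {
  v <- as.character(utils::packageVersion("swpclim"))
  l <- sprintf("# swpclim %s", v)
  if (!is.null(seed)) l <- c(l, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config_hash)) l <- c(l, sprintf("# config_hash: %s", config_hash))
  l
}

# numeric columns are written with 6 significant digits
format_numeric <- function(df) {
  for (v in names(df)) {
    if (is.numeric(df[[v]]) && !is.integer(df[[v]])) {
      df[[v]] <- signif(df[[v]], 6)
    }
  }
  df
}

write_csv_provenance <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed, config_hash), con)
  utils::write.csv(format_numeric(df), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write daily weather CSV
#'
#' The weather interchange format has one row per day with columns `date`
#' (ISO-8601), `tmax_c`, `tmin_c`, `rhmin_pct`, `rhmax_pct`,
#' `radiation_mj_m2`, `wind_ms`, `rain_mm`. Lines starting with `#` are
#' provenance comments and are skipped.
#'
#' @param path CSV path.
#' @return `read_weather_csv()`: a validated weather data frame with internal
#'   column names (`date`, `tmax`, `tmin`, `rh_min`, `rh_max`, `radiation`,
#'   `wind`, `rain`), sorted by date.
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(names(weather_csv_cols), names(raw))
  if (length(miss)) {
    stop("weather CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[names(weather_csv_cols)]
  names(out) <- unname(weather_csv_cols)
  dates <- as.Date(out$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    stop("unparseable date at row(s): ",
         paste(utils::head(which(is.na(dates)), 5), collapse = ", "),
         call. = FALSE)
  }
  out$date <- dates
  validate_weather(out)
}

#' @rdname read_weather_csv
#' @param weather Weather data frame (internal column names).
#' @param seed,config_hash Optional provenance recorded as `#` header lines.
#' @export
write_weather_csv <- function(weather, path, seed = NULL, config_hash = NULL) {
  weather <- validate_weather(weather)
  out <- weather[unname(weather_csv_cols)]
  names(out) <- names(weather_csv_cols)
  write_csv_provenance(out, path, seed, config_hash)
}

#' Read / write water-potential observation CSV
#'
#' One row per vine and day with columns `plot`, `vine`, `cultivar`, `date`
#' (ISO-8601), `plwp_mpa`, `swp_mpa`; either potential may be empty on a row
#' but not both. Potentials are physical (negative MPa); values above
#' +0.005 MPa are rejected, and small positives within the tolerance are
#' truncated to 0. Duplicate `(plot, vine, date)` keys are an error. Extra
#' covariate columns (`tmax`, `vpd_max`, `doy`, `gdd`, ...) are carried
#' through untouched.
#'
#' @param path CSV path.
#' @return A data frame with internal names (`plot`, `vine`, `cultivar`,
#'   `date`, `plwp`, `swp`, plus any carried columns).
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(names(obs_csv_cols), names(raw))
  if (length(miss)) {
    stop("observations CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- raw
  names(out)[match(names(obs_csv_cols), names(out))] <- unname(obs_csv_cols)
  dates <- as.Date(out$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    stop("unparseable date at row(s): ",
         paste(utils::head(which(is.na(dates)), 5), collapse = ", "),
         call. = FALSE)
  }
  out$date <- dates
  both_na <- is.na(out$plwp) & is.na(out$swp)
  if (any(both_na)) {
    stop("row(s) with neither PLWP nor SWP: ",
         paste(utils::head(which(both_na), 5), collapse = ", "),
         call. = FALSE)
  }
  for (v in c("plwp", "swp")) {
    bad <- which(out[[v]] > 0.005)
    if (length(bad)) {
      stop("positive ", v, " beyond +0.005 MPa tolerance at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    out[[v]] <- pmin(out[[v]], 0)
  }
  key <- paste(out$plot, out$vine, out$date, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (plot, vine, date) key(s): ",
         paste(utils::head(unique(key[dup]), 3), collapse = "; "),
         call. = FALSE)
  }
  out[order(out$plot, out$vine, out$date), , drop = FALSE]
}

#' @rdname read_observations_csv
#' @param observations Observation data frame (internal column names).
#' @param seed,config_hash Optional provenance recorded as `#` header lines.
#' @export
write_observations_csv <- function(observations, path, seed = NULL,
                                   config_hash = NULL) {
  out <- observations
  ren <- match(unname(obs_csv_cols), names(out))
  names(out)[stats::na.omit(ren)] <-
    names(obs_csv_cols)[!is.na(ren)]
  write_csv_provenance(out, path, seed, config_hash)
}

# generic derived-table writer (climate, comparison tables, ...)
write_table_csv <- function(df, path, seed = NULL, config_hash = NULL) {
  write_csv_provenance(df, path, seed, config_hash)
}
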