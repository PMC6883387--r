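#' Configuration of a full analysis run
#'
#' Collects everything one reproducible run needs: input paths, site
#' constants, the model forms to fit and cross-validate, the standardization
#' targets, the pairing thresholds, and the seed. The configuration hash
#' recorded in every output's provenance header changes iff a semantic field
#' changes (the output directory is excluded).
#'
#' @param weather_csv,observations_csv Input paths (must exist).
#' @param latitude,altitude Site constants.
#' @param forms Model form ids to fit (default all five).
#' @param cv_group Grouping column for cross-validation folds (default
#'   `"plot"`).
#' @param t_s,doy_s Standardization reference conditions (degrees C, DOY).
#' @param max_delta_plwp,min_gap_days Matched-pair thresholds.
#' @param seed Integer seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @return List of class `swp_run_config`.
#' @export
pipeline_config <- function(weather_csv, observations_csv,
                            latitude = 44.8, altitude = 20,
                            forms = c("M1", "M2", "M3", "M4", "M5"),
                            cv_group = "plot",
                            t_s = 30, doy_s = 200,
                            max_delta_plwp = 0.005, min_gap_days = 7L,
                            seed = 1L, out_dir = tempfile("swpclim_run_")) {
  for (p in c(weather_csv, observations_csv)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  structure(list(
    weather_csv = weather_csv, observations_csv = observations_csv,
    latitude = latitude, altitude = altitude,
    forms = forms, cv_group = cv_group,
    t_s = t_s, doy_s = doy_s,
    max_delta_plwp = max_delta_plwp, min_gap_days = as.integer(min_gap_days),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "swp_run_config")
}

#' @rdname pipeline_config
#' @param config An `swp_run_config`.
#' @export
config_hash <- function(config) {
  sem <- unclass(config)
  sem$out_dir <- NULL
  rlang::hash(sem)
}

#' Run the full SWP analysis pipeline
#'
#' Orchestrates the workflow end to end: ingest the weather and observation
#' CSVs, derive the climatic covariates and attach them to the observations by
#' date, fit and cross-validate the requested model forms, evaluate climatic
#' standardization on both validation pairings (consecutive-day and
#' matched-PLWP) using the fitted Tmax-form coefficients, and write every
#' stage's output (with provenance headers) plus a stage log to the output
#' directory. Deterministic under a fixed seed; a stage failure stops the run
#' but leaves completed stage outputs in place.
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, a list with `climate`, `observations`, `comparison`,
#'   `standardization` (reports per mode/pairing), `log`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "swp_run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    writeLines(log, file.path(config$out_dir, "log.txt"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("[%s] FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  weather <- stage("ingest-weather", read_weather_csv(config$weather_csv))
  note("[ingest-weather] %d days", nrow(weather))
  obs <- stage("ingest-observations",
               read_observations_csv(config$observations_csv))
  note("[ingest-observations] %d rows", nrow(obs))

  climate <- stage("derive-climate",
                   derive_climate_table(weather, config$latitude,
                                        config$altitude))
  write_table_csv(climate, file.path(config$out_dir, "climate.csv"),
                  seed = config$seed, config_hash = hash)
  note("[derive-climate] %d days", nrow(climate))

  data <- stage("join-covariates", {
    idx <- match(as.Date(obs$date), climate$date)
    if (any(is.na(idx))) {
      stop("observation date(s) outside the weather record: ",
           paste(utils::head(unique(obs$date[is.na(idx)]), 3), collapse = ", "))
    }
    for (v in c("doy", "tmax", "vpd_max", "et0", "gdd")) {
      obs[[v]] <- climate[[v]][idx]
    }
    obs
  })
  note("[join-covariates] %d rows with climate attached", nrow(data))

  fit_data <- data[!is.na(data$swp) & !is.na(data$plwp), , drop = FALSE]
  comparison <- stage("compare-models",
                      compare_models(config$forms, fit_data,
                                     seed = config$seed, cv = TRUE,
                                     group = config$cv_group))
  write_table_csv(as.data.frame(comparison),
                  file.path(config$out_dir, "model_comparison.csv"),
                  seed = config$seed, config_hash = hash)
  note("[compare-models] %d forms on %d rows; best by AIC: %s",
       nrow(comparison), nrow(fit_data), comparison$form[1])

  standardization <- stage("standardize", {
    fits <- attr(comparison, "fits")
    m3 <- if ("M3" %in% names(fits)) fits$M3$params else reference_params("M3")
    m5 <- if ("M5" %in% names(fits)) fits$M5$params else reference_params("M5")
    cons <- pair_consecutive_days(fit_data)
    matched <- pair_matched_plwp(fit_data,
                                 max_delta_plwp = config$max_delta_plwp,
                                 min_gap_days = config$min_gap_days)
    reports <- list()
    if (nrow(cons)) {
      reports$consecutive_temperature <- suppressWarnings(
        evaluate_standardization(cons, "temperature", m3))
      reports$consecutive_temperature_doy <- suppressWarnings(
        evaluate_standardization(cons, "temperature_doy", m5))
    }
    if (nrow(matched)) {
      reports$matched_temperature_doy <- suppressWarnings(
        evaluate_standardization(matched, "temperature_doy", m5))
    }
    note("[standardize] %d consecutive-day pairs, %d matched-PLWP pairs",
         nrow(cons), nrow(matched))
    reports
  })
  report_json <- lapply(standardization, function(r) {
    r$pairs <- NULL
    r <- unclass(r)
    r$regression_before <- as.list(r$regression_before)
    r$regression_after <- as.list(r$regression_after)
    r
  })
  jsonlite::write_json(
    list(provenance = list(package = "swpclim",
                           version = as.character(utils::packageVersion("swpclim")),
                           seed = config$seed, config_hash = hash),
         reports = report_json),
    file.path(config$out_dir, "standardization_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(standardization)) {
    write_table_csv(standardization[[nm]]$pairs,
                    file.path(config$out_dir, paste0("pairs_", nm, ".csv")),
                    seed = config$seed, config_hash = hash)
  }
  note("[done] outputs in %s", config$out_dir)

  invisible(list(climate = climate, observations = data,
                 comparison = comparison, standardization = standardization,
                 log = log, out_dir = config$out_dir))
}
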