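#' Standardize SWP to a reference maximum temperature
#'
#' A Tmax-driven SWP model `SWP = a * exp(b*PLWP) * Tmax^p + c` can be
#' inverted algebraically at unchanged soil water status (constant PLWP): the
#' soil-water amplitude `a*exp(b*PLWP) = (SWP - c) / Tmax^p` is carried over
#' to the reference temperature, giving
#'
#' \deqn{SWP_s = (SWP - c) \left(\frac{T_s}{T_{max}}\right)^{p} + c}
#'
#' This removes the day-of-measurement temperature effect so that SWP values
#' collected under different climatic conditions become comparable.
#'
#' @param swp Measured stem water potential, MPa.
#' @param tmax Maximum air temperature on the measurement day, degrees C (> 0).
#' @param t_s Reference temperature to standardize to, degrees C (> 0; a
#'   warning is raised outside the 10-45 degrees C sanity band).
#' @param params Coefficients of an M3-form fit ([swp_params()]); defaults to
#'   the published M3 coefficients (`c = -1.628`, `p = -0.819`).
#' @return Standardized SWP, MPa. Observations whose amplitude term
#'   `swp - c <= 0` (below the model asymptote, outside the model's domain)
#'   return `NA` with a warning.
#' @examples
#' standardize_swp_temperature(-0.8, tmax = 35, t_s = 30)  # ~ -0.689
#' @export
standardize_swp_temperature <- function(swp, tmax, t_s,
                                        params = reference_params("M3")) {
  form <- param_form(params)
  if (form$climate != "tmax" || form$seasonal != "none") {
    stop("`params` must be an M3-form (Tmax power law, no seasonal term)",
         call. = FALSE)
  }
  check_target_temp(t_s)
  if (any(tmax <= 0) || any(t_s <= 0)) {
    stop("`tmax` and `t_s` must be positive (degrees C)", call. = FALSE)
  }
  v <- as.list(unclass(params))
  amp <- swp - v$c
  bad <- amp <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE),
            " observation(s) at or below the model asymptote c = ", v$c,
            " MPa; standardized value set to NA")
  }
  out <- amp * (t_s / tmax)^v$p + v$c
  out[which(bad)] <- NA_real_
  out
}

#' Standardize SWP to a reference temperature and day of year
#'
#' Inverts the full seasonal model `SWP = a*exp(b*PLWP)*Tmax^p + d*DOY + c`
#' at constant PLWP:
#'
#' \deqn{SWP_s = (SWP - d \cdot DOY - c)\left(\frac{T_s}{T_{max}}\right)^{p}
#'   + d \cdot DOY_s + c}
#'
#' With `doy_s = doy` this reduces to the temperature-only standardization,
#' and with `d = 0` it degenerates exactly to it.
#'
#' @inheritParams standardize_swp_temperature
#' @param doy Day of year of the measurement (1-366).
#' @param doy_s Reference day of year to standardize to.
#' @param params Coefficients of an M5-form fit; defaults to the published M5
#'   coefficients (`p = -0.896`, `d = -0.00543`, `c = -0.579`).
#' @return Standardized SWP, MPa (`NA` with a warning where the amplitude term
#'   `swp - d*doy - c <= 0`).
#' @examples
#' standardize_swp_temperature_doy(-0.9, tmax = 34, doy = 240,
#'                                 t_s = 30, doy_s = 200)  # ~ -0.566
#' @export
standardize_swp_temperature_doy <- function(swp, tmax, doy, t_s, doy_s,
                                            params = reference_params("M5")) {
  form <- param_form(params)
  if (form$climate != "tmax" || form$seasonal == "none") {
    stop("`params` must be an M5-form (Tmax power law plus seasonal term)",
         call. = FALSE)
  }
  check_target_temp(t_s)
  if (any(tmax <= 0) || any(t_s <= 0)) {
    stop("`tmax` and `t_s` must be positive (degrees C)", call. = FALSE)
  }
  if (any(doy < 1 | doy > 366) || any(doy_s < 1 | doy_s > 366)) {
    stop("`doy` and `doy_s` must be within [1, 366]", call. = FALSE)
  }
  v <- as.list(unclass(params))
  amp <- swp - v$d * doy - v$c
  bad <- amp <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE),
            " observation(s) with non-positive amplitude term; ",
            "standardized value set to NA")
  }
  out <- amp * (t_s / tmax)^v$p + v$d * doy_s + v$c
  out[which(bad)] <- NA_real_
  out
}

check_target_temp <- function(t_s) {
  if (any(t_s < 10 | t_s > 45)) {
    warning("reference temperature outside the 10-45 degrees C sanity band")
  }
  invisible(TRUE)
}

#' Pair consecutive-day SWP observations
#'
#' The field design measures SWP on two consecutive days with PLWP measured in
#' the intervening night, so soil water status is (near) identical within a
#' pair while the climate differs. This builds those pairs: for each plot and
#' vine, every pair of observations exactly one day apart, the earlier day as
#' the reference.
#'
#' @param data Observation table with columns `plot`, `vine`, `date`, `swp`,
#'   `plwp`, and the climate columns (`tmax`, `doy`, ...).
#' @return A data frame of pairs, one row each, with the reference
#'   observation's columns suffixed `_ref` and the later day's suffixed
#'   `_other`, plus `gap_days` (= 1), `delta_plwp` and `pairing`
#'   (`"consecutive_day"`). Attribute `"n_skipped"` counts observations left
#'   unmatched.
#' @export
pair_consecutive_days <- function(data) {
  req <- c("plot", "vine", "date", "swp")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data <- data[order(data$plot, data$vine, data$date), , drop = FALSE]
  key <- interaction(data$plot, data$vine, drop = TRUE)
  pairs <- list()
  n_skipped <- 0L
  for (lv in levels(key)) {
    sub <- data[key == lv, , drop = FALSE]
    gap <- as.integer(diff(as.Date(sub$date)))
    i <- which(gap == 1L)
    used <- unique(c(i, i + 1L))
    n_skipped <- n_skipped + nrow(sub) - length(used)
    if (length(i)) pairs[[lv]] <- bind_pair(sub[i, ], sub[i + 1L, ])
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else empty_pairs(data)
  rownames(out) <- NULL
  out$pairing <- rep("consecutive_day", nrow(out))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Pair observations with matched predawn water potential
#'
#' Builds within-plot pairs of observations taken well apart in time but at
#' (almost) the same predawn leaf water potential, so that the soil-water term
#' of the model is the same within the pair and any SWP difference is
#' climatic/seasonal. All qualifying ordered pairs are emitted (the earlier
#' observation is the reference); observations may appear in several pairs.
#'
#' @param data Observation table (as in [pair_consecutive_days()]; `plwp`
#'   required).
#' @param max_delta_plwp Largest admissible |PLWP difference| within a pair,
#'   MPa. The threshold is inclusive (default 0.005 MPa).
#' @param min_gap_days Smallest admissible day gap (default 7; 3 is the
#'   permissive variant).
#' @return Pair data frame as in [pair_consecutive_days()], with `pairing =
#'   "plwp_matched"`.
#' @export
pair_matched_plwp <- function(data, max_delta_plwp = 0.005,
                              min_gap_days = 7L) {
  req <- c("plot", "date", "swp", "plwp")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(is.na(data$plwp))) {
    stop("`plwp` must be present on every candidate observation",
         call. = FALSE)
  }
  data <- data[order(data$plot, data$date), , drop = FALSE]
  pairs <- list()
  for (pl in unique(data$plot)) {
    sub <- data[data$plot == pl, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    gap <- as.integer(as.Date(sub$date[idx[, 2]]) - as.Date(sub$date[idx[, 1]]))
    dpl <- abs(sub$plwp[idx[, 2]] - sub$plwp[idx[, 1]])
    ok <- gap >= min_gap_days & dpl <= max_delta_plwp
    if (any(ok)) {
      pairs[[as.character(pl)]] <-
        bind_pair(sub[idx[ok, 1], , drop = FALSE],
                  sub[idx[ok, 2], , drop = FALSE])
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else empty_pairs(data)
  rownames(out) <- NULL
  out$pairing <- rep("plwp_matched", nrow(out))
  out
}

bind_pair <- function(ref, other) {
  keep <- intersect(c("plot", "vine", "cultivar", "date", "swp", "plwp",
                      "tmax", "vpd_max", "doy", "gdd"), names(ref))
  a <- ref[keep]; names(a) <- paste0(keep, "_ref")
  b <- other[keep]; names(b) <- paste0(keep, "_other")
  out <- cbind(a, b)
  out$gap_days <- as.integer(as.Date(other$date) - as.Date(ref$date))
  out$delta_plwp <- other$plwp - ref$plwp
  out
}

empty_pairs <- function(data) {
  keep <- intersect(c("plot", "vine", "cultivar", "date", "swp", "plwp",
                      "tmax", "vpd_max", "doy", "gdd"), names(data))
  cols <- c(paste0(keep, "_ref"), paste0(keep, "_other"),
            "gap_days", "delta_plwp")
  out <- data[0, rep(1, length(cols)), drop = FALSE]
  names(out) <- cols
  out
}

#' Evaluate the benefit of climatic standardization on observation pairs
#'
#' Within each pair the reference SWP is taken as "truth" (same soil water
#' status), and the later/other observation's SWP is compared to it before and
#' after standardizing it to the reference day's climate. The drop in RMSE
#' measures how much day-of-measurement climate the standardization removes.
#'
#' @param pairs Pair table from [pair_consecutive_days()] or
#'   [pair_matched_plwp()].
#' @param mode `"temperature"` (M3 inversion, Tmax only) or
#'   `"temperature_doy"` (M5 inversion, Tmax + DOY).
#' @param params Matching `swp_params`; defaults to the published M3/M5
#'   coefficients.
#' @return List of class `swp_standardization_report`: `n_pairs`,
#'   `n_excluded` (domain-flagged standardized values), `rmse_unstandardized`,
#'   `rmse_standardized`, `pct_improvement`, `r2_before`, `r2_after`,
#'   `regression_before`/`regression_after` (slope and intercept of other vs
#'   ref, the Figs-style summary), and the per-pair table.
#' @export
evaluate_standardization <- function(pairs,
                                     mode = c("temperature",
                                              "temperature_doy"),
                                     params = NULL) {
  mode <- match.arg(mode)
  if (!nrow(pairs)) stop("empty pair list", call. = FALSE)
  if (is.null(params)) {
    params <- reference_params(if (mode == "temperature") "M3" else "M5")
  }
  swp_std <- if (mode == "temperature") {
    standardize_swp_temperature(pairs$swp_other, pairs$tmax_other,
                                t_s = pairs$tmax_ref, params = params)
  } else {
    standardize_swp_temperature_doy(pairs$swp_other, pairs$tmax_other,
                                    pairs$doy_other, t_s = pairs$tmax_ref,
                                    doy_s = pairs$doy_ref, params = params)
  }
  pairs$swp_other_std <- swp_std
  ok <- !is.na(swp_std)
  n_excluded <- sum(!ok)
  ref <- pairs$swp_ref[ok]
  raw <- pairs$swp_other[ok]
  std <- swp_std[ok]
  rmse <- function(x, y) sqrt(mean((x - y)^2))
  lin <- function(x, y) {
    if (length(unique(x)) < 2) return(c(slope = NA_real_, intercept = NA_real_))
    co <- stats::coef(stats::lm(y ~ x))
    c(slope = unname(co[2]), intercept = unname(co[1]))
  }
  r2 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }
  rmse_un <- rmse(ref, raw)
  rmse_st <- rmse(ref, std)
  structure(list(
    mode = mode,
    n_pairs = nrow(pairs),
    n_used = sum(ok),
    n_excluded = n_excluded,
    rmse_unstandardized = rmse_un,
    rmse_standardized = rmse_st,
    pct_improvement = if (rmse_un > 0) 100 * (rmse_un - rmse_st) / rmse_un
                      else 0,
    r2_before = r2(ref, raw),
    r2_after = r2(ref, std),
    regression_before = lin(ref, raw),
    regression_after = lin(ref, std),
    pairs = pairs
  ), class = "swp_standardization_report")
}

#' @export
print.swp_standardization_report <- function(x, ...) {
  cat(sprintf("<standardization report: %s>\n", x$mode))
  cat(sprintf("  pairs: %d (%d used, %d excluded)\n",
              x$n_pairs, x$n_used, x$n_excluded))
  cat(sprintf("  RMSE  raw: %.4f  standardized: %.4f  (improvement %.1f%%)\n",
              x$rmse_unstandardized, x$rmse_standardized, x$pct_improvement))
  cat(sprintf("  r2    raw: %.3f  standardized: %.3f\n",
              x$r2_before, x$r2_after))
  invisible(x)
}
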