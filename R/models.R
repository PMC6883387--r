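#' Stem water potential model forms
#'
#' The model family relates midday stem water potential (SWP, MPa) to predawn
#' leaf water potential (PLWP, MPa, a proxy for soil water availability),
#' optionally modulated by one climatic covariate through a power law and by a
#' linear seasonal term:
#'
#' \deqn{SWP = a \, e^{b \cdot PLWP} \, X^{p} + d \cdot S + c}
#'
#' where `X` is the climatic covariate (VPD_max in kPa or Tmax in degrees C)
#' and `S` the seasonal covariate (day of year, or cumulative growing degree
#' days as a variant). The five members are:
#'
#' * `M1`: PLWP only (`SWP = a e^{b PLWP} + c`)
#' * `M2`: PLWP and VPD_max
#' * `M3`: PLWP and Tmax
#' * `M4`: PLWP, VPD_max and seasonality
#' * `M5`: PLWP, Tmax and seasonality
#'
#' @param id One of `"M1" ... "M5"`.
#' @param seasonal Seasonal covariate for M4/M5: `"doy"` (default) or `"gdd"`.
#' @return An object of class `swp_form`: a list with `id`, `climate`
#'   (`"none"`, `"vpd_max"` or `"tmax"`), `seasonal` (`"none"`, `"doy"` or
#'   `"gdd"`), and `par_names`.
#' @examples
#' model_form("M5")
#' model_form("M4", seasonal = "gdd")
#' @export
model_form <- function(id = c("M1", "M2", "M3", "M4", "M5"),
                       seasonal = c("doy", "gdd")) {
  id <- match.arg(id)
  seasonal <- match.arg(seasonal)
  climate <- switch(id, M1 = "none", M2 = "vpd_max", M3 = "tmax",
                    M4 = "vpd_max", M5 = "tmax")
  seas <- if (id %in% c("M4", "M5")) seasonal else "none"
  par_names <- c("a", "b",
                 if (climate != "none") "p",
                 if (seas != "none") "d",
                 "c")
  structure(list(id = id, climate = climate, seasonal = seas,
                 par_names = par_names),
            class = "swp_form")
}

#' @export
print.swp_form <- function(x, ...) {
  cl <- switch(x$climate, none = "", vpd_max = " * VPD_max^p",
               tmax = " * Tmax^p")
  se <- switch(x$seasonal, none = "", doy = " + d*DOY", gdd = " + d*GDD")
  cat(sprintf("<swp_form %s>  SWP = a * exp(b*PLWP)%s%s + c\n", x$id, cl, se))
  invisible(x)
}

#' Model coefficients
#'
#' Bundles the coefficients of one SWP model form. `a` is the amplitude of the
#' exponential soil-water term at PLWP = 0 (MPa times the climate covariate to
#' the power `-p`), `b > 0` the PLWP rate (MPa^-1), `p` the climate power
#' exponent, `d` the seasonal slope (MPa per day or per degree-day), and `c`
#' the intercept/asymptote (MPa).
#'
#' @param form An [model_form()] object or form id string.
#' @param a,b,p,d,c Coefficients; `p` and `d` are only accepted when the form
#'   carries the corresponding covariate.
#' @return Named numeric vector of class `swp_params` with attribute `form`.
#' @export
swp_params <- function(form, a, b, p = NULL, d = NULL, c) {
  if (is.character(form)) form <- model_form(form)
  stopifnot(inherits(form, "swp_form"))
  vals <- c(a = a, b = b)
  if (form$climate != "none") {
    if (is.null(p)) stop("form ", form$id, " requires `p`", call. = FALSE)
    vals <- c(vals, p = p)
  } else if (!is.null(p)) {
    stop("form M1 has no climate exponent `p`", call. = FALSE)
  }
  if (form$seasonal != "none") {
    if (is.null(d)) stop("form ", form$id, " requires `d`", call. = FALSE)
    vals <- c(vals, d = d)
  } else if (!is.null(d)) {
    stop("form ", form$id, " has no seasonal slope `d`", call. = FALSE)
  }
  vals <- c(vals, c = c)
  if (any(!is.finite(vals))) stop("coefficients must be finite", call. = FALSE)
  if (b <= 0) {
    warning("`b` <= 0: SWP should decline with more negative PLWP")
  }
  structure(vals, form = form, class = "swp_params")
}

#' Published reference coefficients for the five model forms
#'
#' Returns the published field-calibrated coefficient sets for models M1-M5
#' (Bordeaux vineyards, Merlot / Cabernet-Sauvignon / Cabernet franc, two dry
#' seasons), together with their published training RMSE, which is the natural
#' residual scale for simulation. These ship as the default parameters for
#' standardization.
#'
#' @param id Form id (`"M1"`-`"M5"`), or `NULL` for a named list of all five.
#' @return An `swp_params` object (with attribute `rmse`), or a list of them.
#' @examples
#' reference_params("M5")
#' @export
reference_params <- function(id = NULL) {
  tab <- list(
    M1 = list(a = 1.243,  b = 4.011, p = NULL,   d = NULL,     c = -1.616, rmse = 0.214),
    M2 = list(a = 1.518,  b = 4.063, p = -0.233, d = NULL,     c = -1.614, rmse = 0.205),
    M3 = list(a = 20.164, b = 3.890, p = -0.819, d = NULL,     c = -1.628, rmse = 0.201),
    M4 = list(a = 1.479,  b = 2.304, p = -0.318, d = -0.00580, c = -0.444, rmse = 0.166),
    M5 = list(a = 24.789, b = 2.144, p = -0.896, d = -0.00543, c = -0.579, rmse = 0.164)
  )
  build <- function(nm) {
    v <- tab[[nm]]
    pp <- swp_params(model_form(nm), a = v$a, b = v$b, p = v$p, d = v$d, c = v$c)
    attr(pp, "rmse") <- v$rmse
    pp
  }
  if (is.null(id)) {
    out <- lapply(names(tab), build)
    names(out) <- names(tab)
    return(out)
  }
  id <- match.arg(id, names(tab))
  build(id)
}

param_form <- function(params) {
  f <- attr(params, "form")
  if (is.null(f)) stop("`params` lacks a `form` attribute; use swp_params()",
                       call. = FALSE)
  f
}

check_predictors <- function(form, plwp, climate_value, seasonal_value) {
  if (any(plwp > 0.005, na.rm = TRUE)) {
    stop("`plwp` must be <= 0 MPa (tolerance +0.005)", call. = FALSE)
  }
  if (form$climate != "none") {
    if (is.null(climate_value)) {
      stop("form ", form$id, " needs `climate_value` (", form$climate, ")",
           call. = FALSE)
    }
    if (any(climate_value <= 0, na.rm = TRUE)) {
      stop("climate covariate must be > 0 (power law undefined at 0)",
           call. = FALSE)
    }
  }
  if (form$seasonal != "none" && is.null(seasonal_value)) {
    stop("form ", form$id, " needs `seasonal_value` (", form$seasonal, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict stem water potential from a model form
#'
#' Evaluates `SWP = a * exp(b*PLWP) * X^p + d*S + c` for the covariates the
#' form carries. Vectorized over observations.
#'
#' @param params An [swp_params()] object (carries its form).
#' @param plwp Predawn leaf water potential, MPa (<= 0).
#' @param climate_value VPD_max (kPa) or Tmax (degrees C), per the form;
#'   ignored for M1.
#' @param seasonal_value DOY or cumulative GDD, per the form; ignored for
#'   M1-M3.
#' @return Predicted SWP in MPa.
#' @examples
#' predict_swp(reference_params("M1"), plwp = 0)                     # -0.373
#' predict_swp(reference_params("M5"), 0, climate_value = 30,
#'             seasonal_value = 200)                                 # ~ -0.488
#' @export
predict_swp <- function(params, plwp, climate_value = NULL,
                        seasonal_value = NULL) {
  form <- param_form(params)
  check_predictors(form, plwp, climate_value, seasonal_value)
  v <- as.list(unclass(params))
  out <- v$a * exp(v$b * plwp)
  if (form$climate != "none") out <- out * climate_value^v$p
  if (form$seasonal != "none") out <- out + v$d * seasonal_value
  out + v$c
}

#' Analytic gradient of the SWP model surface
#'
#' Partial derivatives of the predicted SWP with respect to the free
#' coefficients, used as the Jacobian in least-squares fitting.
#'
#' @inheritParams predict_swp
#' @return A matrix with one row per observation and one column per
#'   coefficient (in `form$par_names` order).
#' @export
model_gradient <- function(params, plwp, climate_value = NULL,
                           seasonal_value = NULL) {
  form <- param_form(params)
  check_predictors(form, plwp, climate_value, seasonal_value)
  v <- as.list(unclass(params))
  n <- length(plwp)
  expo <- exp(v$b * plwp)
  xp <- if (form$climate != "none") climate_value^v$p else rep(1, n)
  g <- matrix(0, n, length(form$par_names),
              dimnames = list(NULL, form$par_names))
  g[, "a"] <- expo * xp
  g[, "b"] <- v$a * plwp * expo * xp
  if (form$climate != "none") {
    g[, "p"] <- v$a * expo * xp * log(climate_value)
  }
  if (form$seasonal != "none") g[, "d"] <- seasonal_value
  g[, "c"] <- 1
  g
}

# covariate columns a form needs from an observation table
form_covariates <- function(form) {
  c("plwp",
    if (form$climate != "none") form$climate,
    if (form$seasonal != "none") form$seasonal)
}

# pull (plwp, climate, seasonal) vectors out of an observation data frame
extract_predictors <- function(form, data) {
  need <- form_covariates(form)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  list(
    plwp = data$plwp,
    climate = if (form$climate != "none") data[[form$climate]] else NULL,
    seasonal = if (form$seasonal != "none") data[[form$seasonal]] else NULL
  )
}
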