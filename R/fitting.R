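# run code with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# log-linearization starting values: ln(swp - c0) = ln a + b*plwp + p*ln X
default_start <- function(form, data) {
  c0 <- min(data$swp) - 0.1
  amp <- pmax(data$swp - c0, 1e-6)
  pred <- extract_predictors(form, data)
  if (form$climate != "none") {
    lf <- stats::lm(log(amp) ~ pred$plwp + log(pred$climate))
    co <- stats::coef(lf)
    start <- c(a = unname(exp(co[1])), b = max(unname(co[2]), 0.1),
               p = unname(co[3]))
  } else {
    lf <- stats::lm(log(amp) ~ pred$plwp)
    co <- stats::coef(lf)
    start <- c(a = unname(exp(co[1])), b = max(unname(co[2]), 0.1))
  }
  if (form$seasonal != "none") start <- c(start, d = -0.005)
  c(start, c = c0)
}

start_to_params <- function(form, start) {
  swp_params(form, a = start[["a"]], b = start[["b"]],
             p = if ("p" %in% names(start)) start[["p"]],
             d = if ("d" %in% names(start)) start[["d"]],
             c = start[["c"]])
}

#' Fit an SWP model form by nonlinear least squares
#'
#' Fits `SWP = a * exp(b*PLWP) * X^p + d*S + c` to an observation table by
#' Levenberg-Marquardt least squares with the analytic Jacobian
#' ([model_gradient()]). Starting values come from a log-linearization of the
#' amplitude term; a seeded multi-start (jittered restarts) guards against
#' local minima, and the best restart must agree with the runner-up basin
#' before the fit is declared converged.
#'
#' @param form An [model_form()] object or form id string.
#' @param data Data frame with columns `swp`, `plwp` and whichever of
#'   `vpd_max`, `tmax`, `doy`, `gdd` the form uses (MPa, kPa, degrees C, days).
#' @param init Optional named numeric vector of starting values
#'   (`a`, `b`, `p`, `d`, `c` as applicable); default is the log-linearized
#'   heuristic.
#' @param seed Integer seed for the multi-start jitter.
#' @param n_starts Number of restarts (>= 1; the first is unjittered).
#' @param max_iter,ftol Optimizer controls (maximum iterations, relative cost
#'   reduction tolerance).
#' @return An object of class `swp_fit`: fitted `params`, `n`, `k` (free
#'   coefficients), `rss`, `aic`, `bic`, `r2`, `rmse`, `residuals` (observed
#'   minus fitted), `fitted`, `converged`, `n_iterations`.
#' @seealso [compare_models()], [leave_one_plot_out_cv()]
#' @export
fit_model <- function(form, data, init = NULL, seed = 1L, n_starts = 5L,
                      max_iter = 500L, ftol = 1e-10) {
  if (is.character(form)) form <- model_form(form)
  stopifnot(inherits(form, "swp_form"))
  if (!"swp" %in% names(data)) stop("`data` needs an `swp` column", call. = FALSE)
  pred <- extract_predictors(form, data)
  keep <- stats::complete.cases(data[c("swp", form_covariates(form))])
  if (!all(keep)) data <- data[keep, , drop = FALSE]
  pred <- extract_predictors(form, data)
  n <- nrow(data)
  k <- length(form$par_names)
  if (n <= k + 1) stop("need more than k + 1 = ", k + 1, " observations",
                       call. = FALSE)
  if (stats::sd(pred$plwp) < 1e-10) {
    stop("identifiability: `plwp` is constant, a and b are confounded",
         call. = FALSE)
  }
  if (form$climate != "none" && any(pred$climate <= 0)) {
    stop("climate covariate must be positive throughout", call. = FALSE)
  }

  base_start <- if (is.null(init)) default_start(form, data) else {
    if (!setequal(names(init), form$par_names)) {
      stop("`init` must name exactly: ", paste(form$par_names, collapse = ", "),
           call. = FALSE)
    }
    init[form$par_names]
  }

  obs <- data$swp
  resid_fn <- function(theta) {
    suppressWarnings({
      pr <- start_to_params(form, stats::setNames(theta, form$par_names))
      predict_swp(pr, pred$plwp, pred$climate, pred$seasonal) - obs
    })
  }
  jac_fn <- function(theta) {
    suppressWarnings({
      pr <- start_to_params(form, stats::setNames(theta, form$par_names))
      model_gradient(pr, pred$plwp, pred$climate, pred$seasonal)
    })
  }

  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) return(base_start)
      jit <- base_start * exp(stats::rnorm(length(base_start), 0, 0.2))
      # additive coefficients may be near 0; jitter them additively too
      jit[["c"]] <- base_start[["c"]] + stats::rnorm(1, 0, 0.1)
      if ("d" %in% names(jit)) jit[["d"]] <- base_start[["d"]] +
          stats::rnorm(1, 0, 0.002)
      jit
    })
  })

  runs <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = ftol, ptol = 1e-10)),
      error = function(e) NULL
    )
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("optimizer failed from every start", call. = FALSE)
  rsses <- vapply(runs, function(r) sum(r$fvec^2), numeric(1))
  best <- runs[[which.min(rsses)]]
  rss <- min(rsses)
  # multi-start agreement: at least one other start reaches the same basin
  agree <- length(rsses) == 1 ||
    sort(rsses)[2] - rss <= 1e-6 * max(rss, 1e-12)
  conv <- best$info %in% 1:4
  if (!conv) {
    warning("optimizer did not report clean convergence (info = ", best$info,
            "); returning best candidate")
  }
  theta <- stats::setNames(unname(best$par), form$par_names)
  params <- start_to_params(form, theta)
  fitted <- obs - best$fvec
  residuals <- obs - fitted

  if (theta[["b"]] <= 0) warning("fitted b <= 0: check data")
  ic <- information_criteria(n = n, k = k, rss = rss)
  tss <- sum((obs - mean(obs))^2)
  # asymptotic standard errors from the Jacobian at the solution
  se <- tryCatch({
    jac <- jac_fn(unname(best$par))
    sigma2 <- rss / max(n - k, 1)
    sqrt(diag(sigma2 * solve(crossprod(jac))))
  }, error = function(e) rep(NA_real_, k))
  names(se) <- form$par_names
  structure(list(
    form = form, params = params, se = se, n = n, k = k, rss = rss,
    aic = ic[["aic"]], bic = ic[["bic"]],
    r2 = if (tss > 0) 1 - rss / tss else NA_real_,
    rmse = sqrt(rss / n),
    residuals = residuals, fitted = fitted,
    converged = conv, multistart_agreement = agree,
    n_iterations = best$niter, seed = seed
  ), class = "swp_fit")
}

#' @export
print.swp_fit <- function(x, ...) {
  cat(sprintf("<swp_fit %s>  n = %d, k = %d\n", x$form$id, x$n, x$k))
  print(round(unclass(x$params), 5))
  cat(sprintf("  rss = %.5g  rmse = %.4f  r2 = %.4f\n", x$rss, x$rmse, x$r2))
  cat(sprintf("  AIC = %.2f  BIC = %.2f  converged: %s (%d iter)\n",
              x$aic, x$bic, x$converged, x$n_iterations))
  invisible(x)
}

#' Gaussian-likelihood information criteria
#'
#' AIC and BIC under the Gaussian likelihood with the error variance profiled
#' out (`sigma^2 = rss/n`) and sigma counted in the parameter total, i.e. the
#' convention `stats::AIC()` applies to `nls`/`lm` fits:
#' `aic = n*log(2*pi*rss/n) + n + 2*(k+1)` and
#' `bic = n*log(2*pi*rss/n) + n + log(n)*(k+1)`.
#' Absolute values depend on this convention; differences between models on
#' the same data do not.
#'
#' @param fit An `swp_fit` (or anything with `n`, `k`, `rss`), or leave `fit`
#'   `NULL` and pass `n`, `k`, `rss` directly.
#' @param n,k,rss Observation count, free-coefficient count, residual sum of
#'   squares.
#' @return Named numeric vector `c(aic = , bic = )`.
#' @export
information_criteria <- function(fit = NULL, n = fit$n, k = fit$k,
                                 rss = fit$rss) {
  stopifnot(n > 0, k >= 0, rss >= 0)
  if (rss == 0) {
    warning("rss = 0: information criteria are -Inf (perfect fit)")
    return(c(aic = -Inf, bic = -Inf))
  }
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  c(aic = -2 * ll + 2 * (k + 1),
    bic = -2 * ll + log(n) * (k + 1))
}

#' Goodness of fit of an SWP model
#'
#' `r2 = 1 - rss/tss` (pseudo-R-squared about the mean observed SWP, the usual
#' report for nonlinear fits) and `rmse = sqrt(rss/n)`.
#'
#' @param fit An `swp_fit`.
#' @param data Optional observation table to evaluate on; default uses the
#'   training residuals stored in the fit.
#' @return Named numeric vector `c(r2 = , rmse = )`.
#' @export
goodness_of_fit <- function(fit, data = NULL) {
  if (is.null(data)) {
    res <- fit$residuals
    obs <- fit$fitted + res
  } else {
    pred <- extract_predictors(fit$form, data)
    obs <- data$swp
    res <- obs - predict_swp(fit$params, pred$plwp, pred$climate, pred$seasonal)
  }
  rss <- sum(res^2)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) {
    warning("total sum of squares is 0: r2 undefined")
    return(c(r2 = NA_real_, rmse = sqrt(rss / length(res))))
  }
  c(r2 = 1 - rss / tss, rmse = sqrt(rss / length(res)))
}

#' Leave-one-plot-out cross-validation
#'
#' Each distinct plot in turn is held out, the model is refitted on the
#' remaining plots, and the RMSE of the held-out plot's observations is
#' recorded. The summary is the mean and sample standard deviation of the
#' per-fold RMSEs.
#'
#' @inheritParams fit_model
#' @param group Name of the grouping column (default `"plot"`).
#' @return An object of class `swp_cv`: `folds` (data frame with the held-out
#'   id, fold size and RMSE), `rmse_mean`, `rmse_sd`, `failed` (ids of folds
#'   whose training fit failed, if any).
#' @export
leave_one_plot_out_cv <- function(form, data, init = NULL, seed = 1L,
                                  group = "plot") {
  if (is.character(form)) form <- model_form(form)
  if (!group %in% names(data)) {
    stop("grouping column `", group, "` not found", call. = FALSE)
  }
  ids <- sort(unique(data[[group]]))
  if (length(ids) < 2) stop("need at least 2 plots", call. = FALSE)
  folds <- lapply(ids, function(id) {
    test <- data[data[[group]] == id, , drop = FALSE]
    train <- data[data[[group]] != id, , drop = FALSE]
    f <- tryCatch(
      suppressWarnings(fit_model(form, train, init = init, seed = seed)),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      return(data.frame(id = id, n = nrow(test), rmse = NA_real_,
                        failed = TRUE))
    }
    g <- goodness_of_fit(f, test)
    data.frame(id = id, n = nrow(test), rmse = unname(g[["rmse"]]),
               failed = FALSE)
  })
  folds <- do.call(rbind, folds)
  if (any(folds$failed)) {
    warning(sum(folds$failed), " fold(s) failed and were excluded")
  }
  ok <- folds$rmse[!folds$failed]
  structure(list(
    folds = folds,
    rmse_mean = mean(ok),
    rmse_sd = stats::sd(ok),
    failed = folds$id[folds$failed]
  ), class = "swp_cv")
}

#' @export
print.swp_cv <- function(x, ...) {
  cat(sprintf("<swp_cv> %d folds  RMSE %.3f +/- %.3f\n",
              nrow(x$folds), x$rmse_mean, x$rmse_sd))
  invisible(x)
}

#' Variance inflation factors for a form's predictor set
#'
#' Regresses each untransformed predictor of the form (PLWP, the climate
#' covariate, the seasonal covariate) on the others and reports
#' `VIF = 1/(1 - R^2)`, the standard multicollinearity diagnostic.
#'
#' @param data Observation table carrying the form's covariate columns.
#' @param form Form object or id string (needs >= 2 predictors, i.e. M2-M5).
#' @return Named numeric vector of VIFs (all >= 1; `Inf` under perfect
#'   collinearity).
#' @export
variance_inflation <- function(data, form) {
  if (is.character(form)) form <- model_form(form)
  vars <- form_covariates(form)
  if (length(vars) < 2) {
    stop("form ", form$id, " has a single predictor; VIF undefined",
         call. = FALSE)
  }
  x <- data[vars]
  vapply(vars, function(v) {
    fml <- stats::reformulate(setdiff(vars, v), response = v)
    r2 <- summary(stats::lm(fml, data = x))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

form_formula_string <- function(form, params = NULL) {
  fmt <- function(x, digits = 4) formatC(x, digits = digits, format = "fg")
  if (is.null(params)) {
    cl <- switch(form$climate, none = "", vpd_max = " * VPD_max^p",
                 tmax = " * Tmax^p")
    se <- switch(form$seasonal, none = "", doy = " + d*DOY", gdd = " + d*GDD")
    return(sprintf("SWP = a*exp(b*PLWP)%s%s + c", cl, se))
  }
  v <- as.list(unclass(params))
  s <- sprintf("SWP = %s * exp(%s * PLWP)", fmt(v$a), fmt(v$b))
  if (form$climate != "none") {
    s <- sprintf("%s * %s^%s", s,
                 switch(form$climate, vpd_max = "VPD_max", tmax = "Tmax"),
                 fmt(v$p))
  }
  if (form$seasonal != "none") {
    s <- sprintf("%s %+g * %s", s, v$d, toupper(form$seasonal))
  }
  sprintf("%s %+g", s, v$c)
}

#' Fit and rank several model forms on the same data
#'
#' Fits each requested form, optionally cross-validates by plot, and returns
#' one row per form sorted by AIC (lowest first). Per-form failures are
#' recorded in the row rather than aborting the comparison.
#'
#' @inheritParams fit_model
#' @param forms Character vector of form ids, or list of `swp_form`s.
#' @param cv If `TRUE`, add leave-one-plot-out CV columns (requires the
#'   grouping column).
#' @param group Grouping column for CV.
#' @return A data frame of class `swp_comparison` with columns `form`,
#'   `formula`, `k`, `aic`, `bic`, `r2`, `rmse_train`, and with CV
#'   `rmse_cv_mean`, `rmse_cv_sd`; attribute `"fits"` holds the `swp_fit`s.
#' @export
compare_models <- function(forms = c("M1", "M2", "M3", "M4", "M5"), data,
                           init = NULL, seed = 1L, cv = FALSE,
                           group = "plot") {
  forms <- lapply(forms, function(f) if (is.character(f)) model_form(f) else f)
  rows <- list(); fits <- list()
  for (form in forms) {
    fit <- tryCatch(
      suppressWarnings(fit_model(form, data, init = init, seed = seed)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      bad <- data.frame(
        form = form$id, formula = NA_character_, k = NA_integer_,
        aic = NA_real_, bic = NA_real_, r2 = NA_real_, rmse_train = NA_real_,
        error = conditionMessage(fit), stringsAsFactors = FALSE)
      if (cv) {
        bad$rmse_cv_mean <- NA_real_
        bad$rmse_cv_sd <- NA_real_
      }
      rows[[form$id]] <- bad
      next
    }
    fits[[form$id]] <- fit
    row <- data.frame(
      form = form$id,
      formula = form_formula_string(form, fit$params),
      k = fit$k, aic = fit$aic, bic = fit$bic, r2 = fit$r2,
      rmse_train = fit$rmse, error = NA_character_,
      stringsAsFactors = FALSE)
    if (cv) {
      cvr <- tryCatch(
        suppressWarnings(
          leave_one_plot_out_cv(form, data, init = init, seed = seed,
                                group = group)),
        error = function(e) NULL
      )
      row$rmse_cv_mean <- if (is.null(cvr)) NA_real_ else cvr$rmse_mean
      row$rmse_cv_sd <- if (is.null(cvr)) NA_real_ else cvr$rmse_sd
    }
    rows[[form$id]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("swp_comparison", class(out))
  out
}

#' Per-group (cultivar) fits of one form
#'
#' Fits the form separately within each level of `group_key` and reports the
#' pooled training RMSE of the grouped fits next to the all-data fit's RMSE.
#' Extra per-group coefficients cannot worsen the pooled training fit, so
#' `rmse_delta = rmse_pooled - rmse_all <= 0` up to optimizer tolerance.
#'
#' @inheritParams fit_model
#' @param group_key Grouping column, default `"cultivar"`.
#' @param min_n Minimum observations a group needs to be fitted (default
#'   `k + 2`); smaller groups are skipped with a warning.
#' @return List with `fits` (named per-group `swp_fit`s), `fit_all`,
#'   `rmse_pooled`, `rmse_all`, `rmse_delta`, `skipped`.
#' @export
grouped_fit <- function(form, data, group_key = "cultivar", init = NULL,
                        seed = 1L, min_n = NULL) {
  if (is.character(form)) form <- model_form(form)
  if (!group_key %in% names(data)) {
    stop("grouping column `", group_key, "` not found", call. = FALSE)
  }
  k <- length(form$par_names)
  if (is.null(min_n)) min_n <- k + 2
  fit_all <- suppressWarnings(fit_model(form, data, init = init, seed = seed))
  ids <- sort(unique(data[[group_key]]))
  fits <- list(); skipped <- character()
  for (id in ids) {
    sub <- data[data[[group_key]] == id, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning("group `", id, "` has ", nrow(sub), " rows (< ", min_n,
              "); skipped")
      skipped <- c(skipped, as.character(id))
      next
    }
    fits[[as.character(id)]] <-
      suppressWarnings(fit_model(form, sub, init = init, seed = seed))
  }
  used <- !data[[group_key]] %in% skipped
  rss_pooled <- sum(vapply(fits, function(f) f$rss, numeric(1)))
  n_pooled <- sum(vapply(fits, function(f) f$n, numeric(1)))
  list(
    fits = fits, fit_all = fit_all,
    rmse_pooled = sqrt(rss_pooled / n_pooled),
    rmse_all = fit_all$rmse,
    rmse_delta = sqrt(rss_pooled / n_pooled) - fit_all$rmse,
    skipped = skipped
  )
}
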