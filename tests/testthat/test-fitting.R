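test_that("noiseless data are recovered exactly and refits are deterministic", {
  d <- simulate_from_model("M1", n = 200, seed = 1, noise_sd = 0)
  # rss = 0 flags the information criteria; that is the designed behavior
  fit <- suppressWarnings(fit_model("M1", d, seed = 1))
  truth <- unclass(attr(d, "truth"))
  expect_true(fit$converged)
  expect_equal(unclass(fit$params), truth, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_lt(fit$rmse, 1e-6)

  # same data, same seed -> identical result
  fit2 <- suppressWarnings(fit_model("M1", d, seed = 1))
  expect_identical(unclass(fit$params), unclass(fit2$params))
  expect_identical(fit$aic, fit2$aic)
})

test_that("coefficients of the full seasonal model are recovered from noisy data", {
  d <- simulate_from_model("M5", n = 2000, seed = 7)
  fit <- suppressWarnings(fit_model("M5", d, seed = 7))
  truth <- unclass(attr(d, "truth"))
  est <- unclass(fit$params)
  # exponent, seasonal slope and PLWP rate are well identified at n = 2000
  expect_equal(est[["p"]], truth[["p"]], tolerance = 0.10)
  expect_equal(est[["d"]], truth[["d"]], tolerance = 0.10)
  expect_equal(est[["b"]], truth[["b"]], tolerance = 0.10)
  # sign pattern of the published fits
  expect_gt(est[["a"]], 0); expect_gt(est[["b"]], 0)
  expect_lt(est[["p"]], 0); expect_lt(est[["d"]], 0)
  # rmse estimates the generating noise sd
  expect_equal(fit$rmse, 0.164, tolerance = 0.05)
})

test_that("degenerate predictors raise identifiability errors", {
  d <- data.frame(plwp = rep(-0.3, 50), swp = rnorm(50, -1, 0.1))
  expect_error(fit_model("M1", d, seed = 1), "identifiability")
  d2 <- simulate_from_model("M1", n = 5, seed = 2)
  expect_error(fit_model("M5", d2[1:4, ], seed = 1), "observations|lacks")
})

test_that("information criteria follow the Gaussian profile-likelihood convention", {
  ic <- information_criteria(n = 100, k = 2, rss = 3.7)
  expect_equal(ic[["bic"]] - ic[["aic"]], (log(100) - 2) * 3, tolerance = 1e-12)
  # agreement with stats::AIC on an actual nls fit
  set.seed(4)
  d <- data.frame(x = runif(60, -1, 0))
  d$y <- 1.2 * exp(3 * d$x) - 1 + rnorm(60, 0, 0.1)
  nf <- nls(y ~ a * exp(b * x) + c, data = d,
            start = list(a = 1, b = 2, c = -1))
  ours <- information_criteria(n = 60, k = 3, rss = sum(resid(nf)^2))
  expect_equal(ours[["aic"]], AIC(nf), tolerance = 1e-8)
  expect_equal(ours[["bic"]], BIC(nf), tolerance = 1e-8)
  expect_warning(information_criteria(n = 10, k = 2, rss = 0), "rss = 0")
})

test_that("an extra useless parameter is penalized by AIC on average", {
  # data generated without any climate effect: the Tmax power law is noise
  deltas <- vapply(1:25, function(s) {
    d <- simulate_from_model("M1", n = 300, seed = 100 + s)
    set.seed(s); d$tmax <- runif(300, 23.8, 38.9)
    f1 <- suppressWarnings(fit_model("M1", d, seed = s))
    f3 <- suppressWarnings(fit_model("M3", d, seed = s))
    f3$aic - f1$aic
  }, numeric(1))
  expect_gt(mean(deltas), 0)     # the bigger model loses on average
  expect_lt(mean(deltas), 3)     # by roughly the 2-point penalty less the
                                 # chi-square(1) improvement
})

test_that("goodness of fit matches brute-force r2 and rmse", {
  d <- simulate_from_model("M5", n = 400, seed = 12)
  fit <- suppressWarnings(fit_model("M5", d, seed = 12))
  g <- goodness_of_fit(fit)
  pred <- predict_swp(fit$params, d$plwp, d$tmax, d$doy)
  rss <- sum((d$swp - pred)^2)
  expect_equal(g[["rmse"]], sqrt(rss / 400), tolerance = 1e-10)
  expect_equal(g[["r2"]], 1 - rss / sum((d$swp - mean(d$swp))^2),
               tolerance = 1e-10)
  # field-range signal-to-noise puts r2 in the usual band
  expect_gt(g[["r2"]], 0.7)
  expect_lt(g[["r2"]], 0.9)
})

test_that("leave-one-plot-out CV partitions plots into folds", {
  st <- quick_study(21)
  obs <- st$observations
  cv <- suppressWarnings(leave_one_plot_out_cv("M5", obs, seed = 1))
  expect_equal(nrow(cv$folds), length(unique(obs$plot)))
  expect_setequal(cv$folds$id, unique(obs$plot))
  # folds partition the data
  expect_equal(sum(cv$folds$n), nrow(obs))
  expect_true(all(cv$folds$rmse >= 0))
  expect_equal(cv$rmse_mean, mean(cv$folds$rmse), tolerance = 1e-12)
  expect_equal(cv$rmse_sd, sd(cv$folds$rmse), tolerance = 1e-12)

  # homogeneous noiseless plots: every fold predicts the held-out plot exactly
  d <- simulate_from_model("M1", n = 40, seed = 3, noise_sd = 0)
  d$plot <- rep(c("A", "B", "C", "D"), each = 10)
  cv0 <- leave_one_plot_out_cv("M1", d, seed = 1)
  expect_true(all(cv0$folds$rmse < 1e-6))

  expect_error(leave_one_plot_out_cv("M1", d[d$plot == "A", ], seed = 1),
               "at least 2 plots")
})

test_that("variance inflation factors match the auxiliary-regression oracle", {
  # orthogonal by construction
  d <- expand.grid(plwp = seq(-0.8, -0.1, length.out = 10),
                   tmax = seq(24, 38, length.out = 10))
  v <- variance_inflation(d, "M3")
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)

  # duplicated predictor -> infinite VIF
  d2 <- data.frame(plwp = runif(50, -0.9, 0))
  d2$tmax <- 30 - 10 * d2$plwp
  expect_true(all(suppressWarnings(variance_inflation(d2, "M3")) == Inf))

  # independently drawn predictors stay below the field's 1.2 criterion,
  # and match a brute-force recomputation
  set.seed(8)
  d3 <- data.frame(plwp = runif(500, -0.9, 0), tmax = runif(500, 23.8, 38.9),
                   doy = runif(500, 159, 257))
  v3 <- variance_inflation(d3, "M5")
  expect_true(all(v3 >= 1))
  expect_true(all(v3 < 1.2))
  r2_plwp <- summary(lm(plwp ~ tmax + doy, data = d3))$r.squared
  expect_equal(v3[["plwp"]], 1 / (1 - r2_plwp), tolerance = 1e-12)

  expect_error(variance_inflation(d3, "M1"), "single predictor")
})

test_that("model comparison ranks by AIC and tolerates per-form failures", {
  st <- quick_study(31)
  obs <- st$observations
  cmp <- suppressWarnings(compare_models(c("M1", "M3", "M5"), obs, seed = 1))
  expect_equal(nrow(cmp), 3L)
  expect_true(!is.unsorted(cmp$aic))
  expect_equal(cmp$form[1], "M5")  # generating form wins

  one <- suppressWarnings(compare_models("M3", obs, seed = 1))
  expect_equal(nrow(one), 1L)

  # a form whose covariate is missing fails in-row, not fatally
  obs2 <- obs[setdiff(names(obs), "vpd_max")]
  cmp2 <- suppressWarnings(compare_models(c("M1", "M2"), obs2, seed = 1))
  expect_equal(nrow(cmp2), 2L)
  expect_true(any(!is.na(cmp2$error)))
})

test_that("per-cultivar fits can only improve pooled training RMSE", {
  # two groups generated with genuinely different PLWP rates
  set.seed(14)
  mk <- function(b, n) {
    d <- data.frame(plwp = runif(n, -0.9, 0))
    pp <- swp_params("M1", a = 1.2, b = b, c = -1.6)
    d$swp <- predict_swp(pp, d$plwp) + rnorm(n, 0, 0.1)
    d
  }
  d <- rbind(cbind(mk(2.5, 300), cultivar = "Merlot"),
             cbind(mk(5.5, 300), cultivar = "Cabernet-Sauvignon"))
  gf <- suppressWarnings(grouped_fit("M1", d, seed = 1))
  expect_lt(gf$rmse_pooled, gf$rmse_all)           # real group signal
  expect_lte(gf$rmse_delta, 1e-8)

  # identical truth in both groups: no gain beyond noise
  d2 <- rbind(cbind(mk(4, 300), cultivar = "A"),
              cbind(mk(4, 300), cultivar = "B"))
  gf2 <- suppressWarnings(grouped_fit("M1", d2, seed = 1))
  expect_equal(gf2$rmse_pooled, gf2$rmse_all, tolerance = 0.02)

  # single group reduces to fit_model
  d3 <- cbind(mk(4, 200), cultivar = "only")
  gf3 <- suppressWarnings(grouped_fit("M1", d3, seed = 1))
  expect_equal(unclass(gf3$fits$only$params), unclass(gf3$fit_all$params),
               tolerance = 1e-8)
})

test_that("AIC ordering is invariant to shifting all SWP values", {
  st <- quick_study(41)
  obs <- st$observations
  cmp1 <- suppressWarnings(compare_models(c("M1", "M3", "M5"), obs, seed = 2))
  obs2 <- obs; obs2$swp <- obs2$swp - 0.5
  cmp2 <- suppressWarnings(compare_models(c("M1", "M3", "M5"), obs2, seed = 2))
  expect_equal(cmp1$form, cmp2$form)
  expect_equal(cmp1$aic, cmp2$aic, tolerance = 1e-3)
})
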