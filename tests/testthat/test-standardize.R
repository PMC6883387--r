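test_that("temperature standardization is the exact inverse of the Tmax model", {
  # worked value with the published coefficients
  expect_equal(standardize_swp_temperature(-0.8, tmax = 35, t_s = 30),
               -0.689, tolerance = 1e-3)
  # identity at the reference conditions
  expect_equal(standardize_swp_temperature(-0.8, 32, 32), -0.8)

  p3 <- reference_params("M3")
  # predicting at tmax then standardizing to t_s equals predicting at t_s
  plwp <- seq(-0.9, -0.05, length.out = 9)
  s35 <- predict_swp(p3, plwp, 35)
  expect_equal(standardize_swp_temperature(s35, 35, 28, p3),
               predict_swp(p3, plwp, 28), tolerance = 1e-12)

  # round trip and semigroup composition
  x <- standardize_swp_temperature(-0.8, 35, 30)
  expect_equal(standardize_swp_temperature(x, 30, 35), -0.8, tolerance = 1e-12)
  ab <- standardize_swp_temperature(
    standardize_swp_temperature(-0.8, 35, 31), 31, 27)
  expect_equal(ab, standardize_swp_temperature(-0.8, 35, 27), tolerance = 1e-12)

  # cooler reference -> less negative SWP; monotone in swp
  expect_gt(standardize_swp_temperature(-0.8, 35, 30), -0.8)
  sw <- seq(-1.5, -0.3, by = 0.1)
  out <- standardize_swp_temperature(sw, 35, 30)
  expect_true(all(diff(out) > 0))

  # below the asymptote the amplitude term is invalid
  expect_warning(bad <- standardize_swp_temperature(-1.7, 35, 30), "asymptote")
  expect_true(is.na(bad))
  expect_warning(standardize_swp_temperature(-0.8, 35, 8), "sanity band")
  expect_error(standardize_swp_temperature(-0.8, 35, 30,
                                           reference_params("M5")),
               "M3-form")
})

test_that("temperature+DOY standardization inverts the seasonal model", {
  expect_equal(
    standardize_swp_temperature_doy(-0.9, tmax = 34, doy = 240,
                                    t_s = 30, doy_s = 200),
    -0.566, tolerance = 1e-3)
  expect_equal(standardize_swp_temperature_doy(-0.9, 34, 240, 34, 240), -0.9)

  p5 <- reference_params("M5")
  plwp <- seq(-0.85, -0.05, length.out = 7)
  obs <- predict_swp(p5, plwp, 36, 250)
  expect_equal(
    standardize_swp_temperature_doy(obs, 36, 250, 28, 180, p5),
    predict_swp(p5, plwp, 28, 180), tolerance = 1e-12)

  # round trip
  x <- standardize_swp_temperature_doy(-0.9, 34, 240, 30, 200)
  expect_equal(standardize_swp_temperature_doy(x, 30, 200, 34, 240), -0.9,
               tolerance = 1e-12)

  # with doy_s = doy it reduces to the temperature-only operation with the
  # same exponent; with d = 0 it degenerates exactly
  p5_d0 <- swp_params("M5", a = 20.164, b = 3.890, p = -0.819, d = 0, c = -1.628)
  p3_eq <- swp_params("M3", a = 20.164, b = 3.890, p = -0.819, c = -1.628)
  expect_equal(
    standardize_swp_temperature_doy(-0.8, 35, 200, 30, 123, p5_d0),
    standardize_swp_temperature(-0.8, 35, 30, p3_eq), tolerance = 1e-14)

  expect_error(standardize_swp_temperature_doy(-0.9, 34, 400, 30, 200),
               "\\[1, 366\\]")
  expect_error(standardize_swp_temperature_doy(-0.9, 34, 240, 30, 200,
                                               reference_params("M3")),
               "M5-form")
})

test_that("consecutive-day pairing matches the field design", {
  toy <- make_toy_obs()
  pairs <- pair_consecutive_days(toy)
  # plot A has two campaigns of paired days; plot B has none
  expect_equal(nrow(pairs), 2L)
  expect_true(all(pairs$gap_days == 1L))
  expect_true(all(pairs$plot_ref == pairs$plot_other))
  expect_true(all(pairs$vine_ref == pairs$vine_other))
  expect_true(all(pairs$date_ref < pairs$date_other))
  expect_equal(attr(pairs, "n_skipped"), 2L)  # B's two singleton days

  # missing day 2 drops the campaign
  toy2 <- toy[-2, ]
  pairs2 <- pair_consecutive_days(toy2)
  expect_equal(nrow(pairs2), 1L)

  # generated study with missingness: count equals brute-force enumeration
  st <- generate_study(synthetic_study_config(seed = 17, n_plots = 6,
                                              n_vines_per_plot = 3,
                                              missingness = 0.05))
  obs <- st$observations
  pairs3 <- pair_consecutive_days(obs)
  brute <- 0L
  for (v in unique(obs$vine)) {
    sub <- obs[obs$vine == v, ]
    for (i in seq_len(nrow(sub))) {
      brute <- brute + sum(as.Date(sub$date) == as.Date(sub$date[i]) + 1L)
    }
  }
  expect_equal(nrow(pairs3), brute)
  # within a generated pair the night PLWP is shared exactly
  expect_true(all(abs(pairs3$delta_plwp) < 1e-12))
})

test_that("matched-PLWP pairing enumerates all qualifying within-plot pairs", {
  toy <- make_toy_obs()
  # B's two observations: delta = 0.003 <= 0.005, 10 days apart
  pairs <- pair_matched_plwp(toy, max_delta_plwp = 0.005, min_gap_days = 7)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$plot_ref, "B")

  # inclusive threshold: exactly 0.005 qualifies, 0.006 does not
  two <- data.frame(plot = "X", vine = "X-V1", date = as.Date("2018-06-01") + c(0, 7),
                    doy = c(152, 159), plwp = c(-0.2, -0.205), swp = c(-0.6, -0.7),
                    tmax = c(30, 33))
  expect_equal(nrow(pair_matched_plwp(two)), 1L)
  two$plwp[2] <- -0.206
  expect_equal(nrow(pair_matched_plwp(two)), 0L)
  two$plwp[2] <- -0.205
  two$date[2] <- two$date[1] + 6   # below the week gap
  expect_equal(nrow(pair_matched_plwp(two)), 0L)
  expect_equal(nrow(pair_matched_plwp(two, min_gap_days = 3)), 1L)

  # exhaustive oracle over all within-plot ordered pairs
  st <- quick_study(19)
  obs <- st$observations
  got <- pair_matched_plwp(obs, 0.005, 7)
  brute <- 0L
  for (pl in unique(obs$plot)) {
    sub <- obs[obs$plot == pl, ]
    n <- nrow(sub)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      # enumerate unordered pairs; ref is the earlier date
      lo <- if (as.Date(sub$date[i]) <= as.Date(sub$date[j])) i else j
      hi <- i + j - lo
      gap <- as.integer(as.Date(sub$date[hi]) - as.Date(sub$date[lo]))
      if (gap >= 7 && abs(sub$plwp[hi] - sub$plwp[lo]) <= 0.005) {
        brute <- brute + 1L
      }
    }
  }
  expect_equal(nrow(got), brute)
  expect_true(all(got$gap_days >= 7))
  expect_true(all(abs(got$delta_plwp) <= 0.005))
})

test_that("standardization removes the climate signal from paired days", {
  # noiseless pairs generated from the Tmax model at constant PLWP:
  # standardization recovers the reference day exactly
  set.seed(55)
  p3 <- reference_params("M3")
  tm1 <- runif(30, 24, 30); tm2 <- tm1 + runif(30, 2, 8)
  plwp <- rep(seq(-0.8, -0.1, length.out = 6), 5)
  pairs <- data.frame(
    plot_ref = "A", swp_ref = predict_swp(p3, plwp, tm1), tmax_ref = tm1,
    swp_other = predict_swp(p3, plwp, tm2), tmax_other = tm2)
  rep0 <- evaluate_standardization(pairs, "temperature", p3)
  expect_lt(rep0$rmse_standardized, 1e-12)
  expect_equal(rep0$pct_improvement, 100)

  # identical climate on both days: standardization is the identity
  pairs_same <- pairs
  pairs_same$tmax_other <- pairs_same$tmax_ref
  pairs_same$swp_other <- pairs_same$swp_ref + rnorm(30, 0, 0.05)
  rep1 <- evaluate_standardization(pairs_same, "temperature", p3)
  expect_equal(rep1$pct_improvement, 0, tolerance = 1e-10)

  # on a noisy synthetic study the report matches a brute-force recomputation
  st <- quick_study(23)
  pc <- pair_consecutive_days(st$observations)
  p5 <- reference_params("M5")
  rep2 <- suppressWarnings(evaluate_standardization(pc, "temperature_doy", p5))
  std <- suppressWarnings(
    standardize_swp_temperature_doy(pc$swp_other, pc$tmax_other, pc$doy_other,
                                    pc$tmax_ref, pc$doy_ref, p5))
  ok <- !is.na(std)
  expect_equal(rep2$rmse_unstandardized,
               sqrt(mean((pc$swp_ref[ok] - pc$swp_other[ok])^2)),
               tolerance = 1e-12)
  expect_equal(rep2$rmse_standardized,
               sqrt(mean((pc$swp_ref[ok] - std[ok])^2)), tolerance = 1e-12)
  expect_equal(rep2$n_excluded, sum(!ok))
})
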