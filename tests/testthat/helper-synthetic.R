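# shared fixtures, all generated in code

# small observation table with known structure for pairing tests
make_toy_obs <- function() {
  data.frame(
    plot = c("A", "A", "A", "A", "B", "B"),
    vine = c("A-V1", "A-V1", "A-V1", "A-V1", "B-V1", "B-V1"),
    cultivar = "Merlot",
    date = as.Date(c("2018-06-10", "2018-06-11", "2018-07-10", "2018-07-11",
                     "2018-06-10", "2018-06-20")),
    doy = c(161, 162, 191, 192, 161, 171),
    plwp = c(-0.10, -0.10, -0.30, -0.30, -0.20, -0.203),
    swp = c(-0.50, -0.60, -0.90, -1.00, -0.70, -0.80),
    tmax = c(28, 32, 30, 35, 27, 33)
  )
}

# direct simulation from a reference model over the field predictor ranges
simulate_from_model <- function(id, n, seed, noise_sd = NULL) {
  params <- reference_params(id)
  if (is.null(noise_sd)) noise_sd <- attr(params, "rmse")
  form <- attr(params, "form")
  set.seed(seed)
  d <- data.frame(plwp = runif(n, -0.9, 0))
  if (form$climate == "tmax") d$tmax <- runif(n, 23.8, 38.9)
  if (form$climate == "vpd_max") d$vpd_max <- runif(n, 1.2, 5.6)
  if (form$seasonal == "doy") d$doy <- runif(n, 159, 257)
  clim <- if (form$climate != "none") d[[form$climate]] else NULL
  seas <- if (form$seasonal != "none") d$doy else NULL
  d$swp <- predict_swp(params, d$plwp, clim, seas) + rnorm(n, 0, noise_sd)
  attr(d, "truth") <- params
  d
}

# small study for tests that only need structure, not statistical power
quick_study <- function(seed, ...) {
  generate_study(synthetic_study_config(
    seed = seed, n_plots = 6L, n_vines_per_plot = 2L, ...))
}
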