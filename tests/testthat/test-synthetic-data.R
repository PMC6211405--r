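test_that("scenario validation names the offending field", {
  expect_error(den_scenario(n_parks = 0), "n_parks")
  expect_error(den_scenario(temp_params = list(ar1_coefficient = 1)),
               "ar1_coefficient")
  expect_error(den_scenario(event_params = list(t0 = 100, T = 50)), "t0")
  expect_error(den_scenario(snow_params =
                              list(snowfall_probability_at_subzero = 2)),
               "snowfall_probability")
})

test_that("no snowfall flux means snow is identically zero", {
  sc <- tiny_scenario(n_parks = 1, years = 2000:2002,
                      snow_params = list(snowfall_probability_at_subzero = 0))
  expect_true(all(simulate_climate(sc)$snow_cm == 0))
})

test_that("noise-free temperature equals the closed-form seasonal cosine", {
  sc <- noiseless_scenario()
  clim <- simulate_climate(sc)
  tp <- sc$temp_params
  ## solstice/equinox-adjacent days against the closed form
  for (d in c(80, 172, 266, 355)) {
    expect_equal(clim$temperature_c[clim$doy == d],
                 tp$annual_mean +
                   tp$seasonal_amplitude * cos(2 * pi * (d - 196) / 365),
                 tolerance = 1e-12)
  }
})

test_that("warming trend of +0.034 degC/yr is recovered from annual means", {
  ## tolerance derived from the generator's own noise: the AR(1) daily
  ## residual (sd 2, ar1 0.8) averages to an annual-mean sd of about
  ## 2/sqrt(0.36)/sqrt(365/9) ~ 0.5 degC, giving a slope SE of about
  ## 0.003 degC/yr over 69 years; +/-0.01 is > 3 SE.
  sc <- den_scenario("first_exit", n_parks = 2, years = 1946:2014, seed = 4)
  clim <- simulate_climate(sc)
  ann <- dplyr::summarise(dplyr::group_by(clim, .data$park_id, .data$year),
                          t = mean(.data$temperature_c), .groups = "drop")
  for (p in unique(ann$park_id)) {
    sub <- ann[ann$park_id == p, ]
    slope <- coef(lm(t ~ year, sub))[["year"]]
    expect_lt(abs(slope - 0.034), 0.01)
  }
})

test_that("snow is non-negative and spiky-up/slow-down in shape", {
  clim <- simulate_climate(tiny_scenario(seed = 3))
  expect_true(all(clim$snow_cm >= 0))
  ## increases only via snowfall spikes; decreases bounded by compaction+melt
  one <- clim[clim$park_id == "park01", ]
  dx <- diff(one$snow_cm)
  expect_true(any(dx > 1))    # spiky accumulation happens
  expect_true(any(dx < 0))    # decay happens
})

test_that("climate simulation is deterministic and stable under park addition", {
  sc2 <- tiny_scenario(n_parks = 2, seed = 9)
  sc3 <- tiny_scenario(n_parks = 3, seed = 9)
  c2 <- simulate_climate(sc2)
  c3 <- simulate_climate(sc3)
  expect_identical(c2, simulate_climate(sc2))
  ## adding a park leaves the existing parks' draws untouched
  expect_identical(c2$temperature_c,
                   c3$temperature_c[c3$park_id %in% c("park01", "park02")])
})

test_that("coefficient functions honour explicit vectors and zero deviation", {
  L <- 150
  sc <- tiny_scenario(coef_params = list(alpha = rep(0, L), beta = rep(0, L),
                                         park_deviation_variance = 0))
  cf <- simulate_coefficient_functions(sc)
  expect_equal(cf$alpha, rep(0, L))
  for (i in 1:3) expect_equal(cf$a[i, ], cf$alpha)
  expect_error(simulate_coefficient_functions(
    tiny_scenario(coef_params = list(alpha = rep(0, 10)))), "length")
})

test_that("GP-drawn coefficients have the kernel's pointwise variance", {
  ## Monte-Carlo check against the kernel diagonal: 1000 independent draws
  sc0 <- tiny_scenario(coef_params = list(
    alpha = list(variance = 1, length_scale = 10),
    park_deviation_variance = 0))
  draws <- vapply(1:1000, function(s) {
    sc0$seed <- s
    simulate_coefficient_functions(sc0)$alpha[c(10, 75, 140)]
  }, numeric(3))
  v <- apply(draws, 1, var)
  expect_true(all(v > 0.9 & v < 1.1))
})

test_that("event dates follow the stated linear model exactly in the noise-free limit", {
  L <- 150
  sc <- tiny_scenario(n_parks = 2, years = 2000:2004,
                      event_params = list(park_intercept_sd = 0,
                                          residual_sd_mean = 1e-12,
                                          residual_sd_spread = 0),
                      coef_params = list(alpha = rep(0, L), beta = rep(0, L),
                                         park_deviation_variance = 0))
  clim <- simulate_climate(sc)
  cf <- simulate_coefficient_functions(sc)
  ev <- simulate_event_dates(clim, cf, sc)
  expect_true(all(ev$day_of_year == round(sc$event_params$mu)))

  ## single-term sum: alpha(d) = -0.3 at one day shifts the mean by
  ## -0.3 x (that day's anomaly)
  alpha1 <- rep(0, L); alpha1[60] <- -0.3
  sc1 <- tiny_scenario(n_parks = 2, years = 2000:2004,
                       event_params = list(park_intercept_sd = 0,
                                           residual_sd_mean = 1e-12,
                                           residual_sd_spread = 0),
                       coef_params = list(alpha = alpha1, beta = rep(0, L),
                                          park_deviation_variance = 0))
  ev1 <- simulate_event_dates(clim, cf1 <- simulate_coefficient_functions(sc1), sc1)
  anom <- center_climate(clim)
  a60 <- anom[anom$doy == 60, ]
  key <- paste(a60$park_id, a60$year)
  expect_equal(ev1$mean_day - sc$event_params$mu,
               -0.3 * a60$temp_anom[match(paste(ev1$park_id, ev1$year), key)],
               tolerance = 1e-10)
})

test_that("per-park mean dates concentrate on mu + r_i", {
  sc <- tiny_scenario(n_parks = 3, years = 1975:2014, seed = 6,
                      coef_params = list(alpha = rep(0, 150),
                                         beta = rep(0, 150),
                                         park_deviation_variance = 0))
  clim <- simulate_climate(sc)
  ev <- simulate_event_dates(clim, simulate_coefficient_functions(sc), sc)
  tr <- attr(ev, "truth")
  for (p in unique(ev$park_id)) {
    m <- mean(ev$day_of_year[ev$park_id == p])
    expect_lt(abs(m - (tr$mu + tr$r[p])), 2 * tr$sigma[p] / sqrt(40) + 0.5)
  }
})

test_that("simulated date moments converge to the analytic values (long-run)", {
  ## alpha = beta = 0: mean = mu + r_1, sd = sigma_1; checked at 2000 years
  ## within 3 standard errors (plus rounding slack)
  sc <- den_scenario("first_exit", n_parks = 1, years = 1:2000, seed = 2,
                     temp_params = list(trend = 0),
                     coef_params = list(alpha = rep(0, 150),
                                        beta = rep(0, 150),
                                        park_deviation_variance = 0))
  clim <- simulate_climate(sc)
  ev <- simulate_event_dates(clim, simulate_coefficient_functions(sc), sc)
  tr <- attr(ev, "truth")
  n <- nrow(ev)
  se_mean <- tr$sigma[1] / sqrt(n)
  expect_lt(abs(mean(ev$day_of_year) - (tr$mu + tr$r[1])), 3 * se_mean + 0.3)
  se_sd <- tr$sigma[1] / sqrt(2 * (n - 1))
  expect_lt(abs(sd(ev$day_of_year) - tr$sigma[1]), 3 * se_sd + 0.3)
})

test_that("out-of-season dates are retained but flagged", {
  L <- 150
  sc <- tiny_scenario(n_parks = 2, years = 2000:2004,
                      event_params = list(mu = 148, park_intercept_sd = 0,
                                          residual_sd_mean = 8,
                                          residual_sd_spread = 0),
                      coef_params = list(alpha = rep(0, L), beta = rep(0, L),
                                         park_deviation_variance = 0))
  clim <- simulate_climate(sc)
  ev <- simulate_event_dates(clim, simulate_coefficient_functions(sc), sc)
  expect_true(any(ev$flagged))
  expect_equal(nrow(ev), 10)   # nothing dropped
  expect_true(all(ev$flagged == (ev$day_of_year < 1 | ev$day_of_year > 150)))
})

test_that("missing climate coverage is a coverage error naming park-years", {
  sc <- tiny_scenario(n_parks = 2, years = 2000:2002)
  clim <- simulate_climate(sc)
  clim_cut <- clim[!(clim$park_id == "park02" & clim$year == 2001 &
                       clim$doy > 100), ]
  expect_error(simulate_event_dates(clim_cut,
                                    simulate_coefficient_functions(sc), sc),
               "park02/2001")
})
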