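## small shared fixture: 3 parks x 8 years, short season
em_fixture <- function(seed = 5, t0 = 60, T = 79, alpha = NULL) {
  L <- T - t0 + 1
  sc <- den_scenario("first_exit", n_parks = 3, years = 2000:2007,
                     seed = seed,
                     event_params = list(t0 = t0, T = T, mu = 70,
                                         park_intercept_sd = 6,
                                         residual_sd_mean = 4,
                                         residual_sd_spread = 0.5),
                     coef_params = list(alpha = if (is.null(alpha)) rep(0, L)
                                                else alpha,
                                        beta = rep(0, L),
                                        park_deviation_variance = 0))
  clim <- simulate_climate(sc)
  ev <- simulate_event_dates(clim, simulate_coefficient_functions(sc), sc)
  list(sc = sc, clim = clim, ev = ev)
}

test_that("fixed-hyperparameter posterior matches the closed-form oracle", {
  fx <- list(s_alpha = 0.05, s_beta = 0.02, l_ab_global = 5, s_a = 0.02,
             s_b = 0.01, l_ab_park = 5, sigma_r = 8, sigma = c(9, 10, 11),
             mu = 70)
  f <- em_fixture()
  fit <- fit_event_model(f$ev, f$clim, t0 = 60, T = 79, fixed = fx,
                         sampler = list(n_fdraws = 5, seed = 1),
                         representation = "exact")
  oracle <- event_posterior_oracle(f$ev, f$clim, 60, 79, fx)
  expect_lt(max(abs(fit$analytic$alpha_mean - oracle$alpha)), 1e-6)
  ## with mu free and a Normal prior, mu's posterior mean matches too
  fx2 <- fx; fx2$mu <- NULL
  fit2 <- fit_event_model(f$ev, f$clim, t0 = 60, T = 79, fixed = fx2,
                          priors = list(mu_mean = 68, mu_sd = 20),
                          sampler = list(n_fdraws = 5, seed = 1),
                          representation = "exact")
  oracle2 <- event_posterior_oracle(f$ev, f$clim, 60, 79, fx,
                                    mu_prior = list(mean = 68, sd = 20))
  expect_lt(abs(fit2$analytic$mu_mean - oracle2$mu), 1e-6)
  expect_lt(max(abs(fit2$analytic$alpha_mean - oracle2$alpha)), 1e-6)
})

test_that("the reduced-rank representation tracks the exact one closely", {
  fx <- list(s_alpha = 0.05, s_beta = 0.02, l_ab_global = 6, s_a = 0.02,
             s_b = 0.01, l_ab_park = 6, sigma_r = 8, sigma = c(9, 10, 11),
             mu = 70)
  f <- em_fixture()
  fe <- fit_event_model(f$ev, f$clim, t0 = 60, T = 79, fixed = fx,
                        sampler = list(n_fdraws = 5), representation = "exact")
  fl <- fit_event_model(f$ev, f$clim, t0 = 60, T = 79, fixed = fx,
                        sampler = list(n_fdraws = 5),
                        representation = "low_rank", rank = 80)
  ## a 20-day grid is the worst case for the boundary correction; the
  ## low-rank path is only selected automatically on grids > 60 days
  expect_lt(max(abs(fe$analytic$alpha_mean - fl$analytic$alpha_mean)), 2e-3)
})

test_that("window-sum credibility matches exhaustive hand counting", {
  ## 5-day grid, 8 explicit hand-written draws
  A <- rbind(c( 1,  1,  1,  1,  1),
             c(-1, -1, -1, -1, -1),
             c( 1, -1,  1, -1,  1),
             c( 2, -1, -1,  0,  3),
             c(-2,  1,  1,  1, -1),
             c( 0,  0,  0,  0,  0),
             c(-1,  2, -3,  4, -5),
             c( 5, -4,  3, -2,  1))
  fit <- structure(list(grid = 1:5,
                        draws = list(alpha = A, beta = A * 0)),
                   class = "event_model_fit")
  surf <- suppressWarnings(window_sum_credibility(fit, "alpha"))
  for (t1 in 1:5) for (t2 in t1:5) {
    hand <- mean(rowSums(A[, t1:t2, drop = FALSE]) >= 0)
    expect_equal(unname(surf[t1, t2]), hand)
  }
  expect_true(all(is.na(surf[lower.tri(surf)])))
  expect_true(all(surf[upper.tri(surf, diag = TRUE)] >= 0 &
                  surf[upper.tri(surf, diag = TRUE)] <= 1))
})

test_that("credibility surface limits: symmetric draws ~ 0.5, positive draws = 1", {
  set.seed(2)
  S <- 2000
  sym <- matrix(rnorm(S * 4), S, 4)
  fit_sym <- structure(list(grid = 1:4, draws = list(alpha = sym)),
                       class = "event_model_fit")
  surf <- window_sum_credibility(fit_sym, "alpha")
  expect_true(all(abs(surf[upper.tri(surf, diag = TRUE)] - 0.5) <
                    4 * attr(surf, "mc_se")))
  pos <- matrix(abs(rnorm(S * 4)) + 0.01, S, 4)
  fit_pos <- structure(list(grid = 1:4, draws = list(alpha = pos)),
                       class = "event_model_fit")
  expect_true(all(window_sum_credibility(fit_pos, "alpha")[
    upper.tri(surf, diag = TRUE)] == 1))
})

test_that("surface diagonal is the complement of pointwise negativity", {
  set.seed(3)
  A <- matrix(rnorm(600 * 6, mean = rep(c(-1, 0, 1), each = 2)), 600, 6,
              byrow = TRUE)
  fit <- structure(list(grid = 1:6, draws = list(alpha = A)),
                   class = "event_model_fit")
  surf <- window_sum_credibility(fit, "alpha")
  pw <- pointwise_sign_credibility(fit, "alpha")
  expect_equal(unname(diag(surf)), unname(1 - pw$prob))  # no exact zeros drawn
})

test_that("pointwise sign credibility reports maximal runs", {
  A <- matrix(rnorm(1000 * 30), 1000, 30)
  A[, 10:20] <- -1
  fit <- structure(list(grid = 1:30, draws = list(alpha = A)),
                   class = "event_model_fit")
  pw <- pointwise_sign_credibility(fit, "alpha")
  expect_equal(pw$days, 10:20)
  expect_equal(nrow(pw$runs), 1)
  expect_equal(c(pw$runs$start, pw$runs$end), c(10, 20))
  ## all-zero draws: P(<0) = 0 everywhere -> empty set
  fit0 <- structure(list(grid = 1:30, draws = list(alpha = A * 0)),
                    class = "event_model_fit")
  expect_length(pointwise_sign_credibility(fit0, "alpha")$days, 0)
})

test_that("predict_event_shift is exact simple arithmetic on draws", {
  A <- matrix(-0.01, 400, 30)
  fit <- structure(list(grid = 11:40, draws = list(alpha = A)),
                   class = "event_model_fit")
  s <- suppressWarnings(predict_event_shift(fit, c(15, 35), delta = 1))
  expect_equal(s$mean, -0.21, tolerance = 1e-12)
  expect_equal(s$sd, 0)
  s0 <- suppressWarnings(predict_event_shift(fit, c(15, 35), delta = 0))
  expect_equal(s0$mean, 0)
  expect_error(predict_event_shift(fit, c(5, 35)), "grid")
})

test_that("variance explained: noise-free limit -> 100%, null -> ~0% climate", {
  L <- 20
  bump <- -0.2 * exp(-((60:79) - 70)^2 / 8)
  f <- em_fixture(seed = 21, alpha = bump)
  ## noise-free: rebuild with near-zero residual SD
  sc0 <- den_scenario("first_exit", n_parks = 3, years = 2000:2007, seed = 21,
                      event_params = list(t0 = 60, T = 79, mu = 70,
                                          park_intercept_sd = 6,
                                          residual_sd_mean = 1e-9,
                                          residual_sd_spread = 0),
                      coef_params = list(alpha = bump, beta = rep(0, L),
                                         park_deviation_variance = 0))
  ev0 <- simulate_event_dates(f$clim, simulate_coefficient_functions(sc0), sc0)
  ## rounding to integer days adds a floor; use a configuration whose means
  ## spread widely so rounding noise is negligible
  fit0 <- fit_event_model(ev0, f$clim, t0 = 60, T = 79,
                          fixed = list(s_alpha = 0.2, s_beta = 0.01,
                                       l_ab_global = 3, s_a = 0.01,
                                       s_b = 0.005, l_ab_park = 5,
                                       sigma_r = 6, sigma = 0.5, mu = 70),
                          sampler = list(n_fdraws = 30, seed = 1),
                          representation = "exact")
  expect_gt(variance_explained(fit0)$total, 90)
})

test_that("adding a constant to one park's temperatures changes nothing once centred", {
  f <- em_fixture(seed = 31)
  clim2 <- f$clim
  sel <- clim2$park_id == "park02"
  clim2$temperature_c[sel] <- clim2$temperature_c[sel] + 3
  fx <- list(s_alpha = 0.05, s_beta = 0.02, l_ab_global = 5, s_a = 0.02,
             s_b = 0.01, l_ab_park = 5, sigma_r = 8, sigma = c(9, 10, 11),
             mu = 70)
  fit1 <- fit_event_model(f$ev, f$clim, t0 = 60, T = 79, fixed = fx,
                          sampler = list(n_fdraws = 5, seed = 1),
                          representation = "exact")
  fit2 <- fit_event_model(f$ev, clim2, t0 = 60, T = 79, fixed = fx,
                          sampler = list(n_fdraws = 5, seed = 1),
                          representation = "exact")
  expect_equal(fit1$analytic$alpha_mean, fit2$analytic$alpha_mean,
               tolerance = 1e-10)
  expect_equal(fit1$analytic$r_mean, fit2$analytic$r_mean, tolerance = 1e-10)
})

test_that("fit refuses tiny designs and non-finite climate", {
  f <- em_fixture()
  expect_error(fit_event_model(f$ev[1:5, ], f$clim, t0 = 60, T = 79),
               "10")
  clim_bad <- f$clim
  clim_bad$temperature_c[clim_bad$doy == 70] <- Inf
  expect_error(fit_event_model(f$ev, clim_bad, t0 = 60, T = 79),
               "non-finite")
})

test_that("park-years without full coverage are excluded and reported", {
  f <- em_fixture()
  clim_cut <- f$clim[!(f$clim$park_id == "park03" & f$clim$year == 2004 &
                         f$clim$doy %in% 60:79), ]
  fit <- fit_event_model(f$ev, clim_cut, t0 = 60, T = 79,
                         fixed = list(s_alpha = 0.05, s_beta = 0.02,
                                      l_ab_global = 5, s_a = 0.02,
                                      s_b = 0.01, l_ab_park = 5, sigma_r = 8,
                                      sigma = 10, mu = 70),
                         sampler = list(n_fdraws = 5),
                         representation = "exact")
  expect_equal(nrow(fit$excluded), 1)
  expect_equal(fit$excluded$park_id, "park03")
  expect_equal(length(fit$data$z), nrow(f$ev) - 1)
})
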