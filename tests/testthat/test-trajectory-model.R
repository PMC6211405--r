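test_that("masked windows condition on observed entries only (dense path)", {
  win <- simulate_trajectory_windows(2, 2, lags = -4:4, mu = 1, seed = 8)
  fx <- list(s1 = 1, l1 = 3, s2 = 0.5, l2 = 2, tau = 0.2, rho3 = 2,
             s3 = 1, mu = 1)
  win$mask[1, c(1, 5)] <- TRUE
  win$mask[3, 9] <- TRUE
  win$values[win$mask] <- NA
  fit <- fit_temperature_trajectory(win, fixed = fx,
                                    sampler = list(n_fdraws = 3))
  oracle <- trajectory_dense_oracle(win, fx)
  expect_lt(max(abs(fit$analytic$w_mean - oracle)), 1e-6)
})

test_that("analytic posterior mean of w matches dense joint-Gaussian conditioning", {
  win <- simulate_trajectory_windows(2, 3, lags = -5:5, mu = -1,
    k1 = list(variance = 2, length_scale = 4),
    k2 = list(variance = 0.5, length_scale = 3), tau = 0.3,
    k3 = list(variance = 1, range = 2), seed = 3)
  fx <- list(s1 = sqrt(2), l1 = 4, s2 = sqrt(0.5), l2 = 3, tau = 0.3,
             rho3 = 2, s3 = 1, mu = -1)
  fit <- fit_temperature_trajectory(win, fixed = fx,
                                    sampler = list(n_fdraws = 3))
  oracle <- trajectory_dense_oracle(win, fx)
  expect_lt(max(abs(fit$analytic$w_mean - oracle)), 1e-6)
})

test_that("identical noiseless parks collapse onto the common trajectory", {
  lags <- -10:10
  w_true <- 2 + 0.3 * lags
  win <- simulate_trajectory_windows(3, 4, lags = lags, w = w_true,
    k2 = list(variance = 1e-12, length_scale = 5), tau = 0,
    k3 = list(variance = 1e-10, range = 2), seed = 1)
  fx <- list(s1 = 2, l1 = 8, s2 = 1e-5, l2 = 5, tau = 1e-5, rho3 = 2,
             s3 = 1e-4, mu = 2)
  fit <- fit_temperature_trajectory(win, fixed = fx,
                                    sampler = list(n_fdraws = 50, seed = 2))
  for (i in 1:3)
    expect_lt(max(abs(fit$analytic$u_mean[i, ] - w_true)),
              2 * max(fit$analytic$w_sd) + 1e-3)
})

test_that("the fit refuses unidentifiable designs", {
  win1 <- simulate_trajectory_windows(1, 1, lags = -3:3, seed = 1)
  expect_error(fit_temperature_trajectory(win1), "unidentifiable")
})

test_that("sampled fit recovers a linear population slope at the event day", {
  ## scaled from the full-size design (12 parks x 30 years) to 6 x 15;
  ## the +/-0.1 degC/day tolerance scales by sqrt(4) = 2
  win <- simulate_trajectory_windows(6, 15, lags = -10:10,
    w = -1.8 + 0.3 * (-10:10),
    k1 = list(variance = 4, length_scale = 10),
    k2 = list(variance = 0.4, length_scale = 8), tau = 0.3,
    k3 = list(variance = 4, range = 3), seed = 5)
  fit <- suppressWarnings(fit_temperature_trajectory(win,
    sampler = list(chains = 2, iter = 500, warmup = 200, n_fdraws = 100,
                   seed = 4)))
  s <- event_day_climate_summary(fit)
  expect_lt(abs(s$slope - 0.3), 0.2)
  expect_lt(abs(s$value - (-1.8)), 0.5)
})

test_that("variance partition handles the degenerate and null cases", {
  lags <- -10:10
  ## all parks and years share one noiseless trajectory -> (100, 0, 0)
  win <- simulate_trajectory_windows(3, 3, lags = lags, w = sin(lags / 3),
    k2 = list(variance = 1e-12, length_scale = 5), tau = 0,
    k3 = list(variance = 1e-12, range = 2), seed = 1)
  fx <- list(s1 = 1, l1 = 3, s2 = 1e-6, l2 = 5, tau = 1e-6, rho3 = 2,
             s3 = 1e-6, mu = 0)
  fit <- fit_temperature_trajectory(win, fixed = fx,
                                    sampler = list(n_fdraws = 20, seed = 1))
  fit$post$w_mean <- fit$analytic$w_mean
  fit$post$u_mean <- fit$analytic$u_mean
  part <- variance_partition(win, fit)
  expect_equal(unname(part["shared"]), 100, tolerance = 1)
  expect_equal(unname(part["park_additional"]), 0, tolerance = 0.5)
  expect_equal(sum(part), 100, tolerance = 1e-8)

  ## pure white noise, flat truth -> shared ~ 0, idiosyncratic ~ 100
  win0 <- simulate_trajectory_windows(3, 10, lags = lags, w = rep(0, 21),
    k2 = list(variance = 1e-12, length_scale = 5), tau = 0,
    k3 = list(variance = 4, range = 0.01), seed = 2)
  fx0 <- list(s1 = 0.1, l1 = 5, s2 = 0.01, l2 = 5, tau = 0.01, rho3 = 0.01,
              s3 = 2, mu = 0)
  fit0 <- fit_temperature_trajectory(win0, fixed = fx0,
                                     sampler = list(n_fdraws = 20, seed = 1))
  fit0$post$w_mean <- fit0$analytic$w_mean
  fit0$post$u_mean <- fit0$analytic$u_mean
  part0 <- variance_partition(win0, fit0)
  expect_lt(part0["shared"], 10)
  expect_gt(part0["idiosyncratic"], 80)

  ## zero total variance is an error
  winz <- win
  winz$values[] <- 5
  expect_error(variance_partition(winz, fit), "zero")
})

test_that("event-day summary handles constant and ramp inputs", {
  lags <- -10:10
  ## constant trajectory c: value c, slope 0
  win <- simulate_trajectory_windows(2, 3, lags = lags, w = rep(3, 21),
    k2 = list(variance = 1e-12, length_scale = 5), tau = 0,
    k3 = list(variance = 1e-10, range = 2), seed = 1)
  fx <- list(s1 = 1, l1 = 5, s2 = 1e-5, l2 = 5, tau = 1e-5, rho3 = 2,
             s3 = 1e-4, mu = 3)
  fit <- fit_temperature_trajectory(win, fixed = fx,
                                    sampler = list(n_fdraws = 30, seed = 1))
  fit$post$w_mean <- fit$analytic$w_mean
  s <- event_day_climate_summary(fit)
  expect_equal(s$value, 3, tolerance = 1e-3)
  expect_equal(s$slope, 0, tolerance = 1e-3)
  ## ramp 0.27 t: slope 0.27/day
  win2 <- simulate_trajectory_windows(2, 3, lags = lags, w = 0.27 * lags,
    k2 = list(variance = 1e-12, length_scale = 5), tau = 0,
    k3 = list(variance = 1e-10, range = 2), seed = 1)
  fx2 <- modifyList(fx, list(mu = 0, s1 = 3))
  fit2 <- fit_temperature_trajectory(win2, fixed = fx2,
                                     sampler = list(n_fdraws = 30, seed = 1))
  fit2$post$w_mean <- fit2$analytic$w_mean
  expect_equal(event_day_climate_summary(fit2)$slope, 0.27, tolerance = 1e-3)
})

test_that("snow trajectory summary: loess exactness, park means, MC bound", {
  lag <- -30:30
  ## single park, single year: vbar is the raw window; loess reproduces a line
  tri <- 20 + 0.5 * lag
  win1 <- structure(list(event_kind = "first_exit", lag = lag,
                         values = matrix(tri, 1), mask = matrix(FALSE, 1, 61),
                         park = "p1", year = 2000L,
                         excluded = tibble::tibble(), variable = "snow"),
                    class = "lag_windows")
  s1 <- snow_trajectory_summary(win1)
  expect_equal(s1$vbar[1, ], tri)
  expect_lt(max(abs(s1$u_hat[1, ] - tri)), 1e-6)
  expect_true(s1$low_support[["p1"]])
  ## two constant parks: what is the midpoint
  win2 <- structure(list(event_kind = "first_exit", lag = lag,
                         values = rbind(matrix(10, 3, 61), matrix(20, 3, 61)),
                         mask = matrix(FALSE, 6, 61),
                         park = rep(c("a", "b"), each = 3),
                         year = rep(2000:2002, 2),
                         excluded = tibble::tibble(), variable = "snow"),
                    class = "lag_windows")
  s2 <- snow_trajectory_summary(win2)
  expect_equal(unname(s2$w_hat), rep(15, 61))
  expect_equal(s2$w_hat, colMeans(s2$u_hat))   # definition invariant
  ## triangular truth + noise over 30 years: RMSE < 2 * noise_sd / sqrt(30)
  set.seed(9)
  truth <- pmax(0, 25 - abs(lag) / 2)
  noise_sd <- 3
  vals <- matrix(rep(truth, 30), 30, byrow = TRUE) +
    matrix(rnorm(30 * 61, 0, noise_sd), 30)
  win3 <- structure(list(event_kind = "first_exit", lag = lag,
                         values = vals, mask = matrix(FALSE, 30, 61),
                         park = rep("p1", 30), year = 1981:2010,
                         excluded = tibble::tibble(), variable = "snow"),
                    class = "lag_windows")
  s3 <- snow_trajectory_summary(win3)
  rmse <- sqrt(mean((s3$u_hat[1, ] - truth)^2))
  expect_lt(rmse, 2 * noise_sd / sqrt(30))
})

test_that("posterior SD of w contracts at the linear-Gaussian rate", {
  mk <- function(ny, seed) simulate_trajectory_windows(3, ny, lags = -8:8,
    mu = 0, k1 = list(variance = 2, length_scale = 5),
    k2 = list(variance = 0.3, length_scale = 4), tau = 0.2,
    k3 = list(variance = 2, range = 2), seed = seed)
  fx <- list(s1 = sqrt(2), l1 = 5, s2 = sqrt(0.3), l2 = 4, tau = 0.2,
             rho3 = 2, s3 = sqrt(2), mu = 0)
  sd_of <- function(ny) {
    f <- fit_temperature_trajectory(mk(ny, 4), fixed = fx,
                                    sampler = list(n_fdraws = 400, seed = 6))
    mean(f$post$w_sd)
  }
  ## doubling years should roughly halve... the dominant k3 noise averages
  ## as 1/sqrt(n years); allow 20% slack around the sqrt(2) ratio as the
  ## k1/k2 levels do not contract
  r <- sd_of(4) / sd_of(16)
  expect_gt(r, 1.2)
})
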