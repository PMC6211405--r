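## Shared fixtures and independent oracles for the test suite.  Everything is
## generated in code; nothing is read from disk except files the tests write
## themselves.

## small scenario: quick to simulate, covers both climate variables
tiny_scenario <- function(event_kind = "first_exit", n_parks = 3,
                          years = 2000:2009, seed = 1, ...) {
  den_scenario(event_kind, n_parks = n_parks, years = years, seed = seed, ...)
}

## deterministic-temperature scenario (no noise, no trend, no offsets)
noiseless_scenario <- function(...) {
  den_scenario("first_exit", n_parks = 1, years = 2000:2000, seed = 1,
               temp_params = list(innovation_sd = 0, trend = 0,
                                  ar1_coefficient = 0, park_offset_sd = 0),
               ...)
}

## canonical parameter-recovery scenario: 12 parks x 40 years of spring
## den-exit dates, true alpha a negative Gaussian bump (peak -0.05 days/degC,
## sd 2.5 d, centre day 79) integrating to -0.31 days/degC; noise levels
## chosen by power analysis so the exact posterior clears the recovery
## thresholds with margin (see the methods vignette)
recovery_scenario <- function(seed) {
  den_scenario("first_exit", n_parks = 12, years = 1975:2014, seed = seed,
               event_params = list(park_intercept_sd = 5,
                                   residual_sd_mean = 1,
                                   residual_sd_spread = 0.15),
               coef_params = list(park_deviation_variance = 2.5e-5))
}

## independent haversine oracle (spherical law of cosines, different route
## from the implementation's half-angle formula)
haversine_oracle <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  cosc <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(1, pmax(-1, cosc)))
}

## dense joint-Gaussian conditioning oracle for the trajectory model:
## builds the full covariance over (w, all observations) naively and
## conditions directly.  Independent of the package's balanced reduction.
trajectory_dense_oracle <- function(windows, fx) {
  lags <- windows$lag
  d <- length(lags)
  parks <- unique(windows$park)
  P <- length(parks)
  park_of <- match(windows$park, parks)
  nrec <- nrow(windows$values)
  K1 <- fx$s1^2 * exp(-outer(lags, lags, "-")^2 / (2 * fx$l1^2))
  K2 <- fx$s2^2 * exp(-outer(lags, lags, "-")^2 / (2 * fx$l2^2)) + fx$tau^2
  K3 <- lapply(rep(fx$s3, length.out = P), function(s)
    s^2 * exp(-abs(outer(lags, lags, "-")) / fx$rho3))
  obs <- lapply(seq_len(nrec), function(r) which(!windows$mask[r, ]))
  sizes <- lengths(obs)
  off <- cumsum(c(0, sizes))
  N <- sum(sizes)
  Syy <- matrix(0, N, N)
  Swy <- matrix(0, d, N)
  for (r in seq_len(nrec)) {
    sr <- obs[[r]]
    Swy[, (off[r] + 1):off[r + 1]] <- K1[, sr, drop = FALSE]
    for (q in seq_len(nrec)) {
      sq <- obs[[q]]
      B <- K1[sr, sq, drop = FALSE] +
        (if (park_of[r] == park_of[q]) K2[sr, sq, drop = FALSE] else 0)
      if (r == q) B <- B + K3[[park_of[r]]][sr, sq, drop = FALSE]
      Syy[(off[r] + 1):off[r + 1], (off[q] + 1):off[q + 1]] <- B
    }
  }
  yv <- unlist(lapply(seq_len(nrec), function(r) windows$values[r, obs[[r]]]))
  drop(fx$mu + Swy %*% solve(Syy, yv - fx$mu))
}

## closed-form Gaussian posterior oracle for the event model with fixed
## hyperparameters: builds the joint covariance of (mu?, alpha, z) naively.
event_posterior_oracle <- function(ev, clim, t0, T, fx,
                                   mu_prior = NULL) {
  g <- t0:T
  L <- length(g)
  anom <- center_climate(clim)
  sea <- anom[anom$doy >= t0 & anom$doy <= T, ]
  sea <- sea[order(sea$park_id, sea$year, sea$doy), ]
  U <- matrix(sea$temp_anom, ncol = L, byrow = TRUE)
  V <- matrix(sea$snow_anom, ncol = L, byrow = TRUE)
  keyu <- unique(paste(sea$park_id, sea$year))
  ri <- match(paste(ev$park_id, ev$year), keyu)
  U <- U[ri, , drop = FALSE]; V <- V[ri, , drop = FALSE]
  Kse <- function(v, l) v * exp(-outer(g, g, "-")^2 / (2 * l^2))
  Ka <- Kse(fx$s_alpha^2, fx$l_ab_global)
  Kb <- Kse(fx$s_beta^2, fx$l_ab_global)
  Kpa <- Kse(fx$s_a^2, fx$l_ab_park)
  Kpb <- Kse(fx$s_b^2, fx$l_ab_park)
  parks <- sort(unique(ev$park_id))
  pidx <- match(ev$park_id, parks)
  same <- outer(pidx, pidx, "==") * 1
  sig <- rep(fx$sigma, length.out = length(parks))
  Sz <- U %*% Ka %*% t(U) + V %*% Kb %*% t(V) +
    same * (U %*% Kpa %*% t(U) + V %*% Kpb %*% t(V) + fx$sigma_r^2) +
    diag(sig[pidx]^2)
  z <- as.numeric(ev$day_of_year)
  if (is.null(mu_prior)) {
    resid <- z - fx$mu
    list(alpha = drop(Ka %*% t(U) %*% solve(Sz, resid)),
         mu = fx$mu)
  } else {
    Sz2 <- Sz + mu_prior$sd^2
    resid <- z - mu_prior$mean
    list(alpha = drop(Ka %*% t(U) %*% solve(Sz2, resid)),
         mu = mu_prior$mean +
           drop(rep(mu_prior$sd^2, length(z)) %*% solve(Sz2, resid)))
  }
}

## brute-force window enumeration oracle (double loop)
enumerate_windows_oracle <- function(t0, T, step) {
  out <- NULL
  for (k in 0:floor((T - t0) / step)) for (n in 0:floor((T - t0) / step)) {
    if (k < n) out <- rbind(out, c(t0 + step * k, t0 + step * n))
  }
  out
}

## climate table with a given per-park temperature function of (year, doy)
manual_climate <- function(park_ids, years, temp_fun,
                           snow_fun = function(y, d) 0) {
  rows <- list()
  for (p in seq_along(park_ids)) for (yr in years) {
    d <- 1:365
    rows[[length(rows) + 1L]] <- tibble::tibble(
      park_id = park_ids[p], year = yr, doy = d,
      temperature_c = temp_fun(yr, d, p), snow_cm = snow_fun(yr, d))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "origin_year") <- min(years)
  class(out) <- c("daily_climate", class(out))
  out
}
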