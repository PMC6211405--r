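#' Simulate daily climate series for every park in a scenario
#'
#' Daily mean temperature is the sum of a park offset, an annual cosine cycle
#' (warmest near mid-July, day 196), a linear trend across years, and an AR(1)
#' residual that is continuous across year boundaries.  Snow depth follows a
#' three-term balance: on sub-zero days snowfall of exponential-distributed
#' depth arrives with a fixed probability, the pack then decays
#' multiplicatively (compaction and vaporization), and melts in proportion to
#' positive temperature; depth is clipped at zero.
#'
#' @param scenario A [den_scenario()].
#' @return A tibble of class `daily_climate` with columns `park_id`, `year`,
#'   `doy` (1--365), `temperature_c`, `snow_cm`, plus attribute `origin_year`.
#' @examples
#' clim <- simulate_climate(den_scenario(n_parks = 1, years = 2000:2001))
#' range(clim$snow_cm)
#' @export
simulate_climate <- function(scenario) {
  stopifnot(inherits(scenario, "den_scenario"))
  tp <- scenario$temp_params
  sp <- scenario$snow_params
  years <- scenario$years
  y0 <- min(years)
  doy <- seq_len(DAYS_IN_YEAR)
  seasonal <- tp$annual_mean +
    tp$seasonal_amplitude * cos(2 * pi * (doy - 196) / DAYS_IN_YEAR)
  out <- vector("list", scenario$n_parks)
  ids <- park_ids(scenario$n_parks)
  for (i in seq_len(scenario$n_parks)) {
    offset <- with_seed(split_seed(scenario$seed, "park_offset", i),
                        rnorm(1, 0, tp$park_offset_sd))
    eps_prev <- with_seed(split_seed(scenario$seed, "ar_init", i),
                          if (tp$ar1_coefficient < 1 && tp$innovation_sd > 0)
                            rnorm(1, 0, tp$innovation_sd /
                                    sqrt(1 - tp$ar1_coefficient^2)) else 0)
    snow_prev <- 0
    yearly <- vector("list", length(years))
    for (k in seq_along(years)) {
      yr <- years[k]
      draws <- with_seed(split_seed(scenario$seed, "climate", i, yr), {
        list(innov = rnorm(DAYS_IN_YEAR, 0, tp$innovation_sd),
             u = runif(DAYS_IN_YEAR),
             fall = rexp(DAYS_IN_YEAR,
                         rate = 1 / max(sp$snowfall_depth_mean, 1e-12)))
      })
      eps <- numeric(DAYS_IN_YEAR)
      e <- eps_prev
      for (d in doy) {
        e <- tp$ar1_coefficient * e + draws$innov[d]
        eps[d] <- e
      }
      eps_prev <- eps[DAYS_IN_YEAR]
      temp <- offset + seasonal + tp$trend * (yr - y0) + eps
      snow <- numeric(DAYS_IN_YEAR)
      s <- snow_prev
      for (d in doy) {
        if (temp[d] < 0 && draws$u[d] < sp$snowfall_probability_at_subzero &&
            sp$snowfall_depth_mean > 0)
          s <- s + draws$fall[d]
        s <- s * (1 - sp$compaction_rate)
        s <- max(0, s - sp$melt_rate * max(temp[d], 0))
        snow[d] <- s
      }
      snow_prev <- snow[DAYS_IN_YEAR]
      yearly[[k]] <- tibble::tibble(park_id = ids[i], year = yr, doy = doy,
                                    temperature_c = temp, snow_cm = snow)
    }
    out[[i]] <- dplyr::bind_rows(yearly)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "origin_year") <- y0
  class(res) <- c("daily_climate", class(res))
  res
}

#' Simulate true coefficient functions for the event-date model
#'
#' Returns the global temperature and snow coefficient curves `alpha(t)`,
#' `beta(t)` on the integer grid `t0:T` (either the explicit vectors stored in
#' the scenario or draws from a zero-mean squared-exponential GP), plus the
#' park-specific curves `a_i`, `b_i` obtained by adding zero-mean SE-GP
#' deviations with the scenario's `park_deviation_variance`.  Deterministic
#' given the scenario seed.
#'
#' @param scenario A [den_scenario()].
#' @return A list of class `coef_functions` with elements `grid`, `alpha`,
#'   `beta`, and matrices `a`, `b` (parks x days).
#' @export
simulate_coefficient_functions <- function(scenario) {
  stopifnot(inherits(scenario, "den_scenario"))
  cp <- scenario$coef_params
  ep <- scenario$event_params
  grid <- ep$t0:ep$T
  L <- length(grid)
  expand <- function(x, nm, key) {
    if (is.list(x)) {
      with_seed(split_seed(scenario$seed, key),
                gp_draw(grid, x$variance, x$length_scale))
    } else {
      if (length(x) != L)
        stop(sprintf("explicit `%s` has length %d but the grid [t0, T] has %d days",
                     nm, length(x), L), call. = FALSE)
      as.numeric(x)
    }
  }
  alpha <- expand(cp$alpha, "alpha", "coef_alpha")
  beta <- expand(cp$beta, "beta", "coef_beta")
  P <- scenario$n_parks
  a <- matrix(rep(alpha, each = P), P, L)
  b <- matrix(rep(beta, each = P), P, L)
  if (cp$park_deviation_variance > 0) {
    for (i in seq_len(P)) {
      a[i, ] <- alpha + with_seed(split_seed(scenario$seed, "coef_a", i),
        gp_draw(grid, cp$park_deviation_variance, cp$park_deviation_length_scale))
      b[i, ] <- beta + with_seed(split_seed(scenario$seed, "coef_b", i),
        gp_draw(grid, cp$park_deviation_variance, cp$park_deviation_length_scale))
    }
  }
  structure(list(grid = grid, alpha = alpha, beta = beta, a = a, b = b,
                 park_id = park_ids(P)),
            class = "coef_functions")
}

#' Per-park day-of-year climatology and anomalies
#'
#' Computes, for each park and day-of-year, the long-term mean temperature and
#' snow depth over all years present, and returns the climate table with
#' anomaly columns (`temp_anom`, `snow_anom`) attached.  Event-date models in
#' this package always enter climate as these anomalies, which decouples the
#' climate terms from the intercept and park effects; the generator uses the
#' identical convention.
#'
#' @param climate A `daily_climate` tibble (see [simulate_climate()] /
#'   [read_climate()]).
#' @return The input with `temp_anom` and `snow_anom` columns; the climatology
#'   table is attached as attribute `"climatology"`.
#' @export
center_climate <- function(climate) {
  stopifnot(all(c("park_id", "year", "doy", "temperature_c", "snow_cm")
                %in% names(climate)))
  clim <- dplyr::summarise(dplyr::group_by(climate, .data$park_id, .data$doy),
                           temp_clim = mean(.data$temperature_c, na.rm = TRUE),
                           snow_clim = mean(.data$snow_cm, na.rm = TRUE),
                           .groups = "drop")
  out <- dplyr::left_join(climate, clim, by = c("park_id", "doy"))
  out$temp_anom <- out$temperature_c - out$temp_clim
  out$snow_anom <- out$snow_cm - out$snow_clim
  out$temp_clim <- out$snow_clim <- NULL
  attr(out, "origin_year") <- attr(climate, "origin_year") %||% min(climate$year)
  attr(out, "climatology") <- clim
  class(out) <- unique(c("daily_climate", class(out)))
  out
}

#' Simulate denning event dates from climate and coefficient functions
#'
#' For every park x year with full climate coverage of the season `[t0, T]`,
#' the model mean is `mu + r_i + sum_t a_i(t) u_iy(t) + sum_t b_i(t) v_iy(t)`
#' with `u`, `v` the per-park day-of-year temperature and snow anomalies (the
#' same centering convention the fitting functions use).  Gaussian noise with
#' park-specific residual SD `sigma_i` is added and the result rounded to an
#' integer day.  Records whose rounded day falls outside `[t0, T]` are
#' retained but flagged.
#'
#' @param climate A `daily_climate` tibble covering `[t0, T]` for every
#'   park-year to be simulated.
#' @param coefficients A `coef_functions` object (see
#'   [simulate_coefficient_functions()]).
#' @param scenario The [den_scenario()] the coefficients came from.
#' @return A tibble with columns `park_id`, `year`, `event_kind`,
#'   `day_of_year` (integer), `mean_day` (un-rounded model mean, for exact
#'   tests) and `flagged` (outside `[t0, T]`).  True parameter values
#'   (`r_i`, `sigma_i`, coefficient curves) are attached as attribute
#'   `"truth"`.
#' @export
simulate_event_dates <- function(climate, coefficients, scenario) {
  stopifnot(inherits(scenario, "den_scenario"),
            inherits(coefficients, "coef_functions"))
  ep <- scenario$event_params
  grid <- ep$t0:ep$T
  if (!identical(as.integer(coefficients$grid), as.integer(grid)))
    stop("coefficient grid does not match the scenario's [t0, T]", call. = FALSE)
  anom <- center_climate(climate)
  ids <- park_ids(scenario$n_parks)
  if (!all(ids %in% unique(anom$park_id)))
    stop("climate is missing parks required by the scenario", call. = FALSE)

  r <- vapply(seq_len(scenario$n_parks), function(i)
    with_seed(split_seed(scenario$seed, "r_park", i),
              rnorm(1, 0, ep$park_intercept_sd)), 0.0)
  sigma <- vapply(seq_len(scenario$n_parks), function(i)
    with_seed(split_seed(scenario$seed, "sigma_park", i), {
      s <- -1
      while (s <= 0) s <- rnorm(1, ep$residual_sd_mean, ep$residual_sd_spread)
      s
    }), 0.0)

  season <- anom[anom$doy >= ep$t0 & anom$doy <= ep$T, ]
  counts <- dplyr::count(season, .data$park_id, .data$year)
  bad <- counts[counts$n < length(grid), ]
  ## also park-years entirely absent
  full <- expand.grid(park_id = ids, year = scenario$years,
                      stringsAsFactors = FALSE)
  missing_py <- dplyr::anti_join(full, counts, by = c("park_id", "year"))
  if (nrow(bad) > 0 || nrow(missing_py) > 0) {
    offenders <- unique(c(sprintf("%s/%d", bad$park_id, bad$year),
                          sprintf("%s/%d", missing_py$park_id, missing_py$year)))
    stop("climate does not cover [t0, T] for park-years: ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ...", call. = FALSE)
  }
  season <- season[order(season$park_id, season$year, season$doy), ]
  recs <- vector("list", scenario$n_parks)
  for (i in seq_len(scenario$n_parks)) {
    si <- season[season$park_id == ids[i], ]
    U <- matrix(si$temp_anom, ncol = length(grid), byrow = TRUE)
    V <- matrix(si$snow_anom, ncol = length(grid), byrow = TRUE)
    yrs <- unique(si$year)
    mean_day <- ep$mu + r[i] + drop(U %*% coefficients$a[i, ]) +
      drop(V %*% coefficients$b[i, ])
    eps <- vapply(yrs, function(yr)
      with_seed(split_seed(scenario$seed, "event_eps", i, yr),
                rnorm(1, 0, sigma[i])), 0.0)
    day <- as.integer(round(mean_day + eps))
    recs[[i]] <- tibble::tibble(park_id = ids[i], year = yrs,
                                event_kind = scenario$event_kind,
                                day_of_year = day, mean_day = mean_day,
                                flagged = day < ep$t0 | day > ep$T)
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "truth") <- list(mu = ep$mu, r = setNames(r, ids),
                             sigma = setNames(sigma, ids),
                             alpha = coefficients$alpha,
                             beta = coefficients$beta,
                             a = coefficients$a, b = coefficients$b,
                             grid = grid)
  out
}

#' Simulate event-aligned temperature windows directly from the hierarchical
#' trajectory model
#'
#' Draws data from the three-level Gaussian-process model used by
#' [fit_temperature_trajectory()]: a population trajectory `w(t)` (explicit or
#' an SE-GP draw around `mu`), park trajectories `u_i = w + h_i + SE-GP
#' deviation`, and per park-year observations `y_iy = u_i +` an exponential
#' (Ornstein--Uhlenbeck) residual.  Used for oracle and recovery tests where
#' the generative truth must live inside the model family.
#'
#' @param n_parks,n_years Design size (years per park).
#' @param lags Integer lag grid (default -30:30).
#' @param mu Top-level constant mean.
#' @param w Explicit population trajectory on `lags`, or `NULL` to draw one
#'   from the `k1` GP around `mu`.
#' @param k1,k2 Lists `list(variance=, length_scale=)` for the SE kernels of
#'   the population and park-deviation levels.
#' @param tau SD of the constant park offsets `h_i`.
#' @param k3 List `list(variance=, range=)` for the OU residual kernel;
#'   `variance` may be a vector of park-specific variances.
#' @param seed Integer seed.
#' @return A `lag_windows` object (see [align_event_windows()]) with the
#'   generative truth attached as attribute `"truth"`.
#' @export
simulate_trajectory_windows <- function(n_parks, n_years, lags = -30:30,
                                        mu = 0, w = NULL,
                                        k1 = list(variance = 4, length_scale = 15),
                                        k2 = list(variance = 1, length_scale = 10),
                                        tau = 0.5,
                                        k3 = list(variance = 4, range = 3),
                                        seed = 1) {
  d <- length(lags)
  v3 <- rep(k3$variance, length.out = n_parks)
  with_seed(split_seed(seed, "trajectory_sim"), {
    if (is.null(w)) {
      w <- mu + gp_draw(lags, k1$variance, k1$length_scale)
    } else stopifnot(length(w) == d)
    u <- matrix(0, n_parks, d)
    y <- matrix(0, n_parks * n_years, d)
    park <- character(n_parks * n_years)
    year <- integer(n_parks * n_years)
    ids <- park_ids(n_parks)
    K3 <- lapply(v3, function(v) ou_kernel(lags, v, k3$range))
    R3 <- lapply(K3, chol_psd)
    row <- 0L
    for (i in seq_len(n_parks)) {
      h_i <- rnorm(1, 0, tau)
      u[i, ] <- w + h_i + gp_draw(lags, k2$variance, k2$length_scale)
      for (yy in seq_len(n_years)) {
        row <- row + 1L
        y[row, ] <- mvn_draw(u[i, ], R = R3[[i]])
        park[row] <- ids[i]
        year[row] <- 2000L + yy
      }
    }
    structure(list(event_kind = "synthetic", lag = as.integer(lags),
                   values = y, mask = matrix(FALSE, nrow(y), d),
                   park = park, year = year,
                   excluded = tibble::tibble(park_id = character(),
                                             year = integer(),
                                             reason = character()),
                   variable = "temperature"),
              class = "lag_windows",
              truth = list(mu = mu, w = w, u = u, tau = tau,
                           k1 = k1, k2 = k2, k3 = k3, v3 = v3))
  })
}

#' Write a synthetic scenario's data to disk
#'
#' Emits the same CSV dialects [read_phenology()] and [read_climate()] consume
#' (phenology, climate, coordinates) plus a JSON sidecar recording the true
#' generative parameter values for recovery tests.
#'
#' @param scenario A [den_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_scenario_data <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  climate <- simulate_climate(scenario)
  coefs <- simulate_coefficient_functions(scenario)
  events <- simulate_event_dates(climate, coefs, scenario)
  truth <- attr(events, "truth")
  ids <- park_ids(scenario$n_parks)
  coords <- tibble::tibble(id = c(ids, sub("park", "station", ids)),
                           lat = rep(55 + 2 * seq_len(scenario$n_parks), 2),
                           lon = rep(30 + 5 * seq_len(scenario$n_parks), 2))
  paths <- list(
    phenology = file.path(dir, "phenology.csv"),
    climate = file.path(dir, "climate.csv"),
    coordinates = file.path(dir, "coordinates.csv"),
    truth = file.path(dir, "truth.json"))
  readr::write_csv(
    tibble::tibble(park_id = events$park_id, year = events$year,
                   event_kind = events$event_kind,
                   event_date = events$day_of_year), paths$phenology)
  clim_out <- tibble::tibble(station_id = sub("park", "station", climate$park_id),
                             date = format(date_from_doy(climate$year, climate$doy)),
                             temperature_c = climate$temperature_c,
                             snow_cm = climate$snow_cm)
  readr::write_csv(clim_out, paths$climate)
  readr::write_csv(coords, paths$coordinates)
  jsonlite::write_json(
    list(mu = truth$mu, r = as.list(truth$r), sigma = as.list(truth$sigma),
         alpha = truth$alpha, beta = truth$beta, grid = truth$grid,
         seed = scenario$seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
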