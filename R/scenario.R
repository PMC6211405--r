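#' Define a synthetic denning-phenology scenario
#'
#' A scenario fixes every generative parameter needed to simulate multi-park
#' daily climate series and denning event dates: the seasonal temperature
#' model, a three-term snowpack balance, the event-date linear model
#' (overall mean day `mu`, park intercepts `r_i`, time-varying temperature and
#' snow coefficients, park-specific residual scales), and a base seed from
#' which all random streams are derived hierarchically (park, then year), so
#' that adding a park or a year never changes the draws of existing units.
#'
#' Defaults emulate the monitoring setting the package targets: 12 protected
#' areas observed up to 69 years (1946--2014), autumn den-entry dates near day
#' 304 +/- 18 and spring den-exit dates near day 99 +/- 15, a warming trend of
#' +0.034 degC per year, and a continental seasonal cycle.  All series use a
#' 365-day year (Feb 29 dropped).
#'
#' @param event_kind `"first_exit"` (spring) or `"last_entry"` (autumn).
#' @param n_parks Number of parks (>= 1).
#' @param years Inclusive integer range of calendar years.
#' @param seed Base integer seed.
#' @param temp_params,snow_params,event_params,coef_params Named lists
#'   overriding individual defaults; see Details.
#'
#' @details
#' `temp_params`: `annual_mean` (degC), `seasonal_amplitude` (degC),
#' `trend` (degC/year), `ar1_coefficient` (in `[0,1)`), `innovation_sd` (degC),
#' `park_offset_sd` (degC).  Daily temperature is
#' park offset + annual cosine (warmest at day 196) + linear trend + AR(1)
#' residual.
#'
#' `snow_params`: `snowfall_probability_at_subzero`, `snowfall_depth_mean`
#' (cm), `compaction_rate` (fraction/day), `melt_rate` (cm per positive
#' degC-day).  Snow gains an exponential-depth snowfall on sub-zero days with
#' the stated probability, decays multiplicatively (compaction/vaporization),
#' and melts proportionally to positive temperature, clipped at zero.
#'
#' `event_params`: `mu` (day-of-year), `park_intercept_sd` (days, sigma_r),
#' `residual_sd_mean` (days, mean of the park residual SDs sigma_i),
#' `residual_sd_spread` (days, spread of the sigma_i), `t0`, `T` (season
#' bounds; defaults 1/150 for first exit and 211/365 for last entry).
#'
#' `coef_params`: `alpha` and `beta` are either an explicit numeric vector on
#' the grid `t0:T` (days shift per unit of centered covariate) or a list
#' `list(variance=, length_scale=)` describing a zero-mean squared-exponential
#' GP to draw them from; `park_deviation_variance` and
#' `park_deviation_length_scale` govern the park-level SE-GP deviations
#' `a_i - alpha` and `b_i - beta`.  The default `alpha` for spring exits is a
#' negative Gaussian bump (peak -0.05 days/degC, sd 2.5 days, centred 20 days
#' before `mu`) integrating to about -0.3 days/degC; the default `beta` is
#' zero.
#'
#' @return An object of class `den_scenario`.
#' @examples
#' sc <- den_scenario("first_exit", n_parks = 2, years = 2000:2003)
#' sc$event_params$mu
#' @export
den_scenario <- function(event_kind = c("first_exit", "last_entry"),
                         n_parks = 12, years = 1946:2014, seed = 1,
                         temp_params = list(), snow_params = list(),
                         event_params = list(), coef_params = list()) {
  event_kind <- match.arg(event_kind)
  if (!is.numeric(n_parks) || length(n_parks) != 1L || n_parks < 1 ||
      n_parks != round(n_parks))
    abort_field("n_parks", "must be a single integer >= 1")
  if (length(years) < 1L || any(years != round(years)) ||
      any(diff(years) != 1L))
    abort_field("years", "must be a non-empty consecutive integer range")
  check_number(seed, "seed")

  tp <- modifyList(list(annual_mean = 2, seasonal_amplitude = 15,
                        trend = 0.034, ar1_coefficient = 0.8,
                        innovation_sd = 2, park_offset_sd = 3), temp_params)
  check_number(tp$annual_mean, "temp_params$annual_mean")
  check_number(tp$seasonal_amplitude, "temp_params$seasonal_amplitude", lower = 0)
  check_number(tp$trend, "temp_params$trend")
  check_number(tp$ar1_coefficient, "temp_params$ar1_coefficient", lower = 0)
  if (tp$ar1_coefficient >= 1)
    abort_field("temp_params$ar1_coefficient", "must be < 1")
  check_number(tp$innovation_sd, "temp_params$innovation_sd", lower = 0)
  check_number(tp$park_offset_sd, "temp_params$park_offset_sd", lower = 0)

  sp <- modifyList(list(snowfall_probability_at_subzero = 0.3,
                        snowfall_depth_mean = 3,
                        compaction_rate = 0.01, melt_rate = 0.5), snow_params)
  check_number(sp$snowfall_probability_at_subzero,
               "snow_params$snowfall_probability_at_subzero", 0, 1)
  check_number(sp$snowfall_depth_mean, "snow_params$snowfall_depth_mean", lower = 0)
  check_number(sp$compaction_rate, "snow_params$compaction_rate", 0, 1)
  check_number(sp$melt_rate, "snow_params$melt_rate", lower = 0)

  ep_default <- if (event_kind == "first_exit") {
    list(mu = 99, park_intercept_sd = 10, residual_sd_mean = 10,
         residual_sd_spread = 2.5, t0 = 1, T = 150)
  } else {
    list(mu = 304, park_intercept_sd = 12, residual_sd_mean = 12,
         residual_sd_spread = 3, t0 = 211, T = 365)
  }
  ep <- modifyList(ep_default, event_params)
  check_number(ep$mu, "event_params$mu")
  check_number(ep$park_intercept_sd, "event_params$park_intercept_sd", lower = 0)
  check_number(ep$residual_sd_mean, "event_params$residual_sd_mean", lower = 0)
  check_number(ep$residual_sd_spread, "event_params$residual_sd_spread", lower = 0)
  check_number(ep$t0, "event_params$t0", 1, DAYS_IN_YEAR)
  check_number(ep$T, "event_params$T", 1, DAYS_IN_YEAR)
  if (ep$t0 >= ep$T) abort_field("event_params$t0", "must satisfy t0 < T")
  ep$kind <- event_kind

  grid <- ep$t0:ep$T
  bump_centre <- ep$mu - 20
  alpha_default <- -0.05 * exp(-(grid - bump_centre)^2 / (2 * 2.5^2))
  cp <- modifyList(list(alpha = alpha_default, beta = rep(0, length(grid)),
                        park_deviation_variance = 1e-4,
                        park_deviation_length_scale = 10), coef_params)
  for (nm in c("alpha", "beta")) {
    x <- cp[[nm]]
    if (is.list(x)) {
      check_number(x$variance %||% NA, paste0("coef_params$", nm, "$variance"),
                   lower = 0)
      check_number(x$length_scale %||% NA,
                   paste0("coef_params$", nm, "$length_scale"))
      if (x$length_scale <= 0)
        abort_field(paste0("coef_params$", nm, "$length_scale"), "must be > 0")
    } else if (!is.numeric(x)) {
      abort_field(paste0("coef_params$", nm),
                  "must be a numeric vector or list(variance=, length_scale=)")
    }
  }
  check_number(cp$park_deviation_variance,
               "coef_params$park_deviation_variance", lower = 0)
  check_number(cp$park_deviation_length_scale,
               "coef_params$park_deviation_length_scale")
  if (cp$park_deviation_length_scale <= 0)
    abort_field("coef_params$park_deviation_length_scale", "must be > 0")

  structure(list(event_kind = event_kind, n_parks = as.integer(n_parks),
                 years = as.integer(years), seed = as.integer(seed),
                 temp_params = tp, snow_params = sp, event_params = ep,
                 coef_params = cp),
            class = "den_scenario")
}

#' @export
print.den_scenario <- function(x, ...) {
  cat(sprintf("<den_scenario> %s | %d parks | years %d-%d | seed %d\n",
              x$event_kind, x$n_parks, min(x$years), max(x$years), x$seed))
  cat(sprintf("  event: mu=%g  sigma_r=%g  sigma_bar=%g  season [%d, %d]\n",
              x$event_params$mu, x$event_params$park_intercept_sd,
              x$event_params$residual_sd_mean, x$event_params$t0,
              x$event_params$T))
  invisible(x)
}

park_ids <- function(n) sprintf("park%02d", seq_len(n))
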