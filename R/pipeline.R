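#' Assemble and validate a pipeline run configuration
#'
#' Either a synthetic `scenario` or the three input paths (`phenology`,
#' `climate`, `coordinates`) must be supplied.  All stage outputs carry the
#' seed and a hash of this configuration.
#'
#' @param scenario Optional [den_scenario()] — when given, stage 1 simulates
#'   the inputs instead of reading them.
#' @param phenology,climate,coordinates Input CSV paths (ignored when a
#'   scenario is given).
#' @param event_kind `"first_exit"` or `"last_entry"`.
#' @param t0,T Optional season overrides for the event model.
#' @param lag_range Lag window for the trajectory model (default `c(-30, 30)`).
#' @param priors,sampler Overrides passed to the two fitting functions;
#'   `sampler` understands `chains`, `iter` (draws), `warmup`, `n_fdraws`,
#'   `seed`.
#' @param loess_span Span for the snow trajectory summary (default 0.3).
#' @param loo_mode `"existing"` or `"new"` (held-out park intercept handling).
#' @param windows_step Candidate-window lattice step (default 7 days).
#' @param seed Integer run seed.
#' @param outdir Output directory.
#' @param plots Generate best-effort figures (never gate success).
#' @param max_windows Optional cap on the number of candidate windows scanned
#'   (cheapest way to bound runtime on exploratory runs; `Inf` scans all).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, phenology = NULL, climate = NULL,
                       coordinates = NULL,
                       event_kind = c("first_exit", "last_entry"),
                       t0 = NULL, T = NULL, lag_range = c(-30, 30),
                       priors = list(), sampler = list(), loess_span = 0.3,
                       loo_mode = c("existing", "new"), windows_step = 7,
                       seed = 1, outdir = tempfile("denclim_run_"),
                       plots = TRUE, max_windows = Inf) {
  event_kind <- match.arg(event_kind)
  loo_mode <- match.arg(loo_mode)
  if (is.null(scenario)) {
    for (p in c(phenology, climate, coordinates))
      if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
    if (is.null(phenology) || is.null(climate) || is.null(coordinates))
      stop("either a scenario or all three input paths are required",
           call. = FALSE)
  } else stopifnot(inherits(scenario, "den_scenario"))
  td <- t0 %||% if (event_kind == "first_exit") 1L else 211L
  Td <- T %||% if (event_kind == "first_exit") 150L else 365L
  if (td >= Td) stop("configuration error: t0 must be < T", call. = FALSE)
  if (length(lag_range) != 2 || lag_range[1] >= lag_range[2])
    stop("configuration error: lag_range must be increasing length-2",
         call. = FALSE)
  check_number(seed, "seed")
  cfg <- list(scenario = scenario, phenology = phenology, climate = climate,
              coordinates = coordinates, event_kind = event_kind,
              t0 = td, T = Td, lag_range = lag_range, priors = priors,
              sampler = sampler, loess_span = loess_span, loo_mode = loo_mode,
              windows_step = windows_step, seed = as.integer(seed),
              outdir = outdir, plots = plots, max_windows = max_windows)
  class(cfg) <- "run_config"
  cfg
}

stamp <- function(df, cfg) {
  df$seed <- cfg$seed
  df$config_hash <- config_hash(unclass(cfg)[setdiff(names(cfg), "outdir")])
  df
}

#' Run the full pipeline: simulate/ingest, fit both models, compare, report
#'
#' Stages: (1) `data` — simulate from the scenario or ingest and gap-fill the
#' input tables with nearest-station assignment; (2) `trajectory` —
#' event-aligned windows, hierarchical GP fit, variance partition, event-day
#' summary, loess snow summary; (3) `event_model` — time-varying-coefficient
#' fit with coefficient curves, credibility surfaces, sign runs and variance
#' explained; (4) `comparison` — candidate-window LMM scan and LOO-CV
#' comparison against the flexible model; (5) `report` — manifest with
#' package version, config hash, per-stage status and wall time.  A stage
#' error stops downstream stages, leaves completed outputs intact, and names
#' the stage in the error.  Deterministic given (config, seed).
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(packageVersion("denclim")),
                   config_hash = config_hash(
                     unclass(config)[setdiff(names(config), "outdir")]),
                   seed = config$seed, stages = list())
  t_stage <- function(name, expr) {
    t1 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    elapsed <- as.numeric(Sys.time() - t1, units = "secs")
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(status = if (ok) "complete" else "failed",
                                     seconds = round(elapsed, 2),
                                     error = if (!ok) conditionMessage(res))
    if (!ok) {
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    res
  }

  dat <- t_stage("data", {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      sc$seed <- split_seed(config$seed, "scenario")
      sc2 <- den_scenario(sc$event_kind, sc$n_parks, sc$years, sc$seed,
                          sc$temp_params, sc$snow_params,
                          sc$event_params[setdiff(names(sc$event_params), "kind")],
                          sc$coef_params)
      paths <- write_scenario_data(sc2, file.path(config$outdir, "data"))
      clim <- simulate_climate(sc2)
      evs <- read_phenology(paths$phenology)
      list(events = evs, climate = clim)
    } else {
      evs <- read_phenology(config$phenology)
      clim_st <- read_climate(config$climate)
      coords <- read_coordinates(config$coordinates)
      pids <- unique(evs$park_id)
      assignment <- assign_nearest_station(
        coords[coords$id %in% pids, ],
        coords[!coords$id %in% pids, ])
      clim <- fill_gaps(park_climate(clim_st, assignment))
      readr::write_csv(stamp(assignment, config),
                       file.path(config$outdir, "station_assignment.csv"))
      list(events = evs, climate = clim)
    }
  })

  traj <- t_stage("trajectory", {
    tw <- align_event_windows(dat$events, dat$climate, "temperature",
                              config$lag_range)
    sampler <- modifyList(list(seed = split_seed(config$seed, "trajectory")),
                          config$sampler)
    fit <- fit_temperature_trajectory(tw, priors = config$priors,
                                      sampler = sampler)
    part <- variance_partition(tw, fit)
    summ <- event_day_climate_summary(fit)
    sw <- align_event_windows(dat$events, dat$climate, "snow",
                              config$lag_range)
    snow <- snow_trajectory_summary(sw, config$loess_span)
    curves <- tibble::tibble(lag = fit$lag, w_mean = fit$post$w_mean,
                             w_q05 = fit$post$w_q05, w_q95 = fit$post$w_q95)
    for (i in seq_along(fit$park_id))
      curves[[paste0("u_", fit$park_id[i])]] <- fit$post$u_mean[i, ]
    readr::write_csv(stamp(curves, config),
                     file.path(config$outdir, "trajectory_curves.csv"))
    snow_tab <- tibble::tibble(lag = snow$lag, w_hat = snow$w_hat)
    readr::write_csv(stamp(snow_tab, config),
                     file.path(config$outdir, "snow_trajectory.csv"))
    jsonlite::write_json(list(seed = config$seed,
                              partition = as.list(part),
                              event_day = summ[c("value", "posterior_sd",
                                                 "predictive_sd", "slope")],
                              snow_event_day = event_day_climate_summary(snow)),
                         file.path(config$outdir, "trajectory_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fit = fit, snow = snow, partition = part, windows = tw)
  })

  evfit <- t_stage("event_model", {
    sampler <- modifyList(list(seed = split_seed(config$seed, "event")),
                          config$sampler)
    fit <- fit_event_model(dat$events, dat$climate,
                           event_kind = config$event_kind,
                           t0 = config$t0, T = config$T,
                           priors = config$priors, sampler = sampler)
    curves <- tibble::tibble(day = fit$grid,
                             alpha_mean = fit$post$alpha_mean,
                             alpha_q05 = fit$post$alpha_q05,
                             alpha_q95 = fit$post$alpha_q95,
                             beta_mean = fit$post$beta_mean,
                             beta_q05 = fit$post$beta_q05,
                             beta_q95 = fit$post$beta_q95)
    readr::write_csv(stamp(curves, config),
                     file.path(config$outdir, "coefficient_curves.csv"))
    for (coefn in c("alpha", "beta")) {
      surf <- window_sum_credibility(fit, coefn)
      utils::write.csv(as.matrix(surf),
                       file.path(config$outdir,
                                 sprintf("credibility_%s.csv", coefn)))
    }
    runs <- pointwise_sign_credibility(fit, "alpha")
    jsonlite::write_json(list(seed = config$seed,
                              variance_explained = variance_explained(fit),
                              negative_alpha_runs = runs$runs),
                         file.path(config$outdir, "event_model_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  cmp <- t_stage("comparison", {
    wins <- enumerate_windows(config$t0, config$T, config$windows_step)
    if (nrow(wins) > config$max_windows)
      wins <- wins[round(seq(1, nrow(wins), length.out = config$max_windows)), ]
    ev <- dat$events[dat$events$event_kind == config$event_kind, ]
    res <- lapply(seq_len(nrow(wins)), function(k) {
      w <- c(wins$t1[k], wins$t2[k])
      fitw <- tryCatch(fit_window_lmm(ev, dat$climate, w),
                       error = function(e) NULL)
      if (is.null(fitw)) return(tibble::tibble(t1 = w[1], t2 = w[2],
                                               converged = FALSE,
                                               singular = TRUE,
                                               loo_lpd = NA_real_))
      lpd <- if (fitw$singular) NA_real_ else
        loo_cv_lpd(fitw, ev, dat$climate, method = "plugin",
                   mode = config$loo_mode)$total
      tibble::tibble(t1 = w[1], t2 = w[2], converged = TRUE,
                     singular = fitw$singular, loo_lpd = lpd)
    })
    res <- dplyr::bind_rows(res)
    flex <- loo_cv_lpd(evfit, ev, dat$climate, method = "conditional")
    comparison <- compare_models(flex, res)
    readr::write_csv(stamp(comparison$table, config),
                     file.path(config$outdir, "window_comparison.csv"))
    jsonlite::write_json(list(seed = config$seed,
                              flexible_lpd = comparison$flexible_lpd,
                              best_window = comparison$best_window,
                              best_lpd = comparison$best_lpd,
                              delta = comparison$delta,
                              preferred = comparison$preferred),
                         file.path(config$outdir, "comparison_report.json"),
                         auto_unbox = TRUE, digits = NA)
    comparison
  })

  t_stage("report", {
    if (isTRUE(config$plots)) {
      try(suppressWarnings({
        ggplot2::ggsave(file.path(config$outdir, "trajectory.png"),
                        plot_trajectory_fit(traj$fit), width = 7, height = 4,
                        dpi = 120)
        ggplot2::ggsave(file.path(config$outdir, "coefficients.png"),
                        plot_coefficient_curves(evfit), width = 7, height = 4,
                        dpi = 120)
        ggplot2::ggsave(file.path(config$outdir, "credibility_alpha.png"),
                        plot_credibility_surface(
                          window_sum_credibility(evfit, "alpha")),
                        width = 5, height = 4, dpi = 120)
      }), silent = TRUE)
    }
    TRUE
  })

  manifest$stages$report$status <- "complete"
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-day-of-year linear climate trend
#'
#' For each park and day-of-year with at least `min_years` years of data, the
#' ordinary-least-squares slope of the climate variable against calendar
#' year, plus the across-park mean curve (unsmoothed).  Days with fewer years
#' are omitted and reported.
#'
#' @param climate A `daily_climate` tibble.
#' @param variable `"temperature"` or `"snow"`.
#' @param min_years Minimum number of years per day (default 3).
#' @return List with `per_park` (tibble `park_id`, `doy`, `slope`), `mean`
#'   (tibble `doy`, `slope` averaged over parks), and `omitted`.
#' @export
annual_trend_report <- function(climate, variable = c("temperature", "snow"),
                                min_years = 3) {
  variable <- match.arg(variable)
  vcol <- if (variable == "temperature") "temperature_c" else "snow_cm"
  rows <- list(); omitted <- list()
  for (pid in unique(climate$park_id)) {
    sub <- climate[climate$park_id == pid, ]
    for (d in sort(unique(sub$doy))) {
      x <- sub[sub$doy == d, ]
      ok <- is.finite(x[[vcol]])
      if (sum(ok) < min_years) {
        omitted[[length(omitted) + 1L]] <-
          tibble::tibble(park_id = pid, doy = d, n_years = sum(ok))
        next
      }
      yr <- x$year[ok]; vv <- x[[vcol]][ok]
      slope <- cov(yr, vv) / var(yr)
      rows[[length(rows) + 1L]] <- tibble::tibble(park_id = pid, doy = d,
                                                  slope = slope)
    }
  }
  per_park <- dplyr::bind_rows(rows)
  mean_curve <- dplyr::summarise(dplyr::group_by(per_park, .data$doy),
                                 slope = mean(.data$slope), .groups = "drop")
  list(per_park = per_park, mean = mean_curve,
       omitted = if (length(omitted) > 0) dplyr::bind_rows(omitted)
         else tibble::tibble(park_id = character(), doy = integer(),
                             n_years = integer()))
}
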