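#' Read and validate a phenology table
#'
#' Expects a delimited text file with header columns `park_id`, `year`,
#' `event_kind` (`last_entry` or `first_exit`) and `event_date`, the latter
#' either an integer day-of-year or an ISO date.  ISO dates are converted with
#' the package's 365-day convention (Feb 29 maps to day 59 and is flagged).
#' Duplicate `(park_id, year, event_kind)` keys are a schema error listing the
#' offending line numbers.  Records outside the seasonal interval
#' (`[211, 365]` for last entry, `[1, 150]` for first exit) are flagged, never
#' dropped.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A tibble with columns `park_id`, `year`, `event_kind`,
#'   `day_of_year`, `flagged`; a validation report (out-of-interval and
#'   Feb-29 rows) is attached as attribute `"validation"`.
#' @export
read_phenology <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("park_id", "year", "event_kind", "event_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("phenology file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_kind <- which(!raw$event_kind %in% c("last_entry", "first_exit"))
  if (length(bad_kind) > 0)
    stop("unrecognised event_kind at line(s) ",
         paste(bad_kind + 1L, collapse = ", "),
         " (expected last_entry or first_exit)", call. = FALSE)
  ev <- as.character(raw$event_date)
  numeric_like <- grepl("^\\s*-?[0-9]+\\s*$", ev)
  doy <- rep(NA_integer_, length(ev))
  feb29 <- rep(FALSE, length(ev))
  doy[numeric_like] <- as.integer(ev[numeric_like])
  if (any(!numeric_like)) {
    parsed <- as.Date(ev[!numeric_like], format = "%Y-%m-%d")
    bad <- which(!numeric_like)[is.na(parsed)]
    if (length(bad) > 0)
      stop("unparseable event_date at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    doy[!numeric_like] <- doy_365(parsed)
    feb29[!numeric_like] <- is_feb29(parsed)
  }
  out_of_range <- which(doy < 1L | doy > DAYS_IN_YEAR)
  if (length(out_of_range) > 0)
    stop("event_date outside 1..365 at line(s) ",
         paste(out_of_range + 1L, collapse = ", "), call. = FALSE)
  key <- paste(raw$park_id, raw$year, raw$event_kind, sep = "\r")
  if (anyDuplicated(key)) {
    dup_lines <- which(key %in% key[duplicated(key)]) + 1L
    stop("duplicate (park_id, year, event_kind) records at line(s) ",
         paste(dup_lines, collapse = ", "), call. = FALSE)
  }
  lo <- ifelse(raw$event_kind == "last_entry", 211L, 1L)
  hi <- ifelse(raw$event_kind == "last_entry", 365L, 150L)
  flagged <- doy < lo | doy > hi
  out <- tibble::tibble(park_id = as.character(raw$park_id),
                        year = as.integer(raw$year),
                        event_kind = raw$event_kind,
                        day_of_year = doy, flagged = flagged)
  attr(out, "validation") <- tibble::tibble(
    line = c(which(flagged), which(feb29)) + 1L,
    issue = c(rep("out_of_interval", sum(flagged)),
              rep("feb29_mapped_to_59", sum(feb29))))
  out
}

#' Write a phenology table in the dialect [read_phenology()] consumes
#' @param records Tibble with `park_id`, `year`, `event_kind`, `day_of_year`.
#' @param path Output path.
#' @export
write_phenology <- function(records, path) {
  readr::write_csv(tibble::tibble(park_id = records$park_id,
                                  year = records$year,
                                  event_kind = records$event_kind,
                                  event_date = records$day_of_year), path)
  invisible(path)
}

#' Read a daily station climate table
#'
#' Expects header columns `station_id`, `date` (ISO-8601), `temperature_c`,
#' `snow_cm`; missing values as empty fields.  Dates are mapped to the
#' 365-day calendar (Feb 29 rows dropped).  Negative snow depths are an
#' error; the daily grid must be strictly increasing per station.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A tibble of class `daily_climate` with `park_id` set to the station
#'   id (use [park_climate()] to re-key by park), plus `year`, `doy`,
#'   `temperature_c`, `snow_cm`.
#' @export
read_climate <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("station_id", "date", "temperature_c", "snow_cm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("climate file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dates <- suppressWarnings(as.Date(raw$date))
  if (anyNA(dates))
    stop("unparseable date at line(s) ",
         paste(utils::head(which(is.na(dates)), 10) + 1L, collapse = ", "),
         call. = FALSE)
  keep <- !is_feb29(dates)
  raw <- raw[keep, ]; dates <- dates[keep]
  snow <- as.numeric(raw$snow_cm)
  if (any(snow < 0, na.rm = TRUE))
    stop("negative snow depths present; snow_cm must be >= 0", call. = FALSE)
  out <- tibble::tibble(park_id = as.character(raw$station_id),
                        year = as.integer(format(dates, "%Y")),
                        doy = doy_365(dates),
                        temperature_c = as.numeric(raw$temperature_c),
                        snow_cm = snow)
  out <- out[order(out$park_id, out$year, out$doy), ]
  idx <- day_index(out$year, out$doy, min(out$year))
  for (sid in unique(out$park_id)) {
    ii <- idx[out$park_id == sid]
    if (anyDuplicated(ii))
      stop("duplicate dates for station ", sid, call. = FALSE)
  }
  attr(out, "origin_year") <- min(out$year)
  class(out) <- c("daily_climate", class(out))
  out
}

#' Read a coordinates table (`id`, `lat`, `lon` in decimal degrees)
#' @param path File path.
#' @param delim Field delimiter.
#' @export
read_coordinates <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(c("id", "lat", "lon"), names(raw))
  if (length(missing_cols) > 0)
    stop("coordinates file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tibble::tibble(id = as.character(raw$id), lat = as.numeric(raw$lat),
                 lon = as.numeric(raw$lon))
}

#' Great-circle (haversine) distance in km, mean Earth radius 6371 km
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Assign each park its nearest meteorological station
#'
#' Nearest-neighbour assignment by haversine distance; exact ties are broken
#' by lexicographic station id order (documented tie rule).
#'
#' @param park_coords,station_coords Tibbles with columns `id`, `lat`, `lon`.
#' @return A tibble `park_id`, `station_id`, `distance_km`.
#' @export
assign_nearest_station <- function(park_coords, station_coords) {
  if (is.null(station_coords) || nrow(station_coords) == 0)
    stop("station list is empty; cannot assign climate stations", call. = FALSE)
  st <- station_coords[order(station_coords$id), ]
  rows <- lapply(seq_len(nrow(park_coords)), function(i) {
    d <- haversine_km(park_coords$lat[i], park_coords$lon[i], st$lat, st$lon)
    j <- which.min(d)   # ties: first in lexicographic id order
    tibble::tibble(park_id = park_coords$id[i], station_id = st$id[j],
                   distance_km = d[j])
  })
  dplyr::bind_rows(rows)
}

#' Re-key a station climate table by park using a nearest-station assignment
#' @param climate `daily_climate` keyed by station id (from [read_climate()]).
#' @param assignment Output of [assign_nearest_station()].
#' @return `daily_climate` keyed by `park_id`, with station provenance
#'   attached as attribute `"provenance"`.
#' @export
park_climate <- function(climate, assignment) {
  rows <- lapply(seq_len(nrow(assignment)), function(i) {
    sub <- climate[climate$park_id == assignment$station_id[i], ]
    if (nrow(sub) == 0)
      stop("no climate rows for station ", assignment$station_id[i],
           call. = FALSE)
    sub$park_id <- assignment$park_id[i]
    sub
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "origin_year") <- min(out$year)
  attr(out, "provenance") <- assignment
  class(out) <- c("daily_climate", class(out))
  out
}

#' Fill short gaps in daily climate series
#'
#' Gaps of at most `max_gap_days` consecutive missing days are linearly
#' interpolated for temperature and forward-filled for snow depth (which
#' preserves non-negativity); longer gaps are left missing and reported.
#'
#' @param series A `daily_climate` tibble (keyed by `park_id`).
#' @param max_gap_days Maximum gap length to fill (default 3).
#' @return The series with short gaps filled; a report of unfilled gaps is
#'   attached as attribute `"gap_report"`.
#' @export
fill_gaps <- function(series, max_gap_days = 3) {
  origin <- attr(series, "origin_year") %||% min(series$year)
  report <- list()
  out <- series
  idx_all <- day_index(series$year, series$doy, origin)
  for (pid in unique(series$park_id)) {
    sel <- which(series$park_id == pid)
    ord <- sel[order(idx_all[sel])]
    idx <- idx_all[ord]
    for (vcol in c("temperature_c", "snow_cm")) {
      x <- out[[vcol]][ord]
      na_runs <- rle(is.na(x))
      pos <- cumsum(c(1, na_runs$lengths))
      for (k in seq_along(na_runs$lengths)) {
        if (!na_runs$values[k]) next
        s <- pos[k]; e <- pos[k] + na_runs$lengths[k] - 1L
        len <- e - s + 1L
        interior <- s > 1 && e < length(x)
        if (len <= max_gap_days && interior) {
          if (vcol == "temperature_c") {
            x[s:e] <- approx(x = idx[c(s - 1L, e + 1L)],
                             y = x[c(s - 1L, e + 1L)], xout = idx[s:e])$y
          } else {
            x[s:e] <- x[s - 1L]
          }
        } else {
          report[[length(report) + 1L]] <- tibble::tibble(
            park_id = pid, variable = vcol,
            start_year = out$year[ord[s]], start_doy = out$doy[ord[s]],
            length_days = len)
        }
      }
      out[[vcol]][ord] <- x
    }
  }
  attr(out, "gap_report") <- if (length(report) > 0) dplyr::bind_rows(report)
    else tibble::tibble(park_id = character(), variable = character(),
                        start_year = integer(), start_doy = integer(),
                        length_days = integer())
  attr(out, "origin_year") <- origin
  out
}

#' Build event-aligned climate lag windows
#'
#' For every phenology record, extracts the chosen climate variable at lags
#' `lag_range[1]..lag_range[2]` days around the event day (lag 0 = the event
#' day).  Windows are built on the continuous calendar axis, so autumn
#' windows may legitimately cross into January of the following year.  Lags
#' with no climate value are masked; park-years with more than `max_missing`
#' (default 20%) masked lags are excluded and reported.
#'
#' @param events Phenology tibble (see [read_phenology()]).
#' @param climate `daily_climate` keyed by `park_id`.
#' @param variable `"temperature"` or `"snow"`.
#' @param lag_range Integer vector of length 2, default `c(-30, 30)`.
#' @param max_missing Maximum tolerated fraction of masked lags.
#' @return An object of class `lag_windows`: list with `lag`, `values`
#'   (records x lags), `mask` (TRUE = missing), `park`, `year`, `event_kind`,
#'   `variable`, and an `excluded` report.
#' @export
align_event_windows <- function(events, climate,
                                variable = c("temperature", "snow"),
                                lag_range = c(-30, 30), max_missing = 0.2) {
  variable <- match.arg(variable)
  vcol <- if (variable == "temperature") "temperature_c" else "snow_cm"
  origin <- attr(climate, "origin_year") %||% min(climate$year)
  lags <- seq.int(lag_range[1], lag_range[2])
  d <- length(lags)
  values <- matrix(NA_real_, nrow(events), d)
  cl_idx <- split(seq_len(nrow(climate)), climate$park_id)
  lookup <- lapply(cl_idx, function(ii) {
    x <- climate[[vcol]][ii]
    names(x) <- day_index(climate$year[ii], climate$doy[ii], origin)
    x
  })
  for (r in seq_len(nrow(events))) {
    lk <- lookup[[events$park_id[r]]]
    if (is.null(lk)) next
    target <- day_index(events$year[r], events$day_of_year[r], origin) + lags
    values[r, ] <- lk[as.character(target)]
  }
  mask <- is.na(values)
  frac <- rowMeans(mask)
  keep <- frac <= max_missing
  excluded <- tibble::tibble(
    park_id = events$park_id[!keep], year = events$year[!keep],
    reason = ifelse(frac[!keep] == 1, "no_climate_coverage",
                    sprintf("%d/%d lags missing",
                            rowSums(mask)[!keep], d)))
  structure(list(event_kind = unique(events$event_kind)[1],
                 lag = as.integer(lags),
                 values = values[keep, , drop = FALSE],
                 mask = mask[keep, , drop = FALSE],
                 park = events$park_id[keep], year = events$year[keep],
                 excluded = excluded, variable = variable),
            class = "lag_windows")
}

#' @export
print.lag_windows <- function(x, ...) {
  cat(sprintf("<lag_windows> %s | %d records | lags %d..%d | %d excluded\n",
              x$variable, nrow(x$values), min(x$lag), max(x$lag),
              nrow(x$excluded)))
  invisible(x)
}
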