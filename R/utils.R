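#' @importFrom stats dnorm pnorm rnorm runif var sd quantile median optim loess
#'   predict approx cov acf lm coef complete.cases setNames
#' @importFrom utils head tail modifyList packageVersion
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid scenario field `%s`: %s", field, msg), call. = FALSE)
}

## Hierarchical RNG stream splitting.  Streams are derived by hashing a base
## seed with integer keys (park index, year, stage name ...), so adding a park
## or a year never perturbs the draws of existing units.  All derived seeds
## stay below 2^31 - 1; arithmetic keeps intermediate products < 2^53 so it is
## exact in doubles.
split_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in list(...)) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 69069 + as.numeric(k) + 1) %% m
    h <- (h * 31 + 17) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Stable small hash of an arbitrary R object (used for config manifests).
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261 %% 2147483647
  ## fold bytes in chunks to keep the R loop short
  v <- as.numeric(raw)
  for (i in seq_len(ceiling(length(v) / 256))) {
    chunk <- v[((i - 1) * 256 + 1):min(i * 256, length(v))]
    s <- sum(chunk * (seq_along(chunk) %% 97 + 1))
    h <- (h * 31 + s) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

## 365-day calendar: Feb 29 is dropped so that day-of-year is comparable
## across years.  Dates falling on Feb 29 map to day 59 (= Feb 28) and are
## flagged by the callers that care.
DAYS_IN_YEAR <- 365L

doy_365 <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  leap <- (lt$year + 1900L) %% 4L == 0L &
    ((lt$year + 1900L) %% 100L != 0L | (lt$year + 1900L) %% 400L == 0L)
  after_feb28 <- leap & doy >= 60L
  doy[after_feb28] <- doy[after_feb28] - 1L
  ## Feb 29 itself collapsed onto day 59
  doy
}

is_feb29 <- function(dates) {
  lt <- as.POSIXlt(dates)
  lt$mon == 1L & lt$mday == 29L
}

## inverse mapping: (year, doy on the 365-day calendar) -> calendar Date
## (Feb 29 is skipped in leap years, so it is never produced)
date_from_doy <- function(year, doy) {
  year <- as.integer(year); doy <- as.integer(doy)
  leap <- year %% 4L == 0L & (year %% 100L != 0L | year %% 400L == 0L)
  as.Date(sprintf("%04d-01-01", year)) + (doy - 1L) +
    ifelse(leap & doy >= 60L, 1L, 0L)
}

## continuous day index on the 365-day calendar
day_index <- function(year, doy, origin_year) {
  (as.integer(year) - as.integer(origin_year)) * DAYS_IN_YEAR + as.integer(doy)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(name, "must be a single finite number")
  if (x < lower) abort_field(name, sprintf("must be >= %s", lower))
  if (x > upper) abort_field(name, sprintf("must be <= %s", upper))
  invisible(x)
}
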