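#' Daily time series of counts or temperature
#'
#' A `daily_series` is a contiguous, gap-free daily sequence: a `Date` vector
#' with step exactly one day and a numeric vector of the same length. The
#' `kind` tag distinguishes integer health counts (`"count"`), temperature in
#' degrees Celsius (`"temperature"`), and kernel-aggregated counts
#' (`"aggregated"`, non-negative reals).
#'
#' @param dates `Date` vector, strictly increasing by exactly one day.
#' @param values numeric vector of the same length.
#' @param kind one of `"count"`, `"temperature"`, `"aggregated"`.
#'
#' @return An object of class `daily_series` (a data frame with columns
#'   `date` and `value` plus a `kind` attribute).
#' @examples
#' s <- daily_series(as.Date("2000-01-01") + 0:9, rpois(10, 5), "count")
#' s
#' @export
daily_series <- function(dates, values, kind = c("count", "temperature", "aggregated")) {
  kind <- match.arg(kind)
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("'dates' and 'values' must have the same length")
  if (length(dates) == 0L) stop("empty series")
  if (anyNA(dates) || anyNA(values))
    stop("missing values are not permitted in a daily_series")
  if (length(dates) > 1L) {
    step <- diff(as.integer(dates))
    if (any(step != 1L))
      stop("dates must be contiguous: strictly increasing with step exactly 1 day")
  }
  if (kind == "count") {
    if (any(values < 0) || any(values != round(values)))
      stop("count series must hold non-negative integers")
  }
  if (kind == "aggregated" && any(values < 0))
    stop("aggregated series must be non-negative")
  structure(data.frame(date = dates, value = values),
            kind = kind, class = c("daily_series", "data.frame"))
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series: %s, %d days, %s .. %s>\n",
              attr(x, "kind"), nrow(x), format(x$date[1L]),
              format(x$date[nrow(x)])))
  cat(sprintf("  mean %.3f, range [%.3f, %.3f]\n",
              mean(x$value), min(x$value), max(x$value)))
  invisible(x)
}

series_kind <- function(x) attr(x, "kind")

#' Hourly time series
#'
#' Hourly temperature measurements covering whole days: the timestamp vector
#' advances by exactly one hour and the total length is divisible by 24.
#'
#' @param timestamps `POSIXct` vector at hourly step (UTC is used internally;
#'   timestamps are treated as local clock time with no DST).
#' @param values numeric vector.
#' @return An object of class `hourly_series`.
#' @export
hourly_series <- function(timestamps, values) {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop("'timestamps' and 'values' must have the same length")
  if (anyNA(timestamps) || anyNA(values)) stop("missing values not permitted")
  if (length(timestamps) %% 24L != 0L)
    stop("hourly coverage must be whole days (length divisible by 24)")
  if (length(timestamps) > 1L) {
    step <- diff(as.numeric(timestamps))
    if (any(step != 3600))
      stop("timestamps must advance by exactly 1 hour")
  }
  if (as.POSIXlt(timestamps[1L])$hour != 0L)
    stop("hourly series must start at hour 0 of a day")
  structure(data.frame(datetime = timestamps, value = values),
            class = c("hourly_series", "data.frame"))
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("<hourly_series: %d hours (%d days), %s .. %s>\n",
              nrow(x), nrow(x) %/% 24L, format(x$datetime[1L]),
              format(x$datetime[nrow(x)])))
  invisible(x)
}

## n_days x 24 matrix view of an hourly series, with the corresponding dates
hourly_matrix <- function(h) {
  stopifnot(inherits(h, "hourly_series"))
  m <- matrix(h$value, ncol = 24L, byrow = TRUE)
  dates <- as.Date(h$datetime[seq(1L, nrow(h), by = 24L)])
  list(dates = dates, values = m)
}

#' Read and write daily series CSV files
#'
#' Files have a header `date,value` with ISO-8601 dates. The reader validates
#' contiguity and the `kind` invariants; it fails on gaps, duplicates or
#' unparseable rows rather than imputing.
#'
#' @param path file path.
#' @param kind series kind tag, see [daily_series()].
#' @return `read_daily_csv()` returns a [daily_series()];
#'   `write_daily_csv()` returns `path` invisibly.
#' @export
read_daily_csv <- function(path, kind = c("count", "temperature", "aggregated")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "value") %in% names(df)))
    stop("expected columns 'date,value' in ", path)
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d)) stop("unparseable ISO-8601 dates in ", path)
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v)) stop("unparseable or missing values in ", path)
  daily_series(d, v, kind)
}

#' @rdname read_daily_csv
#' @param s a [daily_series()].
#' @export
write_daily_csv <- function(s, path) {
  stopifnot(inherits(s, "daily_series"))
  write.csv(data.frame(date = format(s$date, "%Y-%m-%d"),
                       value = s$value),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write hourly series CSV files (header `datetime,value`)
#'
#' @inheritParams read_daily_csv
#' @return `read_hourly_csv()` returns an [hourly_series()].
#' @export
read_hourly_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("datetime", "value") %in% names(df)))
    stop("expected columns 'datetime,value' in ", path)
  ts <- as.POSIXct(df$datetime, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) stop("unparseable ISO-8601 datetimes in ", path)
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v)) stop("unparseable values in ", path)
  hourly_series(ts, v)
}

#' @rdname read_hourly_csv
#' @param h an [hourly_series()].
#' @export
write_hourly_csv <- function(h, path) {
  stopifnot(inherits(h, "hourly_series"))
  write.csv(data.frame(datetime = format(h$datetime, "%Y-%m-%dT%H:%M:%S"),
                       value = h$value),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inclusive day count between two calendar dates
#'
#' @param start,end `Date` (or ISO-8601 strings), `start <= end`.
#' @return Integer number of days, both endpoints included.
#' @examples
#' days_in_span("1981-01-01", "2011-12-31")  # 11322
#' days_in_span("2007-01-01", "2011-12-31")  # 1826
#' @export
days_in_span <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("'start' must not be after 'end'")
  as.integer(end - start) + 1L
}

## Day-of-year on the fixed 365-day grid: Feb 29 is merged into day 59
## (Feb 28) so every year maps onto 1..365.
doy365 <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  leap <- (lt$year + 1900L) %% 4L == 0L &
    ((lt$year + 1900L) %% 100L != 0L | (lt$year + 1900L) %% 400L == 0L)
  adj <- leap & doy >= 60L
  doy[adj] <- doy[adj] - 1L
  doy[leap & lt$mon == 1L & lt$mday == 29L] <- 59L
  doy
}

#' Reshape a daily series into annual curves
#'
#' Each complete calendar year becomes one row on a common 365-point
#' day-of-year grid. Feb 29 is removed from leap years so all curves share
#' the grid; incomplete boundary years are dropped.
#'
#' @param s a [daily_series()].
#' @return An object of class `year_curves`: a list with integer `years`,
#'   `grid` (1..365) and a `values` matrix (one row per year).
#' @export
to_year_curves <- function(s) {
  stopifnot(inherits(s, "daily_series"))
  yr <- as.integer(format(s$date, "%Y"))
  complete <- vapply(unique(yr), function(y) {
    sum(yr == y) == days_in_span(as.Date(sprintf("%d-01-01", y)),
                                 as.Date(sprintf("%d-12-31", y)))
  }, logical(1L))
  years <- unique(yr)[complete]
  if (length(years) == 0L) stop("series contains no complete calendar year")
  vals <- matrix(NA_real_, length(years), 365L,
                 dimnames = list(years, NULL))
  for (i in seq_along(years)) {
    sel <- yr == years[i]
    d <- s$date[sel]; v <- s$value[sel]
    feb29 <- format(d, "%m-%d") == "02-29"
    vals[i, ] <- v[!feb29]
  }
  structure(list(years = years, grid = 1:365, values = vals,
                 kind = series_kind(s)),
            class = "year_curves")
}

#' @export
print.year_curves <- function(x, ...) {
  cat(sprintf("<year_curves: %d years (%d..%d) x 365 days, kind %s>\n",
              length(x$years), min(x$years), max(x$years), x$kind))
  invisible(x)
}

## Subset helper: window of a daily series by date (keeps contiguity).
window_daily <- function(s, from, to) {
  keep <- s$date >= as.Date(from) & s$date <= as.Date(to)
  daily_series(s$date[keep], s$value[keep], series_kind(s))
}
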