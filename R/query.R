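#' Time-scoped queries over device value streams
#'
#' A query applies one operation to the values one device emitted within a
#' time window. Operations: `value` (the matched values themselves),
#' `maximum`, `minimum`, `average` (scalars over numeric values) and
#' `series` (plot-ready `(time, value)` pairs). Time specifications:
#'
#' * `on-date(d)` — one calendar day;
#' * `between-hours(h1, h2, d)` — an hour range within one day;
#' * `between-dates(d1, d2)` — a day range, both ends inclusive;
#' * `from-date(d)` — from a day onwards;
#' * `total` — all available values.
#'
#' `value` admits the first four; the aggregating operations admit
#' `between-dates`, `from-date` and `total` (hour windows can be opted in
#' via `allow_hours`). Dates are ISO-8601 and are mapped onto the scenario
#' clock through `epoch_date`: the date on which second 0 falls. All
#' windows are half-open, consistent with the day convention of
#' [day_index()].
#'
#' @param operation One of `"value"`, `"maximum"`, `"minimum"`,
#'   `"average"`, `"series"`.
#' @param device Sensor ID whose stream is queried.
#' @param time_spec A time specification from [on_date()], [between_hours()],
#'   [between_dates()], [from_date()] or [total_window()].
#' @param allow_hours Permit `between-hours` for aggregating operations
#'   (default `FALSE`).
#' @return An object of class `adl_query`.
#' @examples
#' q <- query_spec("maximum", "glucometer", between_dates("2021-03-01", "2021-03-07"))
#' @export
query_spec <- function(operation = c("value", "maximum", "minimum",
                                     "average", "series"),
                       device, time_spec, allow_hours = FALSE) {
  operation <- match.arg(operation)
  stopifnot(inherits(time_spec, "adl_time_spec"))
  legal <- if (operation == "value") {
    c("on-date", "between-hours", "between-dates", "from-date")
  } else {
    c("between-dates", "from-date", "total",
      if (allow_hours) "between-hours")
  }
  if (!time_spec$kind %in% legal) {
    stop(sprintf("time spec '%s' is not legal for operation '%s'",
                 time_spec$kind, operation), call. = FALSE)
  }
  structure(list(operation = operation, device = device,
                 time_spec = time_spec),
            class = "adl_query")
}

#' @rdname query_spec
#' @param d,d1,d2 ISO dates (`"YYYY-MM-DD"`).
#' @param h1,h2 Hours of day (0-24), `h1 < h2`.
#' @export
on_date <- function(d) time_spec_new("on-date", d = as.Date(d))

#' @rdname query_spec
#' @export
between_hours <- function(h1, h2, d) {
  stopifnot(h1 >= 0, h2 <= 24, h1 < h2)
  time_spec_new("between-hours", d = as.Date(d), h1 = h1, h2 = h2)
}

#' @rdname query_spec
#' @export
between_dates <- function(d1, d2) {
  d1 <- as.Date(d1); d2 <- as.Date(d2)
  stopifnot(d1 <= d2)
  time_spec_new("between-dates", d1 = d1, d2 = d2)
}

#' @rdname query_spec
#' @export
from_date <- function(d) time_spec_new("from-date", d = as.Date(d))

#' @rdname query_spec
#' @export
total_window <- function() time_spec_new("total")

time_spec_new <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "adl_time_spec")
}

# half-open [start, end) window in scenario seconds
window_seconds <- function(ts, epoch_date) {
  epoch_date <- as.Date(epoch_date)
  day0 <- function(d) as.numeric(difftime(as.Date(d), epoch_date, units = "days")) *
    SECONDS_PER_DAY
  switch(ts$kind,
    "on-date" = c(day0(ts$d), day0(ts$d) + SECONDS_PER_DAY),
    "between-hours" = c(day0(ts$d) + ts$h1 * 3600, day0(ts$d) + ts$h2 * 3600),
    "between-dates" = c(day0(ts$d1), day0(ts$d2) + SECONDS_PER_DAY),
    "from-date" = c(day0(ts$d), Inf),
    "total" = c(-Inf, Inf)
  )
}

#' Run a query over a raw record log
#'
#' @param q An [query_spec()] object.
#' @param records A record tibble (`time`, `sensor_id`, `value`).
#' @param epoch_date The calendar date of scenario second 0 (default
#'   `"2021-03-01"`).
#' @return An object of class `adl_query_result`: a list with the operation
#'   echo, the matched `(time, value)` tibble, `scalar` (for
#'   maximum/minimum/average; `NA` with `empty = TRUE` when nothing
#'   matched — an empty result is distinct from zero), and the window used.
#' @export
run_query <- function(q, records, epoch_date = "2021-03-01") {
  stopifnot(inherits(q, "adl_query"))
  records <- tibble::as_tibble(records)
  w <- window_seconds(q$time_spec, epoch_date)
  sel <- records[records$sensor_id == q$device &
                   records$time >= w[1] & records$time < w[2], , drop = FALSE]
  sel <- sel[order(sel$time), , drop = FALSE]
  matched <- tibble::tibble(time = sel$time, value = sel$value)
  scalar <- NA_real_
  if (q$operation %in% c("maximum", "minimum", "average")) {
    num <- suppressWarnings(as.numeric(sel$value))
    if (anyNA(num) && nrow(sel) > 0) {
      stop(sprintf("device '%s' emitted non-numeric values; %s requires a numeric stream",
                   q$device, q$operation), call. = FALSE)
    }
    if (length(num) > 0) {
      scalar <- switch(q$operation, maximum = max(num), minimum = min(num),
                       average = mean(num))
    }
  }
  structure(list(operation = q$operation, device = q$device,
                 matched = matched, scalar = scalar,
                 empty = nrow(matched) == 0, window = w),
            class = "adl_query_result")
}

#' @export
print.adl_query_result <- function(x, ...) {
  cat(sprintf("<adl_query_result> %s(%s): %d value(s)", x$operation,
              x$device, nrow(x$matched)))
  if (!is.na(x$scalar)) cat(sprintf(", scalar = %s", format(x$scalar)))
  if (x$empty) cat(" [empty]")
  cat("\n")
  invisible(x)
}

#' Save and reuse queries as one-line textual specifications
#'
#' Queries serialize to a single human-readable line, e.g.
#' `AVERAGE glucometer BETWEEN 2021-03-01 2021-03-07`,
#' `VALUE fridge_door ON 2021-03-02`,
#' `VALUE stove HOURS 8 12 2021-03-02`, `MAXIMUM glucometer TOTAL`.
#' `parse_query()` inverts `serialize_query()` exactly, so saved
#' specifications replayed on the same log yield identical results.
#'
#' @param q An `adl_query`.
#' @return `serialize_query()` returns a single string.
#' @export
serialize_query <- function(q) {
  stopifnot(inherits(q, "adl_query"))
  ts <- q$time_spec
  tail <- switch(ts$kind,
    "on-date" = sprintf("ON %s", format(ts$d)),
    "between-hours" = sprintf("HOURS %s %s %s", format(ts$h1), format(ts$h2),
                              format(ts$d)),
    "between-dates" = sprintf("BETWEEN %s %s", format(ts$d1), format(ts$d2)),
    "from-date" = sprintf("FROM %s", format(ts$d)),
    "total" = "TOTAL"
  )
  sprintf("%s %s %s", toupper(q$operation), q$device, tail)
}

#' @rdname serialize_query
#' @param text A one-line query specification.
#' @param allow_hours Passed to [query_spec()].
#' @export
parse_query <- function(text, allow_hours = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  tok <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(tok) < 3) {
    stop(sprintf("parse error at token %d: expected OPERATION DEVICE TIMESPEC",
                 length(tok) + 1), call. = FALSE)
  }
  op <- tolower(tok[1])
  if (!op %in% c("value", "maximum", "minimum", "average", "series")) {
    stop(sprintf("parse error at token 1: unknown operation '%s'", tok[1]),
         call. = FALSE)
  }
  device <- tok[2]
  kw <- toupper(tok[3])
  parse_date <- function(s, pos) {
    d <- tryCatch(as.Date(s), error = function(e) NA)
    if (is.na(d)) {
      stop(sprintf("parse error at token %d: '%s' is not an ISO date", pos, s),
           call. = FALSE)
    }
    d
  }
  need <- function(n) {
    if (length(tok) != n) {
      stop(sprintf("parse error: %s expects %d token(s) after the keyword",
                   kw, n - 3), call. = FALSE)
    }
  }
  ts <- switch(kw,
    "ON" = { need(4); on_date(parse_date(tok[4], 4)) },
    "BETWEEN" = { need(5); between_dates(parse_date(tok[4], 4),
                                         parse_date(tok[5], 5)) },
    "FROM" = { need(4); from_date(parse_date(tok[4], 4)) },
    "HOURS" = {
      need(6)
      h1 <- suppressWarnings(as.numeric(tok[4]))
      h2 <- suppressWarnings(as.numeric(tok[5]))
      if (is.na(h1) || is.na(h2)) {
        stop("parse error at token 4-5: HOURS expects two numbers", call. = FALSE)
      }
      between_hours(h1, h2, parse_date(tok[6], 6))
    },
    "TOTAL" = { need(3); total_window() },
    stop(sprintf("parse error at token 3: unknown time keyword '%s'", tok[3]),
         call. = FALSE)
  )
  query_spec(op, device, ts, allow_hours = allow_hours)
}
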