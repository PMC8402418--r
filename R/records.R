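#' Day index of a timestamp
#'
#' Days are aligned to the scenario epoch, not to calendar midnight: second
#' `t` belongs to day `floor((t - epoch) / 86400)`, so `t = epoch + 86400`
#' opens day 1 under the half-open day convention.
#'
#' @param t Numeric vector of times (seconds).
#' @param epoch Scenario epoch (seconds), default 0. All `t >= epoch`.
#' @return Integer vector of day indices (0-based).
#' @examples
#' day_index(c(0, 86399, 86400)) # 0 0 1
#' @export
day_index <- function(t, epoch = 0) {
  if (any(t < epoch)) stop("time precedes the scenario epoch", call. = FALSE)
  as.integer(floor((t - epoch) / 86400))
}

SECONDS_PER_DAY <- 86400

canonical_value <- function(value) {
  # canonical text form of a sensed value: booleans "true"/"false", numbers
  # via format(), other text verbatim
  if (is.logical(value)) return(ifelse(value, "true", "false"))
  if (is.numeric(value)) {
    return(vapply(value, function(v) format(v, scientific = FALSE), ""))
  }
  as.character(value)
}

#' Parse one raw sensor record
#'
#' A raw record is one sensor emission: the simulator-clock time, the sensor
#' ID, and the sensed value. Two serializations are supported: CSV
#' (`time,sensor_id,value`) and JSONL (one object per line with those three
#' keys). When a sensor registry is supplied the value is coerced to the
#' sensor's declared type (`boolean`, `real`, `text`) and unknown sensor IDs
#' are rejected.
#'
#' @param line A single non-empty line of text.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param registry Optional sensor registry (see [sensor_registry()]).
#' @return A one-row tibble with columns `time` (numeric), `sensor_id`
#'   (character), `value` (character, canonical form).
#' @examples
#' parse_record("120,bathroom_door,true", "csv")
#' @export
parse_record <- function(line, dialect = c("csv", "jsonl"), registry = NULL) {
  dialect <- match.arg(dialect)
  if (!is.character(line) || length(line) != 1 || !nzchar(trimws(line))) {
    stop("record line must be a single non-empty string", call. = FALSE)
  }
  if (dialect == "csv") {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop(sprintf("malformed record '%s': expected 3 comma-separated fields", line),
           call. = FALSE)
    }
    rec <- list(time = parts[1], sensor_id = trimws(parts[2]), value = parts[3])
  } else {
    rec <- tryCatch(jsonlite::fromJSON(line),
                    error = function(e) stop(sprintf("malformed JSONL record: %s",
                                                     conditionMessage(e)), call. = FALSE))
    if (!all(c("time", "sensor_id", "value") %in% names(rec))) {
      stop("JSONL record must have fields time, sensor_id, value", call. = FALSE)
    }
  }
  tm <- suppressWarnings(as.numeric(rec$time))
  if (is.na(tm)) {
    stop(sprintf("malformed record: field 'time' ('%s') is not a number", rec$time),
         call. = FALSE)
  }
  if (tm < 0) stop("malformed record: field 'time' must be >= 0", call. = FALSE)
  sid <- as.character(rec$sensor_id)
  if (!nzchar(sid)) stop("malformed record: field 'sensor_id' is empty", call. = FALSE)
  val <- rec$value
  if (!is.null(registry)) {
    spec <- registry[registry$sensor_id == sid, , drop = FALSE]
    if (nrow(spec) == 0) {
      stop(sprintf("sensor '%s' not present in the registry", sid), call. = FALSE)
    }
    val <- coerce_value(val, spec$value_type[1], sid)
  }
  tibble::tibble(time = tm, sensor_id = sid, value = canonical_value(val))
}

coerce_value <- function(value, value_type, sensor_id) {
  v <- as.character(value)
  switch(value_type,
    boolean = {
      lv <- tolower(trimws(v))
      if (!lv %in% c("true", "false", "1", "0", "on", "off")) {
        stop(sprintf("value '%s' of sensor '%s' is not boolean", v, sensor_id),
             call. = FALSE)
      }
      lv %in% c("true", "1", "on")
    },
    real = {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) {
        stop(sprintf("value '%s' of sensor '%s' is not numeric", v, sensor_id),
             call. = FALSE)
      }
      num
    },
    text = v,
    stop(sprintf("unknown value_type '%s'", value_type), call. = FALSE)
  )
}

#' Read and write raw record logs
#'
#' Record logs are plain text: CSV with header `time,sensor_id,value`, or
#' JSONL with one `{"time":..,"sensor_id":..,"value":..}` object per line.
#' Both round-trip bit-exactly through [write_records()] / [read_records()].
#' Logs are kept sorted by `(time, sensor_id)` with stable tie-breaking.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"jsonl"` (default: inferred from the file
#'   extension, falling back to CSV).
#' @return `read_records()` returns a record tibble.
#' @export
read_records <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "csv") {
    if (length(lines) > 0 && identical(lines[1], "time,sensor_id,value")) {
      lines <- lines[-1]
    }
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(time = numeric(0), sensor_id = character(0),
                          value = character(0)))
  }
  dplyr::bind_rows(lapply(lines, parse_record, dialect = dialect))
}

#' @rdname read_records
#' @param records A record tibble (`time`, `sensor_id`, `value`).
#' @export
write_records <- function(records, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  records <- sort_records(records)
  if (dialect == "csv") {
    lines <- c("time,sensor_id,value",
               sprintf("%s,%s,%s", format(records$time, scientific = FALSE, trim = TRUE),
                       records$sensor_id, records$value))
  } else {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(time = records$time[i],
                            sensor_id = records$sensor_id[i],
                            value = records$value[i]),
                       auto_unbox = TRUE)
    }, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_records
#' @export
sort_records <- function(records) {
  records <- tibble::as_tibble(records)
  records[order(records$time, records$sensor_id), , drop = FALSE]
}
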