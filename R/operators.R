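#' Location operators over a person's movement track
#'
#' A track is a tibble of `(time, zone)` placements for one person, sorted by
#' time: the person is in the most recently entered zone. `inside()` and
#' `outside()` are complements on a consistent track; `joint()` detects the
#' data inconsistency of two different zones recorded at the same instant
#' (it is never true for simulator-produced tracks).
#'
#' @param track A data frame with columns `time` and `zone`.
#' @param zone A zone name.
#' @param t Query time; must not precede the first placement for
#'   `inside()`/`outside()`.
#' @return A logical scalar.
#' @examples
#' tr <- tibble::tibble(time = c(0, 100), zone = c("kitchen", "bathroom"))
#' inside(tr, "kitchen", 50)   # TRUE
#' outside(tr, "kitchen", 150) # TRUE
#' joint(tr, 100)              # FALSE
#' @export
inside <- function(track, zone, t) {
  track <- tibble::as_tibble(track)
  stopifnot(all(c("time", "zone") %in% names(track)), nrow(track) > 0)
  if (t < min(track$time)) {
    stop("query time precedes the first placement in the track", call. = FALSE)
  }
  at <- track[track$time <= t, , drop = FALSE]
  any(at$zone[at$time == max(at$time)] == zone)
}

#' @rdname inside
#' @export
outside <- function(track, zone, t) !inside(track, zone, t)

#' @rdname inside
#' @export
joint <- function(track, t) {
  track <- tibble::as_tibble(track)
  stopifnot(all(c("time", "zone") %in% names(track)))
  here <- unique(track$zone[track$time == t])
  length(here) > 1
}

#' Planned-task check for medical measurements
#'
#' Verifies that a scheduled self-care task (e.g. glucose measurement with a
#' glucometer) was performed a coherent number of times each day: the daily
#' count of readings from the device must fall within `per_day_range`.
#'
#' @param readings A data frame of medical readings with columns `time` and
#'   `device`.
#' @param device The device identifier to count.
#' @param per_day_range `c(min, max)` coherence band of readings per day
#'   (`max` may be `Inf`).
#' @param n_days Number of days in the observation window.
#' @param epoch Scenario epoch (seconds), default 0.
#' @return A tibble with one row per day: `day`, `count`, `planned`
#'   (count within band), plus attribute `all_planned` (weekly verdict),
#'   also exposed as column-independent summary via `all()` over `planned`.
#' @examples
#' rd <- tibble::tibble(time = c(3600, 7200, 50000), device = "glucometer")
#' planned_task(rd, "glucometer", c(3, 6), n_days = 1)
#' @export
planned_task <- function(readings, device, per_day_range, n_days, epoch = 0) {
  stopifnot(length(per_day_range) == 2, per_day_range[1] <= per_day_range[2],
            n_days >= 1)
  readings <- tibble::as_tibble(readings)
  rel <- readings[readings$device == device, , drop = FALSE]
  days <- if (nrow(rel) > 0) day_index(rel$time, epoch) else integer(0)
  counts <- tabulate(days + 1L, nbins = n_days)
  out <- tibble::tibble(
    day = seq_len(n_days) - 1L,
    count = counts,
    planned = counts >= per_day_range[1] & counts <= per_day_range[2]
  )
  attr(out, "all_planned") <- all(out$planned)
  out
}

#' Recurrence of an activity across days
#'
#' Counts instances of a named activity per day and judges whether the
#' routine is *regular*: every day's count lies within the expected band.
#'
#' @param acts An activity tibble (see [detect_activities()]) with at least
#'   `name` and `start` columns.
#' @param name The activity name to count.
#' @param n_days Number of days.
#' @param expected `c(min, max)` expected occurrences per day (`max` may be
#'   `Inf`).
#' @param epoch Scenario epoch.
#' @return A tibble `day`, `count`, `within` with attribute `regular`.
#' @export
recurrence <- function(acts, name, n_days, expected, epoch = 0) {
  stopifnot(length(expected) == 2, expected[1] <= expected[2], n_days >= 1)
  acts <- tibble::as_tibble(acts)
  rel <- acts[acts$name == name, , drop = FALSE]
  days <- if (nrow(rel) > 0) day_index(rel$start, epoch) else integer(0)
  counts <- tabulate(days + 1L, nbins = n_days)
  out <- tibble::tibble(
    day = seq_len(n_days) - 1L,
    count = counts,
    within = counts >= expected[1] & counts <= expected[2]
  )
  attr(out, "regular") <- all(out$within)
  out
}

#' Precedence: does an ordered chain of activities exist?
#'
#' Checks whether instances named `sequence[1], sequence[2], ...` can be
#' picked from `acts` such that each one is finished before (or exactly
#' meets) the next — the precedence criterion used when assembling complex
#' situations. Consecutive picks must satisfy the Allen relation `before`
#' or `meets`.
#'
#' @param sequence Character vector of activity names, in required order.
#' @param acts Activity tibble with columns `name`, `start`, `end`.
#' @return `TRUE` iff a chain exists.
#' @examples
#' acts <- tibble::tibble(name = c("door", "flush", "wash"),
#'                        start = c(0, 12, 15), end = c(10, 13, 20))
#' precedence_ok(c("door", "flush", "wash"), acts) # TRUE
#' @export
precedence_ok <- function(sequence, acts) {
  stopifnot(length(sequence) >= 1)
  acts <- tibble::as_tibble(acts)
  # greedy earliest-finish chain; optimal for existence since choosing the
  # earliest-finishing feasible instance can only enlarge later choices
  prev_end <- -Inf
  for (nm in sequence) {
    cand <- acts[acts$name == nm & acts$start >= prev_end &
                   acts$end > acts$start, , drop = FALSE]
    if (nrow(cand) == 0) return(FALSE)
    prev_end <- min(cand$end)
  }
  TRUE
}

#' Concurrency: pairs of temporally intersecting activities
#'
#' Returns the unordered pairs of activities that were both "open" at some
#' common instant, i.e. whose intervals stand in any Allen relation other
#' than `before`/`after`/`meets`/`met_by`.
#'
#' @param acts Activity tibble with columns `name`, `start`, `end` (rows are
#'   treated as distinct instances).
#' @return A tibble with columns `i`, `j` (row indices, `i < j`), `name_i`,
#'   `name_j`.
#' @export
concurrency <- function(acts) {
  acts <- tibble::as_tibble(acts)
  n <- nrow(acts)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        # strict temporal intersection under half-open semantics
        if (acts$start[i] < acts$end[j] && acts$start[j] < acts$end[i]) {
          out[[length(out) + 1]] <- tibble::tibble(
            i = i, j = j, name_i = acts$name[i], name_j = acts$name[j])
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          name_i = character(0), name_j = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Simultaneity: the dominant activity in a window
#'
#' When the inhabitant multitasks (e.g. watching television while eating),
#' the dominant activity is the one occupying the most time within the
#' window. Ties break by earliest start, then lexicographic name.
#'
#' @param acts Activity tibble with columns `name`, `start`, `end`.
#' @param window An [interval()] (or `c(start, end)`).
#' @return The single dominant activity row (a one-row tibble) with an
#'   `overlap` column giving seconds of overlap with the window.
#' @export
dominant <- function(acts, window) {
  acts <- tibble::as_tibble(acts)
  w <- as_interval(window)
  ov <- pmax(0, pmin(acts$end, w$end) - pmax(acts$start, w$start))
  if (all(ov <= 0)) {
    stop("no activity intersects the window", call. = FALSE)
  }
  acts$overlap <- ov
  acts <- acts[ov > 0, , drop = FALSE]
  acts <- acts[order(-acts$overlap, acts$start, acts$name), , drop = FALSE]
  acts[1, , drop = FALSE]
}
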