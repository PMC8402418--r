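#' Time intervals and Allen's interval algebra
#'
#' Intervals are half-open `[start, end)` spans measured in integer seconds
#' from the scenario epoch. Two intervals *meet* exactly when the first ends
#' at the second's start; the half-open convention makes the thirteen Allen
#' relations mutually exclusive without epsilon tolerances.
#'
#' @param start,end Numeric scalars (seconds since epoch), `start <= end`.
#' @return `interval()` returns an object of class `adl_interval` with fields
#'   `start` and `end`.
#' @examples
#' x <- interval(0, 5)
#' y <- interval(5, 9)
#' allen_relation(x, y) # "meets"
#' @export
interval <- function(start, end) {
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1 ||
      length(end) != 1 || is.na(start) || is.na(end)) {
    stop("interval endpoints must be single non-missing numbers", call. = FALSE)
  }
  if (start > end) {
    stop("interval start must not exceed end", call. = FALSE)
  }
  structure(list(start = as.numeric(start), end = as.numeric(end)),
            class = "adl_interval")
}

#' @export
print.adl_interval <- function(x, ...) {
  cat(sprintf("[%s, %s)\n", format(x$start), format(x$end)))
  invisible(x)
}

#' @rdname interval
#' @param x An `adl_interval`.
#' @export
interval_duration <- function(x) x$end - x$start

as_interval <- function(x) {
  if (inherits(x, "adl_interval")) return(x)
  if (is.numeric(x) && length(x) == 2) return(interval(x[1], x[2]))
  stop("cannot interpret object as an interval", call. = FALSE)
}

#' The thirteen Allen relations
#'
#' @return Character vector of the 13 relation names.
#' @export
allen_relations <- function() {
  c("before", "meets", "overlaps", "starts", "during", "finishes", "equals",
    "after", "met_by", "overlapped_by", "started_by", "contains", "finished_by")
}

#' Classify the Allen relation between two intervals
#'
#' Determines which of the thirteen qualitative interval relations holds
#' between `x` and `y` under half-open semantics. Degenerate (zero-length)
#' intervals are rejected: the activity model only manipulates extended
#' spans, and admitting points would break mutual exclusivity.
#'
#' @param x,y `adl_interval` objects (or length-2 numeric `c(start, end)`).
#' @return A single relation name (see [allen_relations()]).
#' @examples
#' allen_relation(interval(0, 1), interval(2, 3)) # "before"
#' allen_relation(interval(0, 5), interval(5, 9)) # "meets"
#' @export
allen_relation <- function(x, y) {
  x <- as_interval(x); y <- as_interval(y)
  if (interval_duration(x) <= 0 || interval_duration(y) <= 0) {
    stop("allen_relation requires non-degenerate intervals (duration > 0)",
         call. = FALSE)
  }
  x1 <- x$start; x2 <- x$end; y1 <- y$start; y2 <- y$end
  if (x2 < y1) return("before")
  if (x2 == y1) return("meets")
  if (y2 < x1) return("after")
  if (y2 == x1) return("met_by")
  if (x1 == y1 && x2 == y2) return("equals")
  if (x1 == y1) return(if (x2 < y2) "starts" else "started_by")
  if (x2 == y2) return(if (x1 > y1) "finishes" else "finished_by")
  if (x1 > y1 && x2 < y2) return("during")
  if (x1 < y1 && x2 > y2) return("contains")
  if (x1 < y1) return("overlaps")
  "overlapped_by"
}

#' Inverse of an Allen relation
#'
#' `allen_relation(x, y) == r` if and only if
#' `allen_relation(y, x) == allen_inverse(r)`; `equals` is self-inverse.
#'
#' @param r A relation name.
#' @return The inverse relation name.
#' @export
allen_inverse <- function(r) {
  inv <- c(before = "after", after = "before",
           meets = "met_by", met_by = "meets",
           overlaps = "overlapped_by", overlapped_by = "overlaps",
           starts = "started_by", started_by = "starts",
           during = "contains", contains = "during",
           finishes = "finished_by", finished_by = "finishes",
           equals = "equals")
  r <- match.arg(r, allen_relations())
  unname(inv[[r]])
}

#' Metric temporal constraints over an Allen relation
#'
#' A temporal constraint couples an Allen relation with optional metric
#' windows on the *first* operand: `start_window` bounds where `x` may start
#' and `end_window` bounds where `x` may end. Windows are closed at finite
#' endpoints; `Inf` expresses an open upper bound. So the constraint
#' `meets [t1, t2] [0, Inf)` reads: `y` must be met by `x`, `x` must start
#' between `t1` and `t2`, and `x` may end at any time (which, under `meets`,
#' is exactly the start of `y`).
#'
#' @param relation An Allen relation name.
#' @param start_window Optional `c(lower, upper)` bound on `x$start`.
#' @param end_window Optional `c(lower, upper)` bound on `x$end`.
#' @return An object of class `adl_constraint`.
#' @examples
#' ct <- temporal_constraint("meets", start_window = c(2, 5))
#' satisfies_constraint(interval(3, 7), interval(7, 9), ct) # TRUE
#' @export
temporal_constraint <- function(relation, start_window = NULL, end_window = NULL) {
  relation <- match.arg(relation, allen_relations())
  check_window <- function(w, what) {
    if (is.null(w)) return(NULL)
    if (!is.numeric(w) || length(w) != 2 || anyNA(w) || w[1] > w[2]) {
      stop(sprintf("%s must be c(lower, upper) with lower <= upper", what),
           call. = FALSE)
    }
    as.numeric(w)
  }
  structure(
    list(relation = relation,
         start_window = check_window(start_window, "start_window"),
         end_window = check_window(end_window, "end_window")),
    class = "adl_constraint"
  )
}

#' Check a bounded temporal constraint between two intervals
#'
#' @param x,y Intervals (first and second operand).
#' @param constraint An [temporal_constraint()] object.
#' @return `TRUE` iff the Allen relation of `(x, y)` matches and `x`'s start
#'   and end lie inside the respective windows (when given).
#' @export
satisfies_constraint <- function(x, y, constraint) {
  stopifnot(inherits(constraint, "adl_constraint"))
  x <- as_interval(x); y <- as_interval(y)
  if (allen_relation(x, y) != constraint$relation) return(FALSE)
  in_window <- function(t, w) is.null(w) || (t >= w[1] && t <= w[2])
  in_window(x$start, constraint$start_window) &&
    in_window(x$end, constraint$end_window)
}
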