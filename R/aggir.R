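#' AGGIR per-variable daily criteria
#'
#' A criterion lists, for one AGGIR variable, the daily rules that complete
#' situations must satisfy for the day to pass, as `(situation, min, max)`
#' clauses combined conjunctively, plus an optional precondition variable:
#' every counted situation must be preceded (Allen `before`/`meets`) by a
#' complete situation of the precondition variable.
#'
#' The defaults encode the study conditions: toileting at least three times
#' a day; dressing (approaching the wardrobe) at least twice a day;
#' transfers as the conjunction of at least three sitting events and at
#' least one rising-from-bed event per day; cooking and alimentation each at
#' least three times a day, alimentation only counting when triggered by a
#' prior cooking; glucometer measurements within the three-to-six per day
#' coherence band.
#'
#' @param variable Variable name.
#' @param rules A data frame with columns `situation`, `min`, `max`.
#' @param precondition Optional variable name that must precede counted
#'   situations.
#' @return `aggir_criterion()` returns a one-row tibble; `aggir_criteria()`
#'   the default criterion table.
#' @export
aggir_criterion <- function(variable, rules, precondition = NA_character_) {
  rules <- tibble::as_tibble(rules)
  stopifnot(all(c("situation", "min") %in% names(rules)))
  if (!"max" %in% names(rules)) rules$max <- Inf
  if (any(rules$min < 1)) stop("rule minima must be >= 1", call. = FALSE)
  tibble::tibble(variable = variable, rules = list(rules),
                 precondition = precondition)
}

.criteria_cache <- new.env(parent = emptyenv())

#' @rdname aggir_criterion
#' @export
aggir_criteria <- function() {
  if (!is.null(.criteria_cache$default)) return(.criteria_cache$default)
  .criteria_cache$default <- dplyr::bind_rows(
    aggir_criterion("toileting",
                    tibble::tibble(situation = "toileting", min = 3, max = Inf)),
    aggir_criterion("dressing",
                    tibble::tibble(situation = "dressing", min = 2, max = Inf)),
    aggir_criterion("transfers",
                    tibble::tibble(situation = c("transfer_sitting", "transfer_rising"),
                                   min = c(3, 1), max = c(Inf, Inf))),
    aggir_criterion("cooking",
                    tibble::tibble(situation = "cooking", min = 3, max = Inf)),
    aggir_criterion("alimentation",
                    tibble::tibble(situation = "alimentation", min = 3, max = Inf),
                    precondition = "cooking"),
    aggir_criterion("glucose",
                    tibble::tibble(situation = "glucose_measurement", min = 3, max = 6))
  )
  .criteria_cache$default
}

# situations of `variable` that count toward the criterion: complete, and
# preceded by a complete precondition situation when one is required
counted_situations <- function(criterion, situations) {
  sit <- vctrs::vec_slice(situations,
                          which(situations$variable == criterion$variable &
                                  situations$complete))
  pre <- criterion$precondition
  if (!is.na(pre) && nrow(sit) > 0) {
    trig_end <- situations$end[situations$variable == pre & situations$complete]
    # "some trigger ends at or before the start" == "start >= earliest end"
    ok <- if (length(trig_end) == 0) rep(FALSE, nrow(sit)) else
      sit$start >= min(trig_end)
    sit <- vctrs::vec_slice(sit, which(ok))
  }
  sit
}

#' Score one day of one AGGIR variable
#'
#' @param criterion A one-row criterion (see [aggir_criterion()]).
#' @param situations The full situation tibble for the observation window
#'   (all variables; preconditions are resolved against it).
#' @param day Day index (0-based).
#' @return A one-row tibble: `day`, `variable`, `n_detected` (all detected
#'   situations of the variable that day, complete or not — the quantity a
#'   daily report prints), `n_complete`, `n_counted` (complete and
#'   precondition-satisfied; the basis of `pass`), `pass`.
#' @export
evaluate_day <- function(criterion, situations, day) {
  criterion <- tibble::as_tibble(criterion)
  stopifnot(nrow(criterion) == 1)
  situations <- tibble::as_tibble(situations)
  var_day <- situations[situations$variable == criterion$variable &
                          situations$day == day, , drop = FALSE]
  counted <- counted_situations(criterion, situations)
  counted <- counted[counted$day == day, , drop = FALSE]
  rules <- criterion$rules[[1]]
  pass <- TRUE
  for (i in seq_len(nrow(rules))) {
    k <- sum(counted$situation == rules$situation[i])
    if (k < rules$min[i] || k > rules$max[i]) pass <- FALSE
  }
  tibble::tibble(day = as.integer(day), variable = criterion$variable,
                 n_detected = nrow(var_day), n_complete = sum(var_day$complete),
                 n_counted = nrow(counted), pass = pass)
}

#' Score a week of one AGGIR variable
#'
#' The two-state verdict: `"C"` (complete independency) iff every day
#' passes, otherwise `"A"` (complete dependency). The intermediate `"B"`
#' state is deliberately not producible.
#'
#' @param criterion A one-row criterion.
#' @param days A tibble of exactly `n_days` day results from
#'   [evaluate_day()].
#' @param n_days Expected number of days (default 7).
#' @return A one-row tibble: `variable`, `total` (sum of detected counts),
#'   `n_pass_days`, `state`.
#' @export
evaluate_week <- function(criterion, days, n_days = 7) {
  if (!is.data.frame(days)) days <- tibble::as_tibble(days)
  if (nrow(days) != n_days) {
    stop(sprintf("expected %d day results, got %d", n_days, nrow(days)),
         call. = FALSE)
  }
  tibble::new_tibble(list(variable = criterion$variable,
                          total = sum(days$n_detected),
                          total_complete = sum(days$n_complete),
                          n_pass_days = sum(days$pass),
                          state = if (all(days$pass)) "C" else "A"),
                     nrow = 1L)
}

#' Assess all AGGIR variables over an observation window
#'
#' Runs [evaluate_day()] and [evaluate_week()] for every criterion variable
#' present in the situation stream (or the given subset).
#'
#' @param situations Situation tibble from [detect_situations()].
#' @param criteria Criterion table, default [aggir_criteria()].
#' @param n_days Number of days in the window.
#' @param variables Variables to assess; defaults to those present in both
#'   `situations` and `criteria`.
#' @return An object of class `aggir_assessment` with components `days`
#'   and `weeks`; see [tidy.aggir_assessment()] and
#'   [glance.aggir_assessment()].
#' @export
aggir_assess <- function(situations, criteria = aggir_criteria(), n_days = 7,
                         variables = NULL) {
  if (!tibble::is_tibble(situations)) situations <- tibble::as_tibble(situations)
  if (is.null(variables)) {
    variables <- intersect(criteria$variable, unique(situations$variable))
  }
  missing_c <- setdiff(variables, criteria$variable)
  if (length(missing_c) > 0) {
    stop(sprintf("no criterion configured for variable(s): %s",
                 paste(missing_c, collapse = ", ")), call. = FALSE)
  }
  days <- list(); weeks <- list()
  for (v in variables) {
    crit <- criteria[criteria$variable == v, , drop = FALSE]
    # one pass per variable: per-day tallies via tabulate, then the rules
    var_all <- vctrs::vec_slice(situations, which(situations$variable == v))
    counted <- counted_situations(crit, situations)
    n_detected <- tabulate(var_all$day + 1L, nbins = n_days)
    n_complete <- tabulate(var_all$day[var_all$complete] + 1L, nbins = n_days)
    n_counted <- tabulate(counted$day + 1L, nbins = n_days)
    rules <- crit$rules[[1]]
    pass <- rep(TRUE, n_days)
    for (i in seq_len(nrow(rules))) {
      k <- tabulate(counted$day[counted$situation == rules$situation[i]] + 1L,
                    nbins = n_days)
      pass <- pass & k >= rules$min[i] & k <= rules$max[i]
    }
    dres <- tibble::new_tibble(list(
      day = seq_len(n_days) - 1L, variable = rep.int(v, n_days),
      n_detected = n_detected, n_complete = n_complete,
      n_counted = n_counted, pass = pass), nrow = n_days)
    days[[v]] <- dres
    weeks[[v]] <- evaluate_week(crit, dres, n_days)
  }
  structure(list(days = dplyr::bind_rows(days),
                 weeks = dplyr::bind_rows(weeks),
                 n_days = n_days),
            class = "aggir_assessment")
}

#' @export
print.aggir_assessment <- function(x, ...) {
  cat(sprintf("<aggir_assessment> %d day(s), %d variable(s)\n",
              x$n_days, nrow(x$weeks)))
  print(x$weeks)
  invisible(x)
}

#' Tidy an AGGIR assessment into day-level results
#'
#' @param x An `aggir_assessment`.
#' @param ... Unused.
#' @return The day-level tibble (`day`, `variable`, `n_detected`,
#'   `n_complete`, `n_counted`, `pass`).
#' @method tidy aggir_assessment
#' @export
tidy.aggir_assessment <- function(x, ...) x$days

#' One-row-per-variable summary of an AGGIR assessment
#'
#' @param x An `aggir_assessment`.
#' @param ... Unused.
#' @return The week-level tibble (`variable`, `total`, `total_complete`,
#'   `n_pass_days`, `state`).
#' @method glance aggir_assessment
#' @export
glance.aggir_assessment <- function(x, ...) x$weeks

#' Number of failing (day, variable) cells
#'
#' @param assessment An `aggir_assessment` (or its day tibble).
#' @return Integer count of day results with `pass == FALSE`.
#' @export
count_problem_days <- function(assessment) {
  days <- if (inherits(assessment, "aggir_assessment")) assessment$days else
    tibble::as_tibble(assessment)
  sum(!days$pass)
}

DAY_LABELS <- c("MON", "TUE", "WED", "THU", "FRI", "SAT", "SUN")

day_label <- function(day) {
  ifelse(day < length(DAY_LABELS), DAY_LABELS[day + 1], paste0("D", day + 1))
}

#' Write and read the history log
#'
#' The history log is a chronological JSONL account of everything the
#' analyzer concluded: a header line, one line per situation (with day,
#' variable, completeness and the zone it happened in, supporting
#' location-coherence checks), and one line per anomaly. Re-evaluating a
#' read-back log reproduces the original assessment.
#'
#' @param situations Situation tibble.
#' @param anomalies Anomaly tibble (may be empty).
#' @param path Output path.
#' @return `write_history_log()` returns `path` invisibly;
#'   `read_history_log()` a list with `situations` and `anomalies` tibbles.
#' @export
write_history_log <- function(situations, anomalies = NULL, path) {
  situations <- tibble::as_tibble(situations)
  lines <- jsonlite::toJSON(list(type = "header", format = "aggirhome-history",
                                 n_situations = nrow(situations),
                                 n_anomalies = if (is.null(anomalies)) 0L else nrow(anomalies)),
                            auto_unbox = TRUE)
  if (nrow(situations) > 0) {
    sit <- situations[order(situations$start), , drop = FALSE]
    lines <- c(lines, vapply(seq_len(nrow(sit)), function(i) {
      jsonlite::toJSON(list(type = "situation", situation = sit$situation[i],
                            variable = sit$variable[i], start = sit$start[i],
                            end = sit$end[i], day = sit$day[i],
                            complete = sit$complete[i],
                            n_members = sit$n_members[i],
                            location = sit$location[i]),
                       auto_unbox = TRUE, na = "null")
    }, ""))
  }
  if (!is.null(anomalies) && nrow(anomalies) > 0) {
    lines <- c(lines, vapply(seq_len(nrow(anomalies)), function(i) {
      jsonlite::toJSON(list(type = "anomaly", rule = anomalies$rule[i],
                            time = anomalies$time[i], zone = anomalies$zone[i],
                            variables = anomalies$variables[[i]]),
                       auto_unbox = TRUE, na = "null")
    }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_history_log
#' @export
read_history_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  types <- vapply(recs, `[[`, "", "type")
  sit <- recs[types == "situation"]
  situations <- if (length(sit) > 0) {
    dplyr::bind_rows(lapply(sit, function(r) {
      tibble::tibble(situation = r$situation, variable = r$variable,
                     start = r$start, end = r$end, day = as.integer(r$day),
                     complete = r$complete, n_members = as.integer(r$n_members),
                     location = r$location %||% NA_character_)
    }))
  } else {
    tibble::tibble(situation = character(0), variable = character(0),
                   start = numeric(0), end = numeric(0), day = integer(0),
                   complete = logical(0), n_members = integer(0),
                   location = character(0))
  }
  an <- recs[types == "anomaly"]
  anomalies <- if (length(an) > 0) {
    dplyr::bind_rows(lapply(an, function(r) {
      tibble::tibble(rule = r$rule, time = r$time,
                     zone = r$zone %||% NA_character_,
                     variables = list(unlist(r$variables)))
    }))
  } else {
    tibble::tibble(rule = character(0), time = numeric(0),
                   zone = character(0), variables = list())
  }
  list(situations = situations, anomalies = anomalies)
}

#' Render the weekly report
#'
#' A textual twin of the assessment: per variable, one row per day with the
#' detected count and a pass mark, a total row, and the final A/C state;
#' plus a machine-readable list mirror.
#'
#' @param assessment An `aggir_assessment`.
#' @param anomalies Optional anomaly tibble to append.
#' @return An object of class `aggir_report` with components `text`
#'   (character lines) and `data` (a list serializable with
#'   [jsonlite::toJSON()]).
#' @export
render_report <- function(assessment, anomalies = NULL) {
  stopifnot(inherits(assessment, "aggir_assessment"))
  text <- character(0)
  data <- list(variables = list())
  for (v in assessment$weeks$variable) {
    d <- assessment$days[assessment$days$variable == v, , drop = FALSE]
    w <- assessment$weeks[assessment$weeks$variable == v, , drop = FALSE]
    text <- c(text, sprintf("Variable: %s", v))
    for (i in seq_len(nrow(d))) {
      text <- c(text, sprintf("  %-4s %4d  %s", day_label(d$day[i]),
                              d$n_detected[i], if (d$pass[i]) "PASS" else "FAIL"))
    }
    text <- c(text, sprintf("  %-4s %4d  state %s", "Total", w$total, w$state), "")
    data$variables[[v]] <- list(
      days = lapply(seq_len(nrow(d)), function(i) {
        list(day = d$day[i], label = day_label(d$day[i]),
             count = d$n_detected[i], complete = d$n_complete[i],
             pass = d$pass[i])
      }),
      total = w$total, state = w$state
    )
  }
  if (!is.null(anomalies) && nrow(anomalies) > 0) {
    text <- c(text, sprintf("Anomalies: %d", nrow(anomalies)),
              sprintf("  t=%s %s", format(anomalies$time), anomalies$rule))
    data$anomalies <- lapply(seq_len(nrow(anomalies)), function(i) {
      list(rule = anomalies$rule[i], time = anomalies$time[i],
           zone = anomalies$zone[i])
    })
  }
  data$problem_days <- count_problem_days(assessment)
  structure(list(text = text, data = data), class = "aggir_report")
}

#' @export
print.aggir_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' @rdname render_report
#' @param report An `aggir_report`.
#' @param path Output path for the JSON mirror.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "aggir_report"))
  jsonlite::write_json(report$data, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
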