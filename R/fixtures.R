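#' Situation templates used by the scenario generators
#'
#' Each monitored variable has a fixed command template (sensor sequence and
#' dwell durations) that, when simulated and analyzed, yields exactly one
#' complete situation. Incomplete variants omit one essential member
#' (toileting: the flush; dressing: the changing-clothes dwell; cooking:
#' the oven; alimentation: the meal-on-table event). Durations are fixture
#' constants chosen as plausible task lengths; the recognition rules do not
#' depend on them beyond the situation span bounds.
#'
#' @keywords internal
#' @noRd
template_commands <- function(variable, t0, complete = TRUE, role = "normal",
                              person = "resident", value = NULL) {
  cmd <- function(at, kind, target, value) {
    tibble::tibble(at = t0 + at, kind = kind, target = target,
                   value = as.character(value))
  }
  back <- function(at) cmd(at, "move-person", person, "livingroom")
  switch(variable,
    toileting = dplyr::bind_rows(
      cmd(0, "move-person", person, "bathroom"),
      cmd(10, "set-device", "bathroom_door", "true"),
      cmd(70, "set-device", "bathroom_door", "false"),
      if (complete) dplyr::bind_rows(
        cmd(90, "set-device", "toilet_flush", "true"),
        cmd(95, "set-device", "toilet_flush", "false")
      ),
      cmd(110, "set-device", "washbasin", "1"),
      cmd(170, "set-device", "washbasin", "0"),
      back(220)
    ),
    dressing = dplyr::bind_rows(
      cmd(0, "move-person", person, "bedroom"),
      cmd(10, "set-device", "wardrobe_door", "true"),
      cmd(55, "set-device", "wardrobe_door", "false"),
      if (complete) dplyr::bind_rows(
        cmd(65, "set-device", "wardrobe_proximity", "1"),
        cmd(245, "set-device", "wardrobe_proximity", "0")
      ),
      back(260)
    ),
    transfers = if (identical(role, "rising")) {
      dplyr::bind_rows(
        cmd(0, "move-person", person, "bedroom"),
        cmd(10, "set-device", "bed_capacitive", "true"),
        cmd(1210, "set-device", "bed_capacitive", "false"),
        back(1260)
      )
    } else {
      dplyr::bind_rows(
        cmd(10, "set-device", "livingroom_chair", "true"),
        cmd(310, "set-device", "livingroom_chair", "false")
      )
    },
    cooking = dplyr::bind_rows(
      cmd(0, "move-person", person, "kitchen"),
      cmd(20, "set-device", "fridge_door", "true"),
      cmd(50, "set-device", "fridge_door", "false"),
      cmd(70, "set-device", "cabinet_door", "true"),
      cmd(100, "set-device", "cabinet_door", "false"),
      cmd(130, "set-device", "stove", "true"),
      cmd(730, "set-device", "stove", "false"),
      if (complete) dplyr::bind_rows(
        cmd(760, "set-device", "oven", "true"),
        cmd(1060, "set-device", "oven", "false")
      ),
      back(1100)
    ),
    alimentation = dplyr::bind_rows(
      cmd(10, "set-device", "diningroom_chair", "true"),
      cmd(70, "set-device", "diningroom_chair", "false"),
      if (complete) dplyr::bind_rows(
        cmd(90, "set-device", "diningroom_table", "true"),
        cmd(150, "set-device", "diningroom_table", "false")
      ),
      cmd(170, "move-person", person, "diningroom"),
      back(1300)
    ),
    glucose = cmd(0, "medical-reading", "glucometer", value),
    stop(sprintf("no template for variable '%s'", variable), call. = FALSE)
  )
}

template_duration <- function(variable, role = "normal") {
  switch(variable,
    toileting = 220, dressing = 260,
    transfers = if (identical(role, "rising")) 1260 else 310,
    cooking = 1100, alimentation = 1300, glucose = 1,
    stop(sprintf("no template for variable '%s'", variable), call. = FALSE)
  )
}

WAKING_START <- 6 * 3600   # daily activity band: 06:00 ..
WAKING_END <- 22 * 3600    # .. 22:00

# per-day job list: round-robin across variables (so situations of different
# variables interleave through the day), cooking drawn before alimentation
# so every meal has a same-day cooking trigger, and the rising-from-bed
# transfer first (the morning rise)
day_jobs <- function(counts_today, failures_today) {
  queues <- list()
  for (v in names(counts_today)) {
    n <- counts_today[[v]]
    complete <- rep(TRUE, n)
    role <- rep("normal", n)
    if (v == "transfers" && n > 0) role[1] <- "rising"
    f <- failures_today[failures_today$variable == v, , drop = FALSE]
    if (nrow(f) > 0) {
      mode <- f$mode[1]; k <- f$k[1]
      if (mode == "drop-all") {
        n <- 0L
      } else if (mode == "reduce-to") {
        n <- min(n, k)
      } else if (mode == "make-incomplete") {
        if (v == "transfers") {
          # k rising events, remainder plain sittings
          role <- c(rep("rising", min(k, n)), rep("normal", max(0, n - k)))
        } else {
          complete <- seq_len(n) <= k
        }
      } else {
        stop(sprintf("unknown failure mode '%s'", mode), call. = FALSE)
      }
      complete <- complete[seq_len(n)]
      role <- role[seq_len(n)]
    }
    if (n > 0) {
      queues[[v]] <- tibble::tibble(variable = v, complete = complete, role = role)
    }
  }
  jobs <- list()
  while (any(vapply(queues, nrow, 0L) > 0)) {
    for (v in names(queues)) {
      if (nrow(queues[[v]]) > 0) {
        jobs[[length(jobs) + 1]] <- queues[[v]][1, ]
        queues[[v]] <- queues[[v]][-1, , drop = FALSE]
      }
    }
  }
  if (length(jobs) == 0) {
    return(tibble::tibble(variable = character(0), complete = logical(0),
                          role = character(0)))
  }
  dplyr::bind_rows(jobs)
}

#' Build a multi-day scenario embedding known situation counts
#'
#' The central synthetic-data generator: for every day and variable it
#' embeds exactly the requested number of situation templates, jittered
#' deterministically (by `seed`) within the 06:00-22:00 activity band, and
#' applies the failure specification. A failure is one of:
#'
#' * `drop-all` — no situations of the variable that day;
#' * `reduce-to` (`k`) — keep only the first `k`;
#' * `make-incomplete` (`k`) — keep `k` complete, emit the rest with one
#'   essential member missing. For transfers, where every single-activity
#'   situation is trivially complete, `k` is the number of rising-from-bed
#'   events (so `k = 0` yields a day of sittings with no rise).
#'
#' The generator is a bijection from `(counts, failures, seed)` to scenario
#' content: identical inputs produce identical scenarios, and the analyzer
#' recovers the embedded per-day counts exactly.
#'
#' @param counts Named list: variable name to integer vector of per-day
#'   complete-situation counts (length `n_days`).
#' @param failures Optional data frame with columns `day` (0-based),
#'   `variable`, `mode`, `k`.
#' @param seed Integer seed driving the start-time jitter.
#' @param n_days Number of days (default 7).
#' @param registry Sensor registry.
#' @param person Inhabitant ID.
#' @return An `adl_scenario`.
#' @examples
#' wk <- build_week(list(toileting = rep(3, 7)), seed = 1)
#' @export
build_week <- function(counts, failures = NULL, seed = 1L, n_days = 7,
                       registry = default_home_registry(),
                       person = "resident") {
  stopifnot(is.list(counts), length(counts) > 0)
  for (v in names(counts)) {
    if (length(counts[[v]]) != n_days) {
      stop(sprintf("counts$%s must have %d per-day values", v, n_days),
           call. = FALSE)
    }
    if (any(counts[[v]] < 0)) stop("per-day counts must be >= 0", call. = FALSE)
  }
  if (is.null(failures)) {
    failures <- tibble::tibble(day = integer(0), variable = character(0),
                               mode = character(0), k = integer(0))
  }
  failures <- tibble::as_tibble(failures)
  if (!"k" %in% names(failures)) failures$k <- NA_integer_
  band <- WAKING_END - WAKING_START
  with_local_seed(seed, {
    commands <- vector("list", n_days + 1)
    commands[[1]] <- tibble::tibble(at = 0, kind = "move-person",
                                    target = person, value = "livingroom")
    for (d in seq_len(n_days) - 1L) {
      today <- lapply(counts, function(x) x[d + 1])
      jobs <- day_jobs(today, failures[failures$day == d, , drop = FALSE])
      n_jobs <- nrow(jobs)
      if (n_jobs == 0) next
      slot_w <- band / n_jobs
      day_cmds <- vector("list", n_jobs)
      for (i in seq_len(n_jobs)) {
        dur <- template_duration(jobs$variable[i], jobs$role[i])
        if (slot_w < dur + 60) {
          stop(sprintf("infeasible packing on day %d: %d situations do not fit the activity band",
                       d, n_jobs), call. = FALSE)
        }
        jitter <- floor(stats::runif(1, 0, slot_w - dur - 30))
        t0 <- d * SECONDS_PER_DAY + WAKING_START + (i - 1) * slot_w + jitter
        value <- if (jobs$variable[i] == "glucose") {
          round(stats::runif(1, 80, 150), 1)
        }
        day_cmds[[i]] <- template_commands(jobs$variable[i], floor(t0),
                                           complete = jobs$complete[i],
                                           role = jobs$role[i],
                                           person = person, value = value)
      }
      commands[[d + 2]] <- dplyr::bind_rows(day_cmds)
    }
    script <- dplyr::bind_rows(commands)
    scenario(duration = n_days * SECONDS_PER_DAY, registry = registry,
             persons = person, script = script)
  })
}

#' Build a week of scheduled glucometer measurements
#'
#' @param per_day Integer vector: glucometer readings per day.
#' @param seed Jitter seed.
#' @param n_days Number of days (defaults to `length(per_day)`).
#' @inheritParams build_week
#' @return An `adl_scenario` emitting the requested medical readings at
#'   spread times.
#' @export
build_glucose_week <- function(per_day, seed = 1L, n_days = length(per_day),
                               registry = default_home_registry(),
                               person = "resident") {
  build_week(list(glucose = per_day), seed = seed, n_days = n_days,
             registry = registry, person = person)
}

#' Reference weekly scenarios
#'
#' The study conditions as count specifications: an ideal week in which the
#' resident performs every monitored ADL without impediment, and a
#' failure-injected week in which three (day, variable) problems are
#' planted — a day without dressing, a day of sittings with no rise from
#' bed, and a day whose toileting sequences are mostly left incomplete.
#' Analogous pairs exist for the cooking/alimentation week and for the
#' glucometer planned-task week.
#'
#' @param name One of `"ideal-adl"`, `"faulty-adl"`, `"ideal-meal"`,
#'   `"faulty-meal"`, `"ideal-glucose"`, `"faulty-glucose"`.
#' @return A list with `counts` (named list of per-day counts) and
#'   `failures` (tibble or `NULL`).
#' @export
reference_week_spec <- function(name = c("ideal-adl", "faulty-adl",
                                         "ideal-meal", "faulty-meal",
                                         "ideal-glucose", "faulty-glucose")) {
  name <- match.arg(name)
  switch(name,
    "ideal-adl" = list(
      counts = list(transfers = c(7, 6, 7, 7, 8, 8, 6),
                    toileting = c(8, 8, 11, 10, 8, 6, 9),
                    dressing = c(3, 3, 2, 2, 3, 4, 3)),
      failures = NULL
    ),
    "faulty-adl" = list(
      counts = list(transfers = c(7, 7, 7, 6, 8, 3, 6),
                    toileting = c(7, 7, 11, 11, 8, 6, 6),
                    dressing = c(3, 0, 2, 3, 3, 4, 2)),
      failures = tibble::tibble(
        day = c(1L, 5L, 6L),
        variable = c("dressing", "transfers", "toileting"),
        mode = c("drop-all", "make-incomplete", "make-incomplete"),
        k = c(NA_integer_, 0L, 2L))
    ),
    "ideal-meal" = list(
      counts = list(cooking = c(12, 11, 9, 11, 10, 10, 9),
                    alimentation = c(7, 9, 9, 8, 8, 9, 7)),
      failures = NULL
    ),
    "faulty-meal" = list(
      counts = list(cooking = c(7, 10, 11, 5, 9, 7, 10),
                    alimentation = c(9, 6, 8, 8, 3, 5, 9)),
      failures = tibble::tibble(
        day = c(0L, 3L, 5L, 1L, 4L, 5L),
        variable = c(rep("cooking", 3), rep("alimentation", 3)),
        mode = "make-incomplete",
        k = 2L)
    ),
    "ideal-glucose" = list(
      counts = list(glucose = c(3, 3, 6, 4, 3, 3, 5)),
      failures = NULL
    ),
    "faulty-glucose" = list(
      counts = list(glucose = c(6, 1, 3, 0, 3, 4, 2)),
      failures = NULL
    )
  )
}

#' @rdname reference_week_spec
#' @param seed Jitter seed passed to [build_week()].
#' @inheritParams build_week
#' @return `reference_week()` returns the built `adl_scenario`.
#' @export
reference_week <- function(name, seed = 1L,
                           registry = default_home_registry()) {
  spec <- reference_week_spec(name)
  build_week(spec$counts, spec$failures, seed = seed, registry = registry)
}

#' Randomized scenario with ground-truth labels
#'
#' Draws per-day counts uniformly within the given ranges, builds the
#' scenario (all situations complete; one transfer per day is a rise when
#' the count allows), and returns the exact embedded counts together with
#' the pass/fail label each day should receive under the default criteria —
#' the recovery oracle for end-to-end testing.
#'
#' @param rates Named list: variable to `c(min, max)` per-day count range.
#'   Variables must be among toileting, dressing, transfers, cooking,
#'   alimentation, glucose.
#' @param seed Integer seed (drawing and jitter).
#' @param n_days Number of days.
#' @inheritParams build_week
#' @return A list with `scenario` (an `adl_scenario`) and `truth` (a tibble
#'   `day`, `variable`, `n_embedded`, `pass`).
#' @export
random_week <- function(rates, seed = 1L, n_days = 7,
                        registry = default_home_registry()) {
  known <- c("toileting", "dressing", "transfers", "cooking", "alimentation",
             "glucose")
  bad <- setdiff(names(rates), known)
  if (length(bad) > 0) {
    stop(sprintf("no template for variable(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  # draw counts under seed, then delegate scenario construction to a
  # derived jitter seed so both draws are reproducible
  counts <- with_local_seed(seed, {
    lapply(rates, function(r) {
      stopifnot(length(r) == 2, r[1] <= r[2], r[1] >= 0)
      if (r[1] == r[2]) rep(as.integer(r[1]), n_days) else
        sample(seq(r[1], r[2]), n_days, replace = TRUE)
    })
  })
  # keep cooking ahead of alimentation in the round-robin so meals have
  # same-day triggers whenever cooking occurs at all
  ord <- intersect(known, names(counts))
  counts <- counts[ord]
  scn <- build_week(counts, failures = NULL, seed = seed + 1L,
                    n_days = n_days, registry = registry)
  truth <- list()
  cooking_so_far <- 0L
  for (d in seq_len(n_days) - 1L) {
    cooked_today <- if ("cooking" %in% names(counts)) counts$cooking[d + 1] else 0L
    for (v in names(counts)) {
      n <- counts[[v]][d + 1]
      pass <- switch(v,
        toileting = n >= 3,
        dressing = n >= 2,
        transfers = n >= 4,  # >= 3 sittings plus the single rise
        cooking = n >= 3,
        alimentation = {
          counted <- if (cooked_today > 0 || cooking_so_far > 0) n else 0L
          counted >= 3
        },
        glucose = n >= 3 && n <= 6
      )
      truth[[length(truth) + 1]] <- tibble::tibble(
        day = d, variable = v, n_embedded = as.integer(n), pass = pass)
    }
    cooking_so_far <- cooking_so_far + cooked_today
  }
  list(scenario = scn, truth = dplyr::bind_rows(truth))
}
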