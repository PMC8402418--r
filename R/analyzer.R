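#' Classify raw records into typed events
#'
#' The record filter turns the raw log into typed events, one category per
#' record:
#'
#' * presence-sensor transitions become `MoveEvent`s (entering sets
#'   `destination`, leaving sets `origin`);
#' * zone-variable changes (pseudo-sensor `zone#variable`) become
#'   `VarChangingEvent`s carrying `old` and `new` values;
#' * device property changes (doors, switches, capacitive and proximity
#'   sensors) become `PropertyChangingEvent`s;
#' * clock markers (`sensor_id == "clock"`) become `TimeEvent`s;
#' * everything else that resolves in the registry (e.g. medical readings)
#'   becomes a plain `Event`.
#'
#' Records whose sensor does not resolve are rejected with a reason, never
#' aborting the stream; accepted plus rejected always equals the input
#' length (the rejected rows are in `attr(, "rejected")`, see
#' [rejected_records()]).
#'
#' @param records A chronological record tibble (`time`, `sensor_id`,
#'   `value`).
#' @param registry An `adl_registry`.
#' @param persons Person IDs; movement is attributed to the first (the
#'   single-resident assumption of the monitoring model).
#' @return A typed-event tibble with columns `category`, `time`,
#'   `sensor_id`, `subject`, `zone`, `value`, `origin`, `destination`,
#'   `variable`, `old`, `new`.
#' @export
filter_records <- function(records, registry, persons = "resident") {
  records <- tibble::as_tibble(records)
  if (!inherits(registry, "adl_registry")) registry <- validate_registry(registry)
  n <- nrow(records)
  ri <- match(records$sensor_id, registry$sensor_id)
  kind <- registry$kind[ri]
  zone <- registry$zone[ri]
  zones <- unique(stats::na.omit(registry$zone))
  is_zonevar <- is.na(ri) & grepl("#", records$sensor_id, fixed = TRUE) &
    sub("#.*$", "", records$sensor_id) %in% zones
  is_clock <- is.na(ri) & records$sensor_id == "clock"
  category <- rep(NA_character_, n)
  category[!is.na(ri) & kind == "presence"] <- "MoveEvent"
  category[!is.na(ri) & kind == "medical"] <- "Event"
  category[!is.na(ri) & is.na(category)] <- "PropertyChangingEvent"
  category[is_zonevar] <- "VarChangingEvent"
  category[is_clock] <- "TimeEvent"
  bad <- which(is.na(category))
  rejected <- tibble::new_tibble(list(
    time = records$time[bad],
    sensor_id = records$sensor_id[bad],
    value = records$value[bad],
    reason = rep.int("unknown sensor", length(bad))
  ), nrow = length(bad))
  keep <- !is.na(category)
  k <- sum(keep)
  cat_k <- category[keep]
  sid_k <- records$sensor_id[keep]
  subject <- sid_k
  subject[cat_k == "MoveEvent"] <- persons[1]
  na_chr <- rep(NA_character_, k)
  ev <- tibble::new_tibble(list(
    category = cat_k,
    time = records$time[keep],
    sensor_id = sid_k,
    subject = subject,
    zone = zone[keep],
    value = records$value[keep],
    origin = na_chr, destination = na_chr,
    variable = na_chr, old = na_chr, new = na_chr
  ), nrow = k)
  mv <- ev$category == "MoveEvent"
  on <- truthy(ev$value)
  ev$destination[mv & on] <- ev$zone[mv & on]
  ev$origin[mv & !on] <- ev$zone[mv & !on]
  zv <- ev$category == "VarChangingEvent"
  if (any(zv)) {
    ev$zone[zv] <- sub("#.*$", "", ev$sensor_id[zv])
    ev$variable[zv] <- sub("^[^#]*#", "", ev$sensor_id[zv])
    ev$new[zv] <- ev$value[zv]
    # previous value of the same zone variable, in stream order
    ev$old[zv] <- stats::ave(ev$value[zv], ev$sensor_id[zv],
                             FUN = function(v) dplyr::lag(v))
  }
  attr(ev, "rejected") <- rejected
  ev
}

#' @rdname filter_records
#' @param events The result of `filter_records()`.
#' @export
rejected_records <- function(events) {
  attr(events, "rejected") %||%
    tibble::tibble(time = numeric(0), sensor_id = character(0),
                   value = character(0), reason = character(0))
}

# boolean reading of a canonical sensed value; numeric > 0 counts as "on"
# so proximity (real-valued) sensors switch like boolean ones
truthy <- function(v) {
  lv <- tolower(v)
  out <- rep(FALSE, length(v))
  out[lv %in% c("true", "on", "1")] <- TRUE
  num <- is.na(match(lv, c("true", "on", "1", "false", "off", "0")))
  if (any(num)) {
    x <- suppressWarnings(as.numeric(v[num]))
    out[num] <- !is.na(x) & x > 0
  }
  out
}

#' Activity definitions
#'
#' An atomic activity is derived from a single sensor: either the span of a
#' boolean device fluent (`trigger = "fluent"`: the "on"/"open" reading
#' initiates the activity, "off"/"close" terminates it) or a momentary
#' trigger (`trigger = "point"`: every reading yields a one-second
#' activity — used for medical measurements).
#'
#' @param name Activity name.
#' @param sensor_id Sensor the activity is read from.
#' @param variable The AGGIR variable the activity contributes to.
#' @param trigger `"fluent"` or `"point"`.
#' @param zone Zone override (default: the sensor's registry zone).
#' @return A one-row tibble (bind rows to build a definition table).
#' @export
activity_def <- function(name, sensor_id, variable,
                         trigger = c("fluent", "point"), zone = NA_character_) {
  trigger <- match.arg(trigger)
  tibble::tibble(name = name, sensor_id = sensor_id, variable = variable,
                 trigger = trigger, zone = zone)
}

#' Default activity definitions for the monitored variables
#'
#' Wires the reference home's sensors to the atomic activities composing
#' toileting (bathroom door, toilet flush, washbasin), dressing (wardrobe
#' door, wardrobe proximity), transfers (bed and chair capacitive), cooking
#' (fridge, cabinet, stove, oven), alimentation (dining chair, table,
#' dining-room presence) and glucometer use.
#'
#' @param registry Registry used to fill activity zones.
#' @return An activity-definition tibble.
#' @export
default_activity_defs <- function(registry = default_home_registry()) {
  defs <- dplyr::bind_rows(
    activity_def("open_bathroom_door", "bathroom_door", "toileting"),
    activity_def("toilet_flush", "toilet_flush", "toileting"),
    activity_def("wash_hands", "washbasin", "toileting"),
    activity_def("wardrobe_open", "wardrobe_door", "dressing"),
    activity_def("change_clothes", "wardrobe_proximity", "dressing"),
    activity_def("lying_in_bed", "bed_capacitive", "transfers"),
    activity_def("sitting_on_chair", "livingroom_chair", "transfers"),
    activity_def("fridge_use", "fridge_door", "cooking"),
    activity_def("cabinet_use", "cabinet_door", "cooking"),
    activity_def("stove_use", "stove", "cooking"),
    activity_def("oven_use", "oven", "cooking"),
    activity_def("sit_dining", "diningroom_chair", "alimentation"),
    activity_def("meal_on_table", "diningroom_table", "alimentation"),
    activity_def("eat_dwell", "diningroom_presence", "alimentation"),
    activity_def("glucose_measurement", "glucometer", "glucose",
                 trigger = "point")
  )
  ri <- match(defs$sensor_id, registry$sensor_id)
  defs$zone <- ifelse(is.na(defs$zone), registry$zone[ri], defs$zone)
  defs
}

#' Detect atomic activities from typed events
#'
#' For fluent-triggered definitions, consecutive on/off transitions of the
#' device yield half-open activity intervals (a device still on at the end
#' of the observation window is closed at `horizon`). Point-triggered
#' definitions yield a one-second activity per reading.
#'
#' @param events Typed-event tibble from [filter_records()].
#' @param defs Activity-definition tibble (see [activity_def()]).
#' @param horizon End of the observation window (seconds).
#' @param epoch Scenario epoch.
#' @return An activity tibble: `name`, `variable`, `start`, `end`,
#'   `duration`, `location`, `day`, sorted by `start`.
#' @export
detect_activities <- function(events, defs, horizon, epoch = 0) {
  ev_time <- events$time
  ev_value <- events$value
  # index events by sensor once; per definition work on plain vectors
  by_sensor <- split(seq_along(ev_time), events$sensor_id)
  nm <- list(); var <- list(); st <- list(); en <- list(); loc <- list()
  for (d in seq_len(nrow(defs))) {
    def_name <- defs$name[d]
    ix <- by_sensor[[defs$sensor_id[d]]]
    if (is.null(ix)) next
    ix <- ix[order(ev_time[ix])]
    if (defs$trigger[d] == "point") {
      starts <- ev_time[ix]
      ends <- starts + 1
    } else {
      v <- truthy(ev_value[ix])
      keep <- v != c(FALSE, v[-length(v)])
      tt <- ev_time[ix][keep]
      if (length(tt) == 0) next
      n_on <- ceiling(length(tt) / 2)
      starts <- tt[2 * seq_len(n_on) - 1]
      ends <- tt[2 * seq_len(n_on)]
      ends[is.na(ends)] <- horizon
    }
    ok <- starts < ends
    if (!any(ok)) next
    k <- sum(ok)
    nm[[d]] <- rep.int(def_name, k)
    var[[d]] <- rep.int(defs$variable[d], k)
    st[[d]] <- starts[ok]
    en[[d]] <- ends[ok]
    loc[[d]] <- rep.int(defs$zone[d], k)
  }
  start <- unlist(st) %||% numeric(0)
  end <- unlist(en) %||% numeric(0)
  acts <- tibble::new_tibble(list(
    name = unlist(nm) %||% character(0),
    variable = unlist(var) %||% character(0),
    start = start, end = end, duration = end - start,
    location = unlist(loc) %||% character(0),
    day = day_index(start, epoch)
  ), nrow = length(start))
  ord <- order(acts$start, acts$end, acts$name)
  acts[ord, , drop = FALSE]
}

#' Situation definitions
#'
#' A situation (complex event) composes member activities of one AGGIR
#' variable. Ordered definitions require precedence: each member must finish
#' before (or exactly meet) the next. Unordered definitions only require all
#' members to fall inside the span. The whole composition must complete
#' within `max_span` seconds of the first member's start.
#'
#' @param situation Situation name (distinct kinds may share a `variable`).
#' @param variable AGGIR variable scored from this situation.
#' @param members Character vector of activity names.
#' @param ordered Logical: require precedence between consecutive members?
#' @param max_span Maximum envelope span in seconds.
#' @return A one-row tibble with a list-column `members`.
#' @export
situation_def <- function(situation, variable, members, ordered = TRUE,
                          max_span = 1800) {
  stopifnot(length(members) >= 1, max_span > 0)
  tibble::tibble(situation = situation, variable = variable,
                 members = list(members), ordered = ordered,
                 max_span = max_span)
}

#' Default situation definitions
#'
#' Toileting is the ordered sequence door/flush/washbasin within 30 min;
#' dressing the ordered wardrobe-door then changing-clothes dwell within
#' 30 min; transfers are single-activity situations (a chair sitting; a
#' completed bed occupancy read as rising from bed); cooking is the
#' unordered combination fridge/cabinet/stove/oven within 90 min; and
#' alimentation the ordered sitting/meal-on-table/eating-dwell sequence
#' within 90 min.
#'
#' @return A situation-definition tibble.
#' @export
default_situation_defs <- function() {
  dplyr::bind_rows(
    situation_def("toileting", "toileting",
                  c("open_bathroom_door", "toilet_flush", "wash_hands"),
                  ordered = TRUE, max_span = 1800),
    situation_def("dressing", "dressing",
                  c("wardrobe_open", "change_clothes"),
                  ordered = TRUE, max_span = 1800),
    situation_def("transfer_sitting", "transfers", "sitting_on_chair",
                  ordered = TRUE, max_span = SECONDS_PER_DAY),
    situation_def("transfer_rising", "transfers", "lying_in_bed",
                  ordered = TRUE, max_span = SECONDS_PER_DAY),
    situation_def("cooking", "cooking",
                  c("fridge_use", "cabinet_use", "stove_use", "oven_use"),
                  ordered = FALSE, max_span = 5400),
    situation_def("alimentation", "alimentation",
                  c("sit_dining", "meal_on_table", "eat_dwell"),
                  ordered = TRUE, max_span = 5400),
    situation_def("glucose_measurement", "glucose", "glucose_measurement",
                  ordered = TRUE, max_span = 60)
  )
}

#' Assemble complex situations from atomic activities
#'
#' Greedy earliest-match assembly: repeatedly anchor on the earliest
#' unconsumed head activity and extend the chain with the earliest
#' unconsumed instance of each subsequent member that satisfies precedence
#' (`before`/`meets`, for ordered definitions) and the span bound. Members
#' that cannot be matched are skipped, and the partial chain is emitted with
#' `complete = FALSE`; no activity is consumed by two situations of the
#' same definition.
#'
#' @param acts Activity tibble from [detect_activities()], sorted by start.
#' @param defs Situation-definition tibble (see [situation_def()]).
#' @param epoch Scenario epoch.
#' @return A situation tibble: `situation`, `variable`, `start`, `end`,
#'   `day`, `complete`, `n_members`, `location`, and a list-column
#'   `activities` with the matched member rows.
#' @export
detect_situations <- function(acts, defs, epoch = 0) {
  if (!tibble::is_tibble(acts)) acts <- tibble::as_tibble(acts)
  a_name <- acts$name; a_start <- acts$start; a_end <- acts$end
  a_loc <- acts$location
  res <- list()
  for (d in seq_len(nrow(defs))) {
    def <- list(situation = defs$situation[d], variable = defs$variable[d],
                ordered = defs$ordered[d], max_span = defs$max_span[d])
    members <- defs$members[[d]]
    idx_by_member <- lapply(members, function(m) which(a_name == m))
    # ordered defs anchor on the head member; unordered defs on any member
    if (def$ordered && length(idx_by_member[[1]]) == 0) next
    if (!def$ordered && all(lengths(idx_by_member) == 0)) next
    consumed <- rep(FALSE, length(a_name))
    ptr <- rep(1L, length(members))
    repeat {
      # anchor: earliest unconsumed head (ordered) or earliest unconsumed
      # instance of any member (unordered)
      anchor <- NA_integer_; anchor_m <- NA_integer_
      if (def$ordered) {
        ix <- idx_by_member[[1]]
        while (ptr[1] <= length(ix) && consumed[ix[ptr[1]]]) ptr[1] <- ptr[1] + 1L
        if (ptr[1] <= length(ix)) { anchor <- ix[ptr[1]]; anchor_m <- 1L }
      } else {
        best <- Inf
        for (m in seq_along(members)) {
          ix <- idx_by_member[[m]]
          while (ptr[m] <= length(ix) && consumed[ix[ptr[m]]]) ptr[m] <- ptr[m] + 1L
          if (ptr[m] <= length(ix) && a_start[ix[ptr[m]]] < best) {
            best <- a_start[ix[ptr[m]]]; anchor <- ix[ptr[m]]; anchor_m <- m
          }
        }
      }
      if (is.na(anchor)) break
      anchor_start <- a_start[anchor]
      deadline <- anchor_start + def$max_span
      chain <- anchor
      consumed[anchor] <- TRUE
      prev_end <- a_end[anchor]
      for (m in seq_along(members)) {
        if (m == anchor_m) next
        if (def$ordered && m < anchor_m) next
        ix <- idx_by_member[[m]]
        lo <- if (def$ordered) prev_end else anchor_start
        found <- NA_integer_
        p <- ptr[m]
        while (p <= length(ix)) {
          i <- ix[p]
          if (!consumed[i]) {
            if (a_start[i] > deadline) break
            if (a_start[i] >= lo && a_end[i] <= deadline) { found <- i; break }
          }
          p <- p + 1L
        }
        if (!is.na(found)) {
          chain <- c(chain, found)
          consumed[found] <- TRUE
          if (def$ordered) prev_end <- a_end[found]
        }
      }
      chain <- sort(chain)
      res[[length(res) + 1]] <- list(
        situation = def$situation, variable = def$variable,
        start = a_start[chain[1]], end = max(a_end[chain]),
        complete = length(chain) == length(members),
        n_members = length(chain),
        location = a_loc[chain[1]],
        chain = chain
      )
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(situation = character(0), variable = character(0),
                          start = numeric(0), end = numeric(0), day = integer(0),
                          complete = logical(0), n_members = integer(0),
                          location = character(0), activities = list()))
  }
  start <- vapply(res, `[[`, 0, "start")
  out <- tibble::new_tibble(list(
    situation = vapply(res, `[[`, "", "situation"),
    variable = vapply(res, `[[`, "", "variable"),
    start = start,
    end = vapply(res, `[[`, 0, "end"),
    day = day_index(start, epoch),
    complete = vapply(res, `[[`, TRUE, "complete"),
    n_members = vapply(res, `[[`, 0L, "n_members"),
    location = vapply(res, `[[`, "", "location"),
    activities = lapply(res, function(r) vctrs::vec_slice(acts, r$chain))
  ), nrow = length(res))
  ord <- order(out$start, out$situation)
  out[ord, , drop = FALSE]
}
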