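#' Anomaly rule parameters
#'
#' All thresholds of the event detector's anomaly rules are explicit
#' configuration; the defaults are conservative values for an elderly
#' single-resident home. Units are seconds unless noted.
#'
#' @param max_on_seconds Named numeric: per device label (`light`,
#'   `heater`, ...), the longest acceptable continuous ON span.
#' @param allowed_hours Named list: per device label, `c(from, to)` hours of
#'   day during which the device may be switched on.
#' @param door_open_max Longest acceptable continuous door-open span.
#' @param still_timeout Longest acceptable gap without any movement event.
#' @param toileting_band `c(min, max)` expected toileting activities per day
#'   (the irregular-urination band).
#' @param night_hours `c(from, to)` hours defining night for the wandering
#'   rule.
#' @param wandering_min Minimum number of night movement events to flag.
#' @param co2_threshold Concentration (ppm) above which a CO/CO2
#'   `VarChangingEvent` fires.
#' @param kitchen_grace Grace period the resident may be away from the
#'   kitchen while the stove or oven is on.
#' @return A list of class `adl_anomaly_rules`.
#' @export
anomaly_rules <- function(max_on_seconds = c(light = 8 * 3600, heater = 8 * 3600),
                          allowed_hours = list(light = c(6, 24)),
                          door_open_max = 1800,
                          still_timeout = 6 * 3600,
                          toileting_band = c(3, 10),
                          night_hours = c(0, 5),
                          wandering_min = 3,
                          co2_threshold = 1000,
                          kitchen_grace = 600) {
  stopifnot(is.numeric(max_on_seconds), door_open_max > 0, still_timeout > 0,
            length(toileting_band) == 2, length(night_hours) == 2)
  structure(list(max_on_seconds = max_on_seconds,
                 allowed_hours = allowed_hours,
                 door_open_max = door_open_max,
                 still_timeout = still_timeout,
                 toileting_band = toileting_band,
                 night_hours = night_hours,
                 wandering_min = wandering_min,
                 co2_threshold = co2_threshold,
                 kitchen_grace = kitchen_grace),
            class = "adl_anomaly_rules")
}

anomaly_row <- function(rule, time, zone, variables, evidence) {
  tibble::tibble(rule = rule, time = time, zone = zone %||% NA_character_,
                 variables = list(variables), evidence = list(evidence))
}

# ON spans of every sensor with a given device label, via the fluent reading
device_spans <- function(events, registry, labels, horizon) {
  sensors <- registry$sensor_id[registry$device %in% labels]
  out <- list()
  for (sid in sensors) {
    evs <- events[events$sensor_id == sid, , drop = FALSE]
    if (nrow(evs) == 0) next
    evs <- evs[order(evs$time), , drop = FALSE]
    v <- truthy(evs$value)
    keep <- v != dplyr::lag(v, default = FALSE)
    tt <- evs$time[keep]
    if (length(tt) == 0) next
    odd <- seq(1, length(tt), by = 2)
    even <- seq_len(length(tt))[seq_len(length(tt)) %% 2 == 0]
    starts <- tt[odd]
    ends <- if (length(even) < length(odd)) c(tt[even], horizon) else tt[even]
    out[[sid]] <- tibble::tibble(sensor_id = sid,
                                 zone = registry$zone[registry$sensor_id == sid][1],
                                 device = registry$device[registry$sensor_id == sid][1],
                                 start = starts, end = ends)
  }
  dplyr::bind_rows(out)
}

#' Detect behavioural and device anomalies
#'
#' Applies the event detector's anomaly rules to a typed-event stream and
#' the detected activities. Implemented rules: devices (lights, heaters)
#' exceeding their maximum ON time or switched on outside allowed hours;
#' doors left open; the inhabitant staying still too long (no movement
#' events); irregular urination time (toileting recurrence outside the
#' expected band); not changing clothes (a day without any wardrobe
#' activity); wandering at unusual (night) hours; high CO/CO2
#' concentration; abandoning the kitchen while cooking; and pass-through
#' device alarms (flood sensor, siren). Every anomaly cites its evidence
#' events and the AGGIR variables it affects.
#'
#' @param events Typed events from [filter_records()].
#' @param acts Activities from [detect_activities()].
#' @param rules An [anomaly_rules()] object.
#' @param registry The sensor registry (to resolve device labels).
#' @param horizon End of the observation window; defaults to the last event
#'   time plus one.
#' @param track Optional person track (for the abandoned-kitchen rule).
#' @param epoch Scenario epoch.
#' @return An anomaly tibble: `rule`, `time`, `zone`, `variables`
#'   (list-column), `evidence` (list-column).
#' @export
detect_anomalies <- function(events, acts, rules = anomaly_rules(),
                             registry = default_home_registry(),
                             horizon = NULL, track = NULL, epoch = 0) {
  stopifnot(inherits(rules, "adl_anomaly_rules"))
  events <- tibble::as_tibble(events)
  if (is.null(horizon)) {
    horizon <- if (nrow(events) > 0) max(events$time) + 1 else 1
  }
  out <- list()
  add <- function(x) out[[length(out) + 1]] <<- x
  n_days <- max(1L, ceiling((horizon - epoch) / SECONDS_PER_DAY))
  hour_of <- function(t) ((t - epoch) %% SECONDS_PER_DAY) / 3600

  # exceeded MAX time ON / ON at a wrong time
  for (label in union(names(rules$max_on_seconds), names(rules$allowed_hours))) {
    spans <- device_spans(events, registry, label, horizon)
    if (nrow(spans) == 0) next
    limit <- rules$max_on_seconds[[label]] %||% Inf
    for (i in seq_len(nrow(spans))) {
      if (spans$end[i] - spans$start[i] > limit) {
        add(anomaly_row("exceeded_max_time_on", spans$start[i], spans$zone[i],
                        c("location", "coherence"),
                        spans[i, c("sensor_id", "start", "end")]))
      }
      hrs <- rules$allowed_hours[[label]]
      if (!is.null(hrs)) {
        h <- hour_of(spans$start[i])
        if (h < hrs[1] || h >= hrs[2]) {
          add(anomaly_row("on_at_wrong_time", spans$start[i], spans$zone[i],
                          c("coherence"),
                          spans[i, c("sensor_id", "start", "end")]))
        }
      }
    }
  }

  # door LEFT OPEN
  dspans <- device_spans(events, registry, c("door", "fridge", "cabinet", "wardrobe"),
                         horizon)
  if (nrow(dspans) > 0) {
    dspans <- dspans[dspans$device %in% c("door", "fridge", "cabinet", "wardrobe") &
                       dspans$end - dspans$start > rules$door_open_max, , drop = FALSE]
    for (i in seq_len(nrow(dspans))) {
      add(anomaly_row("door_left_open", dspans$start[i], dspans$zone[i],
                      c("location", "coherence"),
                      dspans[i, c("sensor_id", "start", "end")]))
    }
  }

  # inhabitant stays still: gaps between consecutive MoveEvents
  mv <- events[events$category == "MoveEvent", , drop = FALSE]
  if (nrow(mv) > 0) {
    tt <- sort(unique(mv$time))
    gaps <- diff(c(tt, horizon))
    long <- which(gaps > rules$still_timeout)
    for (i in long) {
      add(anomaly_row("inhabitant_stays_still", tt[i], NA_character_,
                      c("location", "coherence", "transfers"),
                      tibble::tibble(gap_start = tt[i], gap_seconds = gaps[i])))
    }
  }

  # irregular urination time: toileting recurrence outside the band
  if (nrow(acts) > 0 && any(acts$name == "toilet_flush")) {
    rec <- recurrence(acts, "toilet_flush", n_days, rules$toileting_band, epoch)
    for (d in rec$day[!rec$within]) {
      add(anomaly_row("irregular_urination_time", epoch + d * SECONDS_PER_DAY,
                      "bathroom", c("toileting", "elimination", "transfers"),
                      rec[rec$day == d, ]))
    }
  }

  # not changing clothes: a day with no wardrobe activity
  wa <- if (nrow(acts) > 0) acts[acts$name == "wardrobe_open", , drop = FALSE] else acts
  days_with <- if (nrow(acts) > 0) unique(wa$day) else integer(0)
  for (d in setdiff(seq_len(n_days) - 1L, days_with)) {
    add(anomaly_row("not_changing_clothes", epoch + d * SECONDS_PER_DAY,
                    "bedroom", c("dressing", "coherence", "toileting"),
                    tibble::tibble(day = d, wardrobe_events = 0L)))
  }

  # wandering around at unusual time
  if (nrow(mv) > 0) {
    h <- hour_of(mv$time)
    night <- mv[h >= rules$night_hours[1] & h < rules$night_hours[2], , drop = FALSE]
    if (nrow(night) > 0) {
      for (d in unique(day_index(night$time, epoch))) {
        nd <- night[day_index(night$time, epoch) == d, , drop = FALSE]
        if (nrow(nd) >= rules$wandering_min) {
          add(anomaly_row("wandering_at_unusual_time", min(nd$time), NA_character_,
                          c("location", "coherence"),
                          nd[, c("time", "sensor_id", "value")]))
        }
      }
    }
  }

  # high CO/CO2 concentration
  zv <- events[events$category == "VarChangingEvent", , drop = FALSE]
  if (nrow(zv) > 0) {
    co <- zv[grepl("^co2?$", zv$variable, ignore.case = TRUE), , drop = FALSE]
    conc <- suppressWarnings(as.numeric(co$new))
    hit <- which(!is.na(conc) & conc > rules$co2_threshold)
    for (i in hit) {
      add(anomaly_row("high_co_concentration", co$time[i], co$zone[i],
                      c("coherence"),
                      co[i, c("time", "zone", "variable", "new")]))
    }
  }

  # abandoning kitchen while cooking (needs the person track)
  if (!is.null(track) && nrow(track) > 0) {
    cook <- device_spans(events, registry, c("stove", "oven"), horizon)
    for (i in seq_len(nrow(cook))) {
      # absences from the kitchen while the burner is on
      tr <- track[track$time <= cook$end[i], , drop = FALSE]
      away_from <- NA_real_
      for (j in seq_len(nrow(tr))) {
        tm <- max(tr$time[j], cook$start[i])
        if (tm >= cook$end[i]) break
        if (tr$zone[j] != cook$zone[i]) {
          if (is.na(away_from)) away_from <- tm
          leave_end <- if (j < nrow(tr)) min(tr$time[j + 1], cook$end[i]) else cook$end[i]
          if (leave_end - away_from > rules$kitchen_grace) {
            add(anomaly_row("abandoning_kitchen_while_cooking", away_from,
                            cook$zone[i], c("location", "coherence"),
                            cook[i, c("sensor_id", "start", "end")]))
            break
          }
        } else {
          away_from <- NA_real_
        }
      }
    }
  }

  # pass-through device alarms
  alarms <- registry$sensor_id[registry$device %in% c("flood", "siren")]
  al <- events[events$sensor_id %in% alarms & truthy(events$value), , drop = FALSE]
  for (i in seq_len(nrow(al))) {
    add(anomaly_row(paste0(registry$device[match(al$sensor_id[i], registry$sensor_id)],
                           "_alarm"),
                    al$time[i], al$zone[i], c("coherence"),
                    al[i, c("time", "sensor_id", "value")]))
  }

  if (length(out) == 0) {
    return(tibble::tibble(rule = character(0), time = numeric(0),
                          zone = character(0), variables = list(),
                          evidence = list()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$time, .data$rule)
}
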