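test_that("filter_records assigns one category per record and conserves counts", {
  reg <- default_home_registry()
  recs <- tibble::tibble(
    time = c(10, 20, 30, 40, 50, 60),
    sensor_id = c("kitchen_presence", "kitchen#temperature", "stove",
                  "glucometer", "clock", "mystery"),
    value = c("true", "22.5", "true", "101", "86400", "1")
  )
  ev <- filter_records(recs, reg)
  expect_equal(ev$category,
               c("MoveEvent", "VarChangingEvent", "PropertyChangingEvent",
                 "Event", "TimeEvent"))
  expect_equal(ev$destination[1], "kitchen")
  expect_equal(ev$new[2], "22.5")
  rej <- rejected_records(ev)
  expect_equal(nrow(rej), 1)
  expect_equal(rej$sensor_id, "mystery")
  expect_equal(nrow(ev) + nrow(rej), nrow(recs))
})

test_that("VarChangingEvents carry old and new values in stream order", {
  reg <- default_home_registry()
  recs <- tibble::tibble(time = c(0, 100, 200),
                         sensor_id = "kitchen#temperature",
                         value = c("20", "22", "19"))
  ev <- filter_records(recs, reg)
  expect_equal(ev$old, c(NA, "20", "22"))
  expect_equal(ev$new, c("20", "22", "19"))
  expect_equal(ev$variable, rep("temperature", 3))
  expect_equal(ev$zone, rep("kitchen", 3))
})

test_that("count conservation holds on random record logs", {
  reg <- default_home_registry()
  set.seed(71)
  ids <- c(reg$sensor_id, "nope1", "nope2", "kitchen#co2", "clock")
  for (i in 1:15) {
    n <- sample(1:60, 1)
    recs <- tibble::tibble(time = sort(sample(0:5000, n, replace = TRUE)),
                           sensor_id = sample(ids, n, replace = TRUE),
                           value = sample(c("true", "false", "5"), n, TRUE))
    ev <- filter_records(recs, reg)
    expect_equal(nrow(ev) + nrow(rejected_records(ev)), n)
  }
})

test_that("fluent activities span on/off transitions; point activities are momentary", {
  reg <- default_home_registry()
  recs <- tibble::tibble(
    time = c(10, 70, 100, 120, 125),
    sensor_id = c("bathroom_door", "bathroom_door", "glucometer",
                  "toilet_flush", "toilet_flush"),
    value = c("true", "false", "99", "true", "false")
  )
  ev <- filter_records(recs, reg)
  acts <- detect_activities(ev, default_activity_defs(reg), horizon = 1000)
  door <- acts[acts$name == "open_bathroom_door", ]
  expect_equal(door$start, 10)
  expect_equal(door$end, 70)
  expect_equal(door$duration, 60)
  expect_equal(door$location, "bathroom")
  expect_equal(door$day, 0L)
  expect_equal(acts$duration[acts$name == "glucose_measurement"], 1)
  expect_equal(acts$start[acts$name == "toilet_flush"], 120)
})

test_that("a device left on is closed at the horizon; repeated values collapse", {
  reg <- default_home_registry()
  recs <- tibble::tibble(time = c(5, 6, 50),
                         sensor_id = "stove",
                         value = c("true", "true", "true"))
  ev <- filter_records(recs, reg)
  acts <- detect_activities(ev, default_activity_defs(reg), horizon = 200)
  st <- acts[acts$name == "stove_use", ]
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start, st$end), c(5, 200))
})

test_that("activity instance counts match a single-pass scan oracle", {
  reg <- default_home_registry()
  set.seed(73)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    recs <- tibble::tibble(
      time = sort(sample(0:2000, n, replace = TRUE)),
      sensor_id = sample(c("stove", "oven"), n, replace = TRUE),
      value = sample(c("true", "false"), n, replace = TRUE)
    )
    ev <- filter_records(recs, reg)
    acts <- detect_activities(ev, default_activity_defs(reg), horizon = 3000)
    for (sid in c("stove", "oven")) {
      sub <- recs[recs$sensor_id == sid, ]
      state <- FALSE; k <- 0L
      for (j in seq_len(nrow(sub))) {
        v <- sub$value[j] == "true"
        if (v && !state) k <- k + 1L
        state <- v
      }
      nm <- if (sid == "stove") "stove_use" else "oven_use"
      expect_equal(sum(acts$name == nm), k, info = sprintf("case %d %s", i, sid))
    }
  }
})

test_that("ordered situations assemble under precedence, with partial matches flagged", {
  defs <- situation_def("toileting", "toileting",
                        c("open_bathroom_door", "toilet_flush", "wash_hands"),
                        ordered = TRUE, max_span = 1800)
  acts <- acts_tbl(c("open_bathroom_door", "toilet_flush", "wash_hands"),
                   c(0, 12, 15), c(10, 13, 20), variable = "toileting")
  sit <- detect_situations(acts, defs)
  expect_equal(nrow(sit), 1)
  expect_true(sit$complete)
  expect_equal(sit$start, 0)
  expect_equal(sit$end, 20)

  # door then wash with no flush: one incomplete situation
  acts2 <- acts_tbl(c("open_bathroom_door", "wash_hands"),
                    c(0, 15), c(10, 20), variable = "toileting")
  sit2 <- detect_situations(acts2, defs)
  expect_equal(nrow(sit2), 1)
  expect_false(sit2$complete)
  expect_equal(sit2$n_members, 2)
})

test_that("situation envelopes contain members and assemblies are disjoint", {
  res <- run_pipeline(build_week(list(toileting = rep(4, 3),
                                      dressing = rep(2, 3)),
                                 seed = 77, n_days = 3))
  sit <- res$situations
  used <- list()
  for (i in seq_len(nrow(sit))) {
    mem <- sit$activities[[i]]
    expect_true(all(mem$start >= sit$start[i] & mem$end <= sit$end[i]))
    key <- sit$situation[i]
    ids <- paste(mem$name, mem$start)
    expect_false(any(ids %in% used[[key]]), info = "activity reused")
    used[[key]] <- c(used[[key]], ids)
  }
})

test_that("greedy assembly matches the exhaustive maximum on small inputs", {
  set.seed(79)
  members <- c("a", "b", "c")
  defs <- situation_def("s", "v", members, ordered = TRUE, max_span = 40)
  for (i in 1:120) {
    n <- sample(2:8, 1)
    st <- sample(0:50, n, replace = TRUE)
    acts <- acts_tbl(sample(members, n, replace = TRUE), st,
                     st + sample(1:10, n, replace = TRUE))
    acts <- dplyr::arrange(acts, start, end)
    got <- detect_situations(acts, defs)
    expect_equal(sum(got$complete),
                 oracle_max_complete_chains(acts, members, 40),
                 info = sprintf("case %d", i))
  }
})

test_that("unordered definitions accept members in any order within the span", {
  defs <- situation_def("cooking", "cooking",
                        c("fridge_use", "stove_use"), ordered = FALSE,
                        max_span = 100)
  acts <- acts_tbl(c("stove_use", "fridge_use"), c(0, 30), c(20, 50),
                   variable = "cooking")
  sit <- detect_situations(acts, defs)
  expect_true(sit$complete)
  # outside the span: two partial situations
  acts2 <- acts_tbl(c("stove_use", "fridge_use"), c(0, 500), c(20, 520),
                    variable = "cooking")
  sit2 <- detect_situations(acts2, defs)
  expect_equal(sum(sit2$complete), 0)
  expect_equal(nrow(sit2), 2)
})

test_that("device overstay and door-left-open anomalies fire with evidence", {
  reg <- default_home_registry()
  recs <- tibble::tibble(
    time = c(0, 9.5 * 3600, 10 * 3600, 10 * 3600 + 2000),
    sensor_id = c("livingroom_light", "livingroom_light",
                  "bathroom_door", "bathroom_door"),
    value = c("true", "false", "true", "false")
  )
  ev <- filter_records(recs, reg)
  acts <- detect_activities(ev, default_activity_defs(reg), horizon = 86400)
  rules <- anomaly_rules(max_on_seconds = c(light = 8 * 3600),
                         door_open_max = 1800)
  an <- detect_anomalies(ev, acts, rules, reg, horizon = 86400)
  expect_true("exceeded_max_time_on" %in% an$rule)
  expect_true("door_left_open" %in% an$rule)
  expect_true(all(vapply(an$evidence, function(e) nrow(e) >= 1, TRUE)))
  # all devices nominal: no device anomalies
  ok <- filter_records(
    tibble::tibble(time = c(0, 600), sensor_id = "livingroom_light",
                   value = c("true", "false")), reg)
  an0 <- detect_anomalies(ok, detect_activities(ok, default_activity_defs(reg), 86400),
                          rules, reg, horizon = 3600)
  expect_false(any(an0$rule %in% c("exceeded_max_time_on", "door_left_open")))
})

test_that("door-left-open firings equal an independent interval scan", {
  reg <- default_home_registry()
  set.seed(83)
  rules <- anomaly_rules(door_open_max = 300)
  for (i in 1:10) {
    n <- sample(2:20, 1) * 2
    tt <- sort(sample(0:5000, n))
    recs <- tibble::tibble(time = tt, sensor_id = "fridge_door",
                           value = rep(c("true", "false"), n / 2))
    ev <- filter_records(recs, reg)
    an <- detect_anomalies(ev, detect_activities(ev, default_activity_defs(reg), 6000),
                           rules, reg, horizon = 6000)
    spans <- matrix(tt, ncol = 2, byrow = TRUE)
    expected <- sum(spans[, 2] - spans[, 1] > 300)
    expect_equal(sum(an$rule == "door_left_open"), expected)
  }
})

test_that("anomaly detection is monotone in the ON-time threshold", {
  reg <- default_home_registry()
  set.seed(89)
  n <- 30
  tt <- sort(sample(0:(5 * 86400), 2 * n))
  recs <- tibble::tibble(time = tt, sensor_id = "livingroom_light",
                         value = rep(c("true", "false"), n))
  ev <- filter_records(recs, reg)
  acts <- detect_activities(ev, default_activity_defs(reg), 6 * 86400)
  fired <- function(limit) {
    an <- detect_anomalies(ev, acts,
                           anomaly_rules(max_on_seconds = c(light = limit)),
                           reg, horizon = 6 * 86400)
    sum(an$rule == "exceeded_max_time_on")
  }
  loose <- fired(8 * 3600)
  tight <- fired(3600)
  expect_gte(tight, loose)
})

test_that("behavioural anomalies: stillness, night wandering, missing dressing, CO2", {
  reg <- default_home_registry()
  recs <- tibble::tibble(
    time = c(3600, 2 * 3600, 2.2 * 3600, 2.4 * 3600, 50000, 60000),
    sensor_id = c("kitchen_presence", "kitchen_presence", "kitchen_presence",
                  "kitchen_presence", "kitchen#co2", "kitchen_presence"),
    value = c("true", "false", "true", "false", "1500", "true")
  )
  ev <- filter_records(recs, reg)
  acts <- detect_activities(ev, default_activity_defs(reg), horizon = 86400)
  rules <- anomaly_rules(still_timeout = 4 * 3600, night_hours = c(0, 5),
                         wandering_min = 3, co2_threshold = 1000)
  an <- detect_anomalies(ev, acts, rules, reg, horizon = 86400)
  expect_true("inhabitant_stays_still" %in% an$rule)
  expect_true("wandering_at_unusual_time" %in% an$rule)
  expect_true("not_changing_clothes" %in% an$rule)
  expect_true("high_co_concentration" %in% an$rule)
})

test_that("abandoning the kitchen while cooking requires the grace period to lapse", {
  reg <- default_home_registry()
  recs <- tibble::tibble(time = c(100, 4000), sensor_id = "stove",
                         value = c("true", "false"))
  ev <- filter_records(recs, reg)
  acts <- detect_activities(ev, default_activity_defs(reg), horizon = 5000)
  track_away <- tibble::tibble(time = c(0, 200), zone = c("kitchen", "bedroom"))
  rules <- anomaly_rules(kitchen_grace = 600)
  an <- detect_anomalies(ev, acts, rules, reg, horizon = 5000,
                         track = track_away)
  expect_true("abandoning_kitchen_while_cooking" %in% an$rule)
  track_stay <- tibble::tibble(time = 0, zone = "kitchen")
  an2 <- detect_anomalies(ev, acts, rules, reg, horizon = 5000,
                          track = track_stay)
  expect_false("abandoning_kitchen_while_cooking" %in% an2$rule)
})
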