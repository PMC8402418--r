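tiny_registry <- function() {
  sensor_registry(
    sensor_id = c("bathroom_door", "bathroom_presence", "glucometer"),
    kind = c("magnetic", "presence", "medical"),
    value_type = c("boolean", "boolean", "real"),
    zone = c("bathroom", "bathroom", "livingroom"),
    device = c("door", "presence", "glucometer")
  )
}

tiny_scenario <- function(script) {
  scenario(duration = 1000, registry = tiny_registry(),
           zones = c("bathroom", "livingroom"), persons = "resident",
           script = script)
}

test_that("scenario construction validates targets and sorts the script", {
  s <- tiny_scenario(tibble::tibble(at = 120, kind = "set-device",
                                    target = "bathroom_door", value = "true"))
  expect_equal(nrow(s$script), 1)
  expect_error(
    tiny_scenario(tibble::tibble(at = 1, kind = "set-device",
                                 target = "ghost", value = "1")),
    "unknown sensor"
  )
  expect_warning(
    s2 <- tiny_scenario(tibble::tibble(at = c(50, 10), kind = "set-device",
                                       target = "bathroom_door",
                                       value = c("false", "true"))),
    "not sorted"
  )
  expect_equal(s2$script$at, c(10, 50))
})

test_that("set-device commands emit one record each and moves emit presence transitions", {
  s <- tiny_scenario(tibble::tibble(
    at = c(120, 200, 300),
    kind = c("set-device", "move-person", "move-person"),
    target = c("bathroom_door", "resident", "resident"),
    value = c("true", "bathroom", "livingroom")
  ))
  rec <- run_scenario(s)
  expect_equal(rec$time, c(120, 200, 300))
  expect_equal(rec$sensor_id, c("bathroom_door", "bathroom_presence",
                                "bathroom_presence"))
  expect_equal(rec$value, c("true", "true", "false"))
})

test_that("record count equals device commands plus presence transitions (counting oracle)", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(1:25, 1)
    kinds <- sample(c("set-device", "move-person", "medical-reading"), n, TRUE)
    script <- tibble::tibble(
      at = sort(sample(0:900, n, replace = TRUE)),
      kind = kinds,
      target = ifelse(kinds == "move-person", "resident",
                      ifelse(kinds == "medical-reading", "glucometer",
                             "bathroom_door")),
      value = ifelse(kinds == "move-person",
                     sample(c("bathroom", "livingroom"), n, TRUE),
                     ifelse(kinds == "medical-reading", "99.5", "true"))
    )
    s <- tiny_scenario(script)
    rec <- run_scenario(s)
    # oracle: device commands + one presence record per enter/exit of the
    # (single) presence-equipped zone
    expected <- sum(script$kind != "move-person")
    zone <- NA_character_
    for (j in seq_len(n)) {
      if (script$kind[j] != "move-person") next
      if (!is.na(zone) && zone == "bathroom") expected <- expected + 1L
      if (script$value[j] == "bathroom") expected <- expected + 1L
      zone <- script$value[j]
    }
    expect_equal(nrow(rec), expected, info = sprintf("case %d", i))
    expect_true(all(diff(rec$time) >= 0))
  }
})

test_that("simulation is deterministic and tracks are single-placement", {
  wk <- reference_week("ideal-adl", seed = 3)
  r1 <- run_scenario(wk)
  r2 <- run_scenario(wk)
  expect_identical(r1, r2)
  tr <- person_tracks(wk)
  expect_true(all(diff(tr$time) > 0))
  for (t in sample(tr$time, 25)) expect_false(joint(tr, t))
})

test_that("scenario XML survives a save/load round trip", {
  wk <- reference_week("faulty-adl", seed = 5)
  path <- withr::local_tempfile(fileext = ".xml")
  write_scenario(wk, path)
  back <- read_scenario(path)
  expect_equal(back$duration, wk$duration)
  expect_equal(back$zones, wk$zones)
  expect_equal(back$persons, wk$persons)
  expect_equal(back$script, wk$script)
  expect_equal(tibble::as_tibble(back$registry), tibble::as_tibble(wk$registry))
  # and the rebuilt scenario simulates identically
  expect_identical(run_scenario(back), run_scenario(wk))
})

test_that("malformed scenario XML yields validation errors naming the element", {
  expect_error(load_scenario("<house duration='10'/>"), "root")
  expect_error(load_scenario("<scenario><sensors/></scenario>"), "duration")
  expect_error(
    load_scenario(paste0(
      "<scenario duration='100'><sensors>",
      "<sensor id='s' kind='magnetic' zone='z'/></sensors>",
      "<script><command at='nope' kind='set-device' target='s' value='1'/>",
      "</script></scenario>")),
    "command\\[1\\]"
  )
})

test_that("notification callbacks see every emitted record", {
  s <- tiny_scenario(tibble::tibble(at = c(1, 2), kind = "set-device",
                                    target = "bathroom_door",
                                    value = c("true", "false")))
  seen <- 0L
  run_scenario(s, notify = function(rec) seen <<- seen + 1L)
  expect_equal(seen, 2L)
})

test_that("the packaged example scenario loads and analyzes", {
  path <- system.file("extdata", "example-day.xml", package = "aggirhome")
  scn <- read_scenario(path)
  res <- run_pipeline(scn)
  got <- situation_counts(res)
  expect_equal(got$n[got$variable == "toileting"], 3)
  expect_equal(got$n[got$variable == "dressing"], 2)
  expect_equal(sum(got$n[got$variable == "transfers"]), 4)
  expect_equal(got$n[got$variable == "glucose"], 3)
})
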