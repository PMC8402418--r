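#' Scripted smart-home scenarios
#'
#' A scenario bundles the home description (zones, sensor registry,
#' inhabitants) with a chronological script of commands executed on the
#' simulator clock. Four command kinds exist:
#'
#' * `set-device` — set a device sensor's value (records one emission);
#' * `move-person` — relocate an inhabitant to a zone (presence sensors in
#'   the origin/destination zones emit transitions);
#' * `set-zone-var` — change a physical zone variable such as temperature
#'   (records an emission on the pseudo-sensor `zone#variable`);
#' * `medical-reading` — a body-network device reading (records the value).
#'
#' The simulator is event-driven and fully deterministic: the same scenario
#' always yields byte-identical record logs.
#'
#' @param duration Scenario length in seconds (must cover the script).
#' @param registry Sensor registry, see [sensor_registry()].
#' @param zones Character vector of zone names (defaults to the registry's).
#' @param persons Character vector of inhabitant IDs.
#' @param script A tibble with columns `at`, `kind`, `target`, `value`.
#' @param epoch Scenario epoch, fixed at 0.
#' @return An object of class `adl_scenario`.
#' @export
scenario <- function(duration, registry, zones = NULL, persons = "resident",
                     script = NULL, epoch = 0) {
  registry <- validate_registry(registry)
  if (is.null(zones)) zones <- unique(stats::na.omit(registry$zone))
  if (anyDuplicated(zones)) stop("zone names must be unique", call. = FALSE)
  if (is.null(script)) {
    script <- tibble::tibble(at = numeric(0), kind = character(0),
                             target = character(0), value = character(0))
  }
  script <- tibble::as_tibble(script)
  stopifnot(all(c("at", "kind", "target", "value") %in% names(script)))
  script$at <- as.numeric(script$at)
  script$value <- as.character(script$value)
  if (any(script$at < 0)) stop("script times must be >= 0", call. = FALSE)
  bad_kind <- setdiff(unique(script$kind),
                      c("set-device", "move-person", "set-zone-var", "medical-reading"))
  if (length(bad_kind) > 0) {
    stop(sprintf("unknown command kind(s): %s", paste(bad_kind, collapse = ", ")),
         call. = FALSE)
  }
  # resolve targets
  dev_cmd <- script$kind %in% c("set-device", "medical-reading")
  unknown_dev <- setdiff(unique(script$target[dev_cmd]), registry$sensor_id)
  if (length(unknown_dev) > 0) {
    stop(sprintf("script references unknown sensor(s): %s",
                 paste(unknown_dev, collapse = ", ")), call. = FALSE)
  }
  unknown_p <- setdiff(unique(script$target[script$kind == "move-person"]), persons)
  if (length(unknown_p) > 0) {
    stop(sprintf("script references unknown person(s): %s",
                 paste(unknown_p, collapse = ", ")), call. = FALSE)
  }
  zv <- script$kind == "set-zone-var"
  if (any(zv)) {
    zv_zone <- sub("#.*$", "", script$target[zv])
    unknown_z <- setdiff(unique(zv_zone), zones)
    if (length(unknown_z) > 0) {
      stop(sprintf("script references unknown zone(s): %s",
                   paste(unknown_z, collapse = ", ")), call. = FALSE)
    }
    if (any(!grepl("#", script$target[zv]))) {
      stop("set-zone-var target must be 'zone#variable'", call. = FALSE)
    }
  }
  mv <- script$kind == "move-person"
  if (any(mv)) {
    unknown_z <- setdiff(unique(script$value[mv]), zones)
    if (length(unknown_z) > 0) {
      stop(sprintf("move-person destination references unknown zone(s): %s",
                   paste(unknown_z, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.unsorted(script$at)) {
    warning("script commands were not sorted by time; sorting", call. = FALSE)
  }
  ord <- order(script$at, seq_len(nrow(script)))
  script <- script[ord, , drop = FALSE]
  if (nrow(script) > 0 && duration < max(script$at)) {
    stop("scenario duration must cover the last script command", call. = FALSE)
  }
  structure(list(epoch = 0, duration = as.numeric(duration), zones = zones,
                 registry = registry, persons = persons, script = script),
            class = "adl_scenario")
}

#' @export
print.adl_scenario <- function(x, ...) {
  cat(sprintf("<adl_scenario> %d day(s), %d zone(s), %d sensor(s), %d command(s)\n",
              ceiling(x$duration / SECONDS_PER_DAY), length(x$zones),
              nrow(x$registry), nrow(x$script)))
  invisible(x)
}

#' Execute a scenario, producing the raw record log
#'
#' Every `set-device`, `set-zone-var` and `medical-reading` command emits one
#' raw record. `move-person` commands emit derived presence records: when a
#' person enters a zone containing a presence sensor that sensor reports
#' `true`; when the person leaves, `false`. Output is chronological, sorted
#' by `(time, sensor_id)` with stable tie-breaking.
#'
#' @param scn An `adl_scenario`.
#' @param notify Optional callback `function(record_row)` invoked per emitted
#'   record (the notification facility); return value ignored.
#' @return A record tibble (`time`, `sensor_id`, `value`).
#' @export
run_scenario <- function(scn, notify = NULL) {
  stopifnot(inherits(scn, "adl_scenario"))
  sc <- scn$script
  reg <- scn$registry
  presence_by_zone <- stats::setNames(
    as.list(reg$sensor_id[reg$kind == "presence"]),
    reg$zone[reg$kind == "presence"]
  )
  # each command emits at most two records (a move: exit + entry)
  cap <- max(2L * nrow(sc), 1L)
  times <- numeric(cap); sids <- character(cap); vals <- character(cap)
  n_emitted <- 0L
  emit <- function(t, sid, v) {
    n_emitted <<- n_emitted + 1L
    times[n_emitted] <<- t
    sids[n_emitted] <<- sid
    vals[n_emitted] <<- v
  }
  where <- stats::setNames(rep(NA_character_, length(scn$persons)), scn$persons)
  for (i in seq_len(nrow(sc))) {
    t <- sc$at[i]; kind <- sc$kind[i]; target <- sc$target[i]; value <- sc$value[i]
    if (kind == "set-device") {
      vt <- reg$value_type[reg$sensor_id == target][1]
      emit(t, target, canonical_value(coerce_value(value, vt, target)))
    } else if (kind == "medical-reading") {
      emit(t, target, canonical_value(coerce_value(value, "real", target)))
    } else if (kind == "set-zone-var") {
      emit(t, target, canonical_value(coerce_value(value, "real", target)))
    } else { # move-person
      from <- where[[target]]
      if (!is.na(from) && !is.null(presence_by_zone[[from]])) {
        emit(t, presence_by_zone[[from]], "false")
      }
      if (!is.null(presence_by_zone[[value]])) {
        emit(t, presence_by_zone[[value]], "true")
      }
      where[[target]] <- value
    }
  }
  idx <- seq_len(n_emitted)
  out <- tibble::tibble(time = times[idx], sensor_id = sids[idx],
                        value = vals[idx])
  out <- sort_records(out)
  if (!is.null(notify)) {
    for (i in seq_len(nrow(out))) notify(out[i, ])
  }
  out
}

#' Person movement tracks implied by a scenario script
#'
#' @param scn An `adl_scenario`.
#' @return A tibble `person_id`, `time`, `zone`, time-ordered per person; at
#'   any instant each person occupies exactly one zone.
#' @export
person_tracks <- function(scn) {
  stopifnot(inherits(scn, "adl_scenario"))
  mv <- scn$script[scn$script$kind == "move-person", , drop = FALSE]
  tibble::tibble(person_id = mv$target, time = mv$at, zone = mv$value) |>
    dplyr::arrange(.data$person_id, .data$time)
}

#' Read and write scenario XML
#'
#' The scenario dialect is a documented reconstruction (see
#' `inst/extdata/scenario-schema.md`): root `<scenario duration=...>` with
#' `<zones>`, `<sensors>`, `<persons>` and `<script>` children; each script
#' child is `<command at=... kind=... target=... value=.../>`.
#'
#' @param path Path to an XML file (or, for `load_scenario()`, XML text).
#' @return An `adl_scenario`.
#' @export
read_scenario <- function(path) {
  load_scenario(xml2::read_xml(path))
}

#' @rdname read_scenario
#' @param doc XML text or an `xml2` document.
#' @export
load_scenario <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  root <- xml2::xml_find_first(doc, "/scenario")
  if (inherits(root, "xml_missing")) {
    stop("validation error at /: document root must be <scenario>", call. = FALSE)
  }
  duration <- suppressWarnings(as.numeric(xml2::xml_attr(root, "duration")))
  if (is.na(duration)) {
    stop("validation error at /scenario: numeric 'duration' attribute required",
         call. = FALSE)
  }
  zones <- xml2::xml_attr(xml2::xml_find_all(doc, "/scenario/zones/zone"), "name")
  snodes <- xml2::xml_find_all(doc, "/scenario/sensors/sensor")
  if (length(snodes) == 0) {
    stop("validation error at /scenario/sensors: at least one sensor required",
         call. = FALSE)
  }
  att <- function(nodes, a, default = NA_character_) {
    v <- xml2::xml_attr(nodes, a)
    ifelse(is.na(v), default, v)
  }
  registry <- sensor_registry(
    sensor_id = xml2::xml_attr(snodes, "id"),
    kind = xml2::xml_attr(snodes, "kind"),
    attribute = att(snodes, "attribute", "On/Off"),
    value_type = att(snodes, "value-type", "boolean"),
    zone = xml2::xml_attr(snodes, "zone"),
    device = att(snodes, "device"),
    range_min = suppressWarnings(as.numeric(att(snodes, "range-min"))),
    range_max = suppressWarnings(as.numeric(att(snodes, "range-max")))
  )
  persons <- xml2::xml_attr(xml2::xml_find_all(doc, "/scenario/persons/person"), "id")
  if (length(persons) == 0) persons <- "resident"
  cnodes <- xml2::xml_find_all(doc, "/scenario/script/command")
  script <- tibble::tibble(
    at = suppressWarnings(as.numeric(xml2::xml_attr(cnodes, "at"))),
    kind = xml2::xml_attr(cnodes, "kind"),
    target = xml2::xml_attr(cnodes, "target"),
    value = xml2::xml_attr(cnodes, "value")
  )
  if (nrow(script) > 0 && anyNA(script$at)) {
    bad <- which(is.na(script$at))[1]
    stop(sprintf("validation error at /scenario/script/command[%d]: bad 'at'", bad),
         call. = FALSE)
  }
  if (length(zones) == 0) zones <- unique(stats::na.omit(registry$zone))
  scenario(duration = duration, registry = registry, zones = zones,
           persons = persons, script = script)
}

#' @rdname read_scenario
#' @param scn An `adl_scenario`.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "adl_scenario"))
  doc <- xml2::xml_new_root("scenario", duration = format(scn$duration, scientific = FALSE))
  zs <- xml2::xml_add_child(doc, "zones")
  for (z in scn$zones) xml2::xml_add_child(zs, "zone", name = z)
  ss <- xml2::xml_add_child(doc, "sensors")
  for (i in seq_len(nrow(scn$registry))) {
    r <- scn$registry[i, ]
    args <- list(ss, "sensor", id = r$sensor_id, kind = r$kind,
                 attribute = r$attribute, `value-type` = r$value_type)
    if (!is.na(r$zone)) args$zone <- r$zone
    if (!is.na(r$device)) args$device <- r$device
    if (!is.na(r$range_min)) args$`range-min` <- format(r$range_min, scientific = FALSE)
    if (!is.na(r$range_max)) args$`range-max` <- format(r$range_max, scientific = FALSE)
    do.call(xml2::xml_add_child, args)
  }
  ps <- xml2::xml_add_child(doc, "persons")
  for (p in scn$persons) xml2::xml_add_child(ps, "person", id = p)
  cs <- xml2::xml_add_child(doc, "script")
  for (i in seq_len(nrow(scn$script))) {
    cm <- scn$script[i, ]
    xml2::xml_add_child(cs, "command",
                        at = format(cm$at, scientific = FALSE),
                        kind = cm$kind, target = cm$target, value = cm$value)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
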