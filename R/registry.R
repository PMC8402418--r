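#' Sensor registries
#'
#' A registry describes every sensor deployed in a scenario: its kind,
#' switching attribute, value type, zone, and the device it instruments.
#' Home sensor kinds follow the ambient catalogue (electromagnetic,
#' proximity, capacitive, magnetic, presence); `medical` covers body-network
#' devices. Value types are constrained per kind: proximity sensors report
#' doubles, the other home kinds booleans, medical devices reals (or text
#' for categorical channels such as body position).
#'
#' @param sensor_id,kind,attribute,value_type,zone,device Character vectors
#'   (recycled to a common length).
#' @param range_min,range_max Optional numeric validity range for medical
#'   channels.
#' @return A registry tibble of class `adl_registry`.
#' @export
sensor_registry <- function(sensor_id, kind, attribute = "On/Off",
                            value_type = "boolean", zone = NA_character_,
                            device = NA_character_,
                            range_min = NA_real_, range_max = NA_real_) {
  out <- tibble::tibble(
    sensor_id = as.character(sensor_id), kind = kind, attribute = attribute,
    value_type = value_type, zone = as.character(zone),
    device = as.character(device),
    range_min = as.numeric(range_min), range_max = as.numeric(range_max)
  )
  validate_registry(out)
}

HOME_KINDS <- c("electromagnetic", "proximity", "capacitive", "magnetic",
                "presence", "medical")

#' @rdname sensor_registry
#' @param registry A registry tibble.
#' @export
validate_registry <- function(registry) {
  registry <- tibble::as_tibble(registry)
  req <- c("sensor_id", "kind", "attribute", "value_type", "zone", "device")
  missing_cols <- setdiff(req, names(registry))
  if (length(missing_cols) > 0) {
    stop(sprintf("registry lacks columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (!"range_min" %in% names(registry)) registry$range_min <- NA_real_
  if (!"range_max" %in% names(registry)) registry$range_max <- NA_real_
  if (anyDuplicated(registry$sensor_id)) {
    stop("duplicate sensor_id in registry", call. = FALSE)
  }
  bad_kind <- setdiff(unique(registry$kind), HOME_KINDS)
  if (length(bad_kind) > 0) {
    stop(sprintf("unknown sensor kind(s): %s", paste(bad_kind, collapse = ", ")),
         call. = FALSE)
  }
  # kind/value-type compatibility from the sensor catalogue
  allowed <- list(
    electromagnetic = "boolean", proximity = "real", capacitive = "boolean",
    magnetic = "boolean", presence = "boolean", medical = c("real", "text")
  )
  for (i in seq_len(nrow(registry))) {
    ok <- registry$value_type[i] %in% allowed[[registry$kind[i]]]
    if (!ok) {
      stop(sprintf("sensor '%s': value_type '%s' invalid for kind '%s'",
                   registry$sensor_id[i], registry$value_type[i],
                   registry$kind[i]), call. = FALSE)
    }
  }
  class(registry) <- unique(c("adl_registry", class(registry)))
  registry
}

#' Default smart-home registry for the reference scenarios
#'
#' Zones and devices sufficient for the five monitored variables: bathroom
#' (door, flush, washbasin, presence), bedroom (wardrobe door and proximity,
#' bed capacitive), living room (chair capacitive, presence), kitchen
#' (fridge and cabinet doors, stove, oven, presence), dining room (chair and
#' table capacitive, presence), plus a glucometer.
#'
#' @return An `adl_registry` tibble.
#' @export
default_home_registry <- function() {
  sensor_registry(
    sensor_id = c(
      "bathroom_door", "toilet_flush", "washbasin", "bathroom_presence",
      "wardrobe_door", "wardrobe_proximity", "bed_capacitive",
      "livingroom_chair", "livingroom_presence", "livingroom_light",
      "fridge_door", "cabinet_door", "stove", "oven", "kitchen_presence",
      "diningroom_chair", "diningroom_table", "diningroom_presence",
      "glucometer"
    ),
    kind = c(
      "magnetic", "electromagnetic", "proximity", "presence",
      "magnetic", "proximity", "capacitive",
      "capacitive", "presence", "electromagnetic",
      "magnetic", "magnetic", "electromagnetic", "electromagnetic", "presence",
      "capacitive", "capacitive", "presence",
      "medical"
    ),
    attribute = c(
      "Open/Close", "On/Off", "On/Off", "On/Off",
      "Open/Close", "On/Off", "On/Off",
      "On/Off", "On/Off", "On/Off",
      "Open/Close", "Open/Close", "On/Off", "On/Off", "On/Off",
      "On/Off", "On/Off", "On/Off",
      "measurement"
    ),
    value_type = c(
      "boolean", "boolean", "real", "boolean",
      "boolean", "real", "boolean",
      "boolean", "boolean", "boolean",
      "boolean", "boolean", "boolean", "boolean", "boolean",
      "boolean", "boolean", "boolean",
      "real"
    ),
    zone = c(
      rep("bathroom", 4),
      rep("bedroom", 3),
      rep("livingroom", 3),
      rep("kitchen", 5),
      rep("diningroom", 3),
      "livingroom"
    ),
    device = c(
      "door", "flush", "washbasin", "presence",
      "wardrobe", "wardrobe", "bed",
      "chair", "presence", "light",
      "fridge", "cabinet", "stove", "oven", "presence",
      "chair", "table", "presence",
      "glucometer"
    ),
    range_min = c(rep(NA_real_, 18), 10),
    range_max = c(rep(NA_real_, 18), 600)
  )
}

#' Catalogue of medical (body-network) sensor channels
#'
#' Commercial physiological devices with their measured parameter, units and
#' validity range where the device defines one (the glucometer has no fixed
#' physiological range; a plausibility range is carried by the registry
#' instead).
#'
#' @return A tibble with columns `device`, `parameter`, `units`,
#'   `range_min`, `range_max`.
#' @export
medical_sensor_catalog <- function() {
  tibble::tribble(
    ~device,           ~parameter,          ~units,       ~range_min, ~range_max,
    "spo2",            "pulse",             "ppm",        25,   250,
    "spo2",            "oxygen_saturation", "percent",    35,   100,
    "ecg",             "heart_rate",        "bpm",        0,    200,
    "airflow",         "respiratory_rate",  "ppm",        0,    60,
    "blood_pressure",  "systolic",          "mmHg",       0,    300,
    "blood_pressure",  "diastolic",         "mmHg",       0,    300,
    "glucometer",      "glucose",           "mg/dL",      NA,   NA,
    "body_temperature","temperature",       "celsius",    0,    50,
    "emg",             "muscle_rate",       "cpm",        0,    60,
    "spirometer",      "volume",            "L",          0.01, 9.99,
    "gsr",             "conductance",       "siemens",    0,    20,
    "snore",           "snore_rate",        "spm",        0,    60
  )
}

#' Flag medical readings outside their validity range
#'
#' Readings outside the device's declared range are flagged, never silently
#' clamped: out-of-range values usually indicate sensor faults and must stay
#' visible downstream.
#'
#' @param readings A tibble with columns `device`, `parameter`, `value`,
#'   `time`.
#' @param catalog A range catalogue, default [medical_sensor_catalog()].
#' @return The input with a logical `in_range` column (`NA` range = `TRUE`).
#' @export
validate_medical_readings <- function(readings, catalog = medical_sensor_catalog()) {
  readings <- tibble::as_tibble(readings)
  out <- dplyr::left_join(readings, catalog,
                          by = c("device", "parameter"))
  out$in_range <- is.na(out$range_min) | is.na(out$range_max) |
    (out$value >= out$range_min & out$value <= out$range_max)
  out$range_min <- NULL; out$range_max <- NULL
  if ("units" %in% names(readings)) out$units <- readings$units
  out
}

#' Zone map of a registry
#'
#' @param registry An `adl_registry`.
#' @return A tibble `zone`, `sensors` (list-column of sensor IDs).
#' @export
registry_zones <- function(registry) {
  registry |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$zone)) |>
    dplyr::group_by(zone = .data$zone) |>
    dplyr::summarise(sensors = list(.data$sensor_id), .groups = "drop")
}

#' Read and write a registry as YAML
#'
#' @param path File path.
#' @export
read_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  validate_registry(dplyr::bind_rows(lapply(doc$sensors, function(s) {
    tibble::tibble(
      sensor_id = s$sensor_id, kind = s$kind,
      attribute = s$attribute %||% "On/Off",
      value_type = s$value_type %||% "boolean",
      zone = s$zone %||% NA_character_, device = s$device %||% NA_character_,
      range_min = s$range_min %||% NA_real_,
      range_max = s$range_max %||% NA_real_
    )
  })))
}

#' @rdname read_registry
#' @param registry An `adl_registry`.
#' @export
write_registry <- function(registry, path) {
  sensors <- lapply(seq_len(nrow(registry)), function(i) {
    s <- as.list(registry[i, ])
    s[!vapply(s, function(v) is.na(v) || is.null(v), TRUE)]
  })
  yaml::write_yaml(list(sensors = sensors), path)
  invisible(path)
}
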