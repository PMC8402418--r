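#' Run the full monitoring pipeline on a scenario
#'
#' Convenience driver chaining the stages: simulate the scenario, filter
#' the raw records into typed events, detect atomic activities, assemble
#' complex situations, detect anomalies, and score the AGGIR variables.
#'
#' @param scn An `adl_scenario` (e.g. from [build_week()] or
#'   [read_scenario()]).
#' @param activity_defs Activity definitions, default
#'   [default_activity_defs()] for the scenario's registry.
#' @param situation_defs Situation definitions, default
#'   [default_situation_defs()].
#' @param criteria AGGIR criteria, default [aggir_criteria()].
#' @param rules Anomaly rules, or `NULL` to skip anomaly detection.
#' @return A list of class `adl_pipeline`: `records`, `events`,
#'   `activities`, `situations`, `anomalies`, `assessment`, `scenario`.
#' @examples
#' \donttest{
#' res <- run_pipeline(reference_week("ideal-glucose"))
#' glance(res$assessment)
#' }
#' @export
run_pipeline <- function(scn,
                         activity_defs = default_activity_defs(scn$registry),
                         situation_defs = default_situation_defs(),
                         criteria = aggir_criteria(),
                         rules = NULL) {
  stopifnot(inherits(scn, "adl_scenario"))
  records <- run_scenario(scn)
  events <- filter_records(records, scn$registry, scn$persons)
  n_days <- max(1L, ceiling(scn$duration / SECONDS_PER_DAY))
  activities <- detect_activities(events, activity_defs, horizon = scn$duration)
  situations <- detect_situations(activities, situation_defs)
  anomalies <- if (!is.null(rules)) {
    detect_anomalies(events, activities, rules, scn$registry,
                     horizon = scn$duration, track = person_tracks(scn))
  }
  assessment <- aggir_assess(situations, criteria, n_days = n_days)
  structure(list(records = records, events = events, activities = activities,
                 situations = situations, anomalies = anomalies,
                 assessment = assessment, scenario = scn),
            class = "adl_pipeline")
}

#' @export
print.adl_pipeline <- function(x, ...) {
  cat(sprintf("<adl_pipeline> %d records -> %d events -> %d activities -> %d situations\n",
              nrow(x$records), nrow(x$events), nrow(x$activities),
              nrow(x$situations)))
  print(x$assessment)
  invisible(x)
}

#' Weekly detected counts per (day, variable)
#'
#' @param x An `adl_pipeline` or situation tibble.
#' @param complete_only Count only complete situations?
#' @return A tibble `day`, `variable`, `n`.
#' @export
situation_counts <- function(x, complete_only = TRUE) {
  sit <- if (inherits(x, "adl_pipeline")) x$situations else tibble::as_tibble(x)
  if (complete_only) sit <- sit[sit$complete, , drop = FALSE]
  dplyr::count(sit, .data$day, .data$variable, name = "n")
}
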