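#' Narratives of actions and fluents
#'
#' A *fluent* is a time-varying boolean property of the home ("bathroom door
#' is open", "stove is on"). A *narrative* records which actions happened
#' when, and which fluents each action initiates or terminates. The
#' reasoning primitives (`clipped()`, `holds_at()`, `fluent_intervals()`)
#' follow the classical event-calculus reading: a fluent holds from an
#' initiating action until the next terminating action, and `InitiallyP`
#' fluents hold from time 0.
#'
#' Boundary convention: initiation is inclusive and termination exclusive,
#' so a fluent initiated at `t0` and terminated at `t1` holds exactly on the
#' half-open span `[t0, t1)` — the same convention as [interval()]. With
#' integer time this makes `fluent_intervals()` agree with per-second
#' sampling of `holds_at()`.
#'
#' @param happenings A data frame with columns `time` (numeric) and `action`
#'   (character): action `action` occurs at `time`.
#' @param effects A data frame with columns `action`, `fluent` and `effect`
#'   (`"initiate"` or `"terminate"`) mapping actions to their consequences.
#' @param fluents A data frame with columns `fluent` and `initially`
#'   (logical); fluents absent from `effects` and `fluents` are unknown.
#' @return An object of class `adl_narrative`.
#' @examples
#' n <- narrative(
#'   happenings = data.frame(time = c(2, 6), action = c("open", "close")),
#'   effects = data.frame(action = c("open", "close"), fluent = "door_open",
#'                        effect = c("initiate", "terminate")),
#'   fluents = data.frame(fluent = "door_open", initially = FALSE)
#' )
#' holds_at("door_open", 4, n)      # TRUE
#' fluent_intervals("door_open", n, horizon = 10)
#' @export
narrative <- function(happenings, effects, fluents = NULL) {
  happenings <- tibble::as_tibble(happenings)
  effects <- tibble::as_tibble(effects)
  stopifnot(all(c("time", "action") %in% names(happenings)),
            all(c("action", "fluent", "effect") %in% names(effects)))
  if (!all(effects$effect %in% c("initiate", "terminate"))) {
    stop("effect must be 'initiate' or 'terminate'", call. = FALSE)
  }
  # one action must never both initiate and terminate the same fluent
  dup <- effects |>
    dplyr::distinct(.data$action, .data$fluent, .data$effect) |>
    dplyr::count(.data$action, .data$fluent) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("an action cannot both initiate and terminate the same fluent",
         call. = FALSE)
  }
  if (is.null(fluents)) {
    fluents <- tibble::tibble(fluent = unique(effects$fluent), initially = FALSE)
  }
  fluents <- tibble::as_tibble(fluents)
  stopifnot(all(c("fluent", "initially") %in% names(fluents)))
  if (anyDuplicated(fluents$fluent)) {
    stop("fluent names must be unique within a narrative", call. = FALSE)
  }
  happenings <- dplyr::arrange(happenings, .data$time, .data$action)
  structure(list(happenings = happenings, effects = effects, fluents = fluents),
            class = "adl_narrative")
}

known_fluent <- function(f, n) {
  if (!f %in% c(n$fluents$fluent, n$effects$fluent)) {
    stop(sprintf("unknown fluent '%s'", f), call. = FALSE)
  }
}

# times at which some happening initiates/terminates fluent f
fluent_transition_times <- function(f, n, effect) {
  acts <- n$effects$action[n$effects$fluent == f & n$effects$effect == effect]
  sort(n$happenings$time[n$happenings$action %in% acts])
}

#' @rdname narrative
#' @param t1,t2 Window endpoints, `t1 <= t2`.
#' @param f A fluent name.
#' @param n An `adl_narrative`.
#' @return `clipped()` returns `TRUE` iff some happening strictly after `t1`
#'   and at or before `t2` terminates `f`.
#' @export
clipped <- function(t1, f, t2, n) {
  stopifnot(inherits(n, "adl_narrative"), t1 <= t2)
  known_fluent(f, n)
  terms <- fluent_transition_times(f, n, "terminate")
  any(terms > t1 & terms <= t2)
}

#' @rdname narrative
#' @param tau Query time (seconds, `>= 0`).
#' @return `holds_at()` returns `TRUE` iff `f` holds at `tau`: either it held
#'   initially and was not clipped on `(0, tau]`, or some action initiated it
#'   at `t0 <= tau` and it was not clipped on `(t0, tau]`.
#' @export
holds_at <- function(f, tau, n) {
  stopifnot(inherits(n, "adl_narrative"), tau >= 0)
  known_fluent(f, n)
  inits <- fluent_transition_times(f, n, "initiate")
  inits <- inits[inits <= tau]
  if (length(inits) > 0 && !clipped(max(inits), f, tau, n)) return(TRUE)
  init0 <- n$fluents$initially[n$fluents$fluent == f]
  init0 <- length(init0) == 1 && isTRUE(init0)
  init0 && !clipped(0, f, tau, n) && length(inits) == 0
}

#' @rdname narrative
#' @param horizon End of the observation window (seconds, `> 0`).
#' @return `fluent_intervals()` returns a tibble of maximal disjoint spans
#'   (`start`, `end`) within `[0, horizon)` on which the fluent holds,
#'   sorted and non-overlapping.
#' @export
fluent_intervals <- function(f, n, horizon) {
  stopifnot(inherits(n, "adl_narrative"), horizon > 0)
  known_fluent(f, n)
  inits <- fluent_transition_times(f, n, "initiate")
  terms <- fluent_transition_times(f, n, "terminate")
  init0 <- n$fluents$initially[n$fluents$fluent == f]
  init0 <- length(init0) == 1 && isTRUE(init0)
  # replay the transition sequence; terminations apply before initiations
  # at a shared timestamp so a terminate+initiate pair re-opens the fluent
  ev <- data.frame(time = c(terms, inits),
                   delta = c(rep(0L, length(terms)), rep(1L, length(inits))))
  ev <- ev[order(ev$time, ev$delta), , drop = FALSE]
  state <- init0
  opened_at <- if (init0) 0 else NA_real_
  out_start <- numeric(0); out_end <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    tm <- ev$time[i]
    if (ev$delta[i] == 1L) {         # initiate
      if (!state) { state <- TRUE; opened_at <- tm }
    } else {                          # terminate
      if (state) {
        if (tm > opened_at) { out_start <- c(out_start, opened_at); out_end <- c(out_end, tm) }
        state <- FALSE; opened_at <- NA_real_
      }
    }
  }
  if (state && horizon > opened_at) {
    out_start <- c(out_start, opened_at); out_end <- c(out_end, horizon)
  }
  keep <- out_start < horizon
  out_start <- out_start[keep]
  out_end <- pmin(out_end[keep], horizon)
  keep <- pmax(out_start, 0) < out_end
  out_start <- pmax(out_start[keep], 0); out_end <- out_end[keep]
  # merge abutting spans (terminate+initiate at one timestamp) so the
  # result is maximal
  if (length(out_start) > 1) {
    merged_s <- out_start[1]; merged_e <- out_end[1]
    for (i in 2:length(out_start)) {
      if (out_start[i] <= merged_e[length(merged_e)]) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], out_end[i])
      } else {
        merged_s <- c(merged_s, out_start[i]); merged_e <- c(merged_e, out_end[i])
      }
    }
    out_start <- merged_s; out_end <- merged_e
  }
  tibble::tibble(start = out_start, end = out_end)
}
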