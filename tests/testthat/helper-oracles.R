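# Independent oracles used across the suite. These deliberately re-derive
# the semantics from first principles (truth tables, forward replay,
# exhaustive search) rather than calling the implementation under test.

# truth table of the 13 Allen relations between [x1,x2) and [y1,y2):
# returns every relation whose defining predicate holds
oracle_allen_all <- function(x1, x2, y1, y2) {
  preds <- c(
    before        = x2 < y1,
    meets         = x2 == y1,
    overlaps      = x1 < y1 && y1 < x2 && x2 < y2,
    starts        = x1 == y1 && x2 < y2,
    during        = y1 < x1 && x2 < y2,
    finishes      = y1 < x1 && x2 == y2,
    equals        = x1 == y1 && x2 == y2,
    after         = y2 < x1,
    met_by        = y2 == x1,
    overlapped_by = y1 < x1 && x1 < y2 && y2 < x2,
    started_by    = x1 == y1 && y2 < x2,
    contains      = x1 < y1 && y2 < x2,
    finished_by   = x1 < y1 && x2 == y2
  )
  names(preds)[preds]
}

# forward-replay state machine for holds_at: process happenings with
# time <= tau in chronological order, terminations before initiations at a
# shared timestamp
oracle_replay_holds <- function(f, tau, n) {
  eff <- n$effects[n$effects$fluent == f, , drop = FALSE]
  init0 <- n$fluents$initially[n$fluents$fluent == f]
  state <- length(init0) == 1 && isTRUE(init0)
  hp <- n$happenings[n$happenings$time <= tau, , drop = FALSE]
  if (nrow(hp) == 0) return(state)
  for (tm in sort(unique(hp$time))) {
    here <- hp$action[hp$time == tm]
    if (any(here %in% eff$action[eff$effect == "terminate"])) state <- FALSE
    if (any(here %in% eff$action[eff$effect == "initiate"])) state <- TRUE
  }
  state
}

# random narrative over a handful of fluents with dedicated init/term
# actions; action times start at 1 so the epoch boundary stays clean
random_narrative <- function(n_fluents = 2, n_happenings = 8, t_max = 40) {
  fl <- paste0("f", seq_len(n_fluents))
  effects <- rbind(
    data.frame(action = paste0("init_", fl), fluent = fl, effect = "initiate"),
    data.frame(action = paste0("term_", fl), fluent = fl, effect = "terminate")
  )
  happenings <- data.frame(
    time = sample(seq_len(t_max), n_happenings, replace = TRUE),
    action = sample(effects$action, n_happenings, replace = TRUE)
  )
  narrative(happenings, effects,
            data.frame(fluent = fl,
                       initially = sample(c(TRUE, FALSE), n_fluents, TRUE)))
}

# exhaustive maximum number of disjoint complete chains for an ordered
# situation definition (small inputs only)
oracle_max_complete_chains <- function(acts, members, max_span) {
  k <- length(members)
  n <- nrow(acts)
  chains_from <- function(avail) {
    # all index chains matching members in order with precedence + span
    res <- list()
    extend <- function(chain, m) {
      if (m > k) { res[[length(res) + 1]] <<- chain; return(invisible()) }
      for (i in avail) {
        if (i %in% chain) next
        if (acts$name[i] != members[m]) next
        if (m > 1) {
          prev <- chain[length(chain)]
          if (acts$start[i] < acts$end[prev]) next
          if (acts$end[i] > acts$start[chain[1]] + max_span) next
        }
        extend(c(chain, i), m + 1)
      }
    }
    extend(integer(0), 1)
    res
  }
  best <- function(avail) {
    top <- 0L
    for (ch in chains_from(avail)) {
      top <- max(top, 1L + best(setdiff(avail, ch)))
    }
    top
  }
  best(seq_len(n))
}

# simple per-day histogram oracle
oracle_day_counts <- function(times, n_days, epoch = 0) {
  counts <- integer(n_days)
  for (t in times) {
    d <- floor((t - epoch) / 86400) + 1
    if (d >= 1 && d <= n_days) counts[d] <- counts[d] + 1L
  }
  counts
}

# reference activity tibble builder
acts_tbl <- function(names, starts, ends, variable = "v", location = "zone") {
  tibble::tibble(name = names, variable = variable, start = starts,
                 end = ends, duration = ends - starts, location = location,
                 day = as.integer(floor(starts / 86400)))
}
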