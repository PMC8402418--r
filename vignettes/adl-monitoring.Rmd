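---
title: "Rule-based ADL detection and AGGIR scoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based ADL detection and AGGIR scoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggirhome)
library(dplyr)
```

## The monitoring model

`aggirhome` implements a deterministic, rule-based pipeline for assessing
the autonomy of a single resident from ambient sensor data. The AGGIR grid
(Autonomy Gerontology Iso-Resources Groups) scores autonomy per *variable* —
toileting, dressing, transfers, alimentation, and so on — and this package
grades each monitored variable with a two-state verdict: **C** (complete
independency: the resident performed the variable's activities of daily
living adequately every day of the observation window) or **A** (complete
dependency: at least one day failed). The intermediate partial-dependency
state **B** is intentionally out of scope; the recognition rules here are
binary by construction, and a graded middle state would require evidence
the binary sensor model cannot supply.

The pipeline has five stages:

1. **Simulation** (`run_scenario()`): a scripted, event-driven home
   simulator executes a scenario (zones, devices, inhabitant moves on an
   integer-second clock) and emits the raw record log — one
   `(time, sensor_id, value)` triple per device change, plus derived
   presence-sensor transitions when a person enters or leaves an equipped
   zone. Batch execution is deterministic: a scenario always replays to a
   byte-identical log.
2. **Record filtering** (`filter_records()`): raw records become typed
   events — `MoveEvent`, `VarChangingEvent`, `PropertyChangingEvent`,
   `TimeEvent`, or plain `Event` — and records whose sensor does not
   resolve in the registry are rejected with a reason. Counts conserve:
   accepted plus rejected equals input.
3. **Atomic activity detection** (`detect_activities()`): each activity is
   read from one sensor, either as the span of a boolean device *fluent*
   (door open at `t0`, closed at `t1` yields the activity `[t0, t1)`) or
   as a momentary trigger (each glucometer reading is a one-second
   activity).
4. **Situation assembly** (`detect_situations()`): complex events compose
   member activities of one variable under temporal constraints (next
   section). Partial matches are kept with `complete = FALSE`.
5. **AGGIR scoring** (`aggir_assess()`): per-day counts of complete
   situations are tested against per-variable daily criteria; a week is
   graded C only if all days pass.

## Temporal reasoning

Intervals are half-open `[start, end)` in integer seconds from the scenario
epoch. This single convention does a lot of work: the thirteen Allen
relations become mutually exclusive without epsilon tolerances (`meets`
requires exact endpoint equality, which integer time makes meaningful), and
day boundaries at `epoch + k * 86400` assign every second to exactly one
day. Zero-length intervals may be stored but are rejected by the Allen
classifier — activities in this model always have extent, and point
intervals would break the exactly-one-of-13 property. Metric bounds attach
to a relation as closed windows on the first operand's start and end times
(`temporal_constraint()`), with `Inf` as the open upper bound.

The event calculus layer (`narrative()`, `holds_at()`, `clipped()`,
`fluent_intervals()`) uses the classical Initiates/Terminates/InitiallyP
reading with negation-as-failure resolved by forward replay — sufficient
because narratives here are finite and totally ordered, so no
circumscription machinery is needed. One boundary convention is fixed
throughout: initiation is inclusive, termination exclusive, so a fluent
initiated at `t0` and terminated at `t1` holds exactly on `[t0, t1)`. With
integer time this makes `fluent_intervals()` agree with per-second sampling
of `holds_at()` and keeps fluent spans identical to the activity intervals
derived from the same on/off transitions. At a shared timestamp a
termination applies before an initiation, so a terminate-and-reinitiate
pair leaves the fluent holding.

## Situation definitions and the assembly algorithm

The default composition rules (`default_situation_defs()`):

| situation | members | ordering | span |
|---|---|---|---|
| toileting | bathroom door, toilet flush, washbasin | precedence | 30 min |
| dressing | wardrobe door, changing-clothes dwell | precedence | 30 min |
| transfer (sitting) | chair occupancy | single | day |
| transfer (rising) | completed bed occupancy | single | day |
| cooking | fridge, cabinet, stove, oven | any order | 90 min |
| alimentation | dining chair, meal on table, eating dwell | precedence | 90 min |

*Precedence* means each member must finish before the next starts — the
Allen relation `before` or `meets`; `meets` is accepted because sensor
activities may abut at a shared integer timestamp. Span bounds (30/90
minutes) are configurable defaults chosen as generous upper bounds on the
tasks' realistic durations; the recognition rules are insensitive to their
exact values as long as they exceed task length and stay below the typical
gap between repetitions.

Dressing is modelled with two members rather than the nominal three
(open wardrobe / change clothes / close wardrobe): under fluent semantics
one open-plus-close pair of the wardrobe door *is* a single door activity,
so a separate "close" member would have no instance of its own. Transfers
are two single-activity situation kinds under one variable because the
scoring rule counts sittings and risings separately (below); a completed
bed-occupancy interval is read as one rising-from-bed event at its end.

Assembly is greedy earliest-match: anchor on the earliest unconsumed head
activity, extend with the earliest unconsumed instance of each later
member that satisfies ordering and span, emit (complete or partial), and
repeat. Members that cannot be matched are skipped so that, e.g., a
door-then-washbasin sequence with no flush yields one *incomplete*
toileting situation. No activity is consumed by two situations of the same
definition. Greediness is a deliberate resolution of an under-determined
problem (overlapping candidate assemblies); its adequacy is checked in the
test suite by equivalence with an exhaustive maximum-assembly search on
small inputs, and the earliest-match rule makes the result independent of
definition-table order.

## Scoring criteria

The default daily criteria (`aggir_criteria()`), applied to *complete*
situations only:

* **toileting** — at least 3 per day;
* **dressing** — at least 2 per day (approaching the wardrobe twice);
* **transfers** — a conjunction: at least 3 sitting events *and* at least
  1 rising-from-bed event per day. The conjunction (rather than a single
  pooled count) is what makes a day of sittings with no rise fail even at
  a respectable total;
* **cooking** — at least 3 per day; cooking is not itself a discriminatory
  AGGIR variable but acts as the trigger for alimentation;
* **alimentation** — at least 3 per day, counting only situations preceded
  (`before`/`meets`) by a complete cooking situation;
* **glucose** — a planned-task coherence band of 3 to 6 measurements per
  day (a band, not just a floor: implausibly many readings are as
  incoherent as too few).

A reported day carries three counts: `n_detected` (all situations of the
variable that day, complete or not — the quantity a daily report prints),
`n_complete`, and `n_counted` (complete and precondition-satisfied, the
basis of `pass`). Keeping detected and counted quantities separate is what
lets a day *show* six toileting sequences yet *fail* because fewer than
three were carried to completion. The weekly verdict requires all days to
pass; `count_problem_days()` counts failing (day, variable) cells.

## The synthetic-data generator

`build_week()` emulates weekly study conditions at the raw-record level:
for every day and variable it embeds exactly the requested number of
situation templates — fixed command sequences with plausible dwell times
(a toileting visit spans about four minutes, cooking about twenty) —
jittered deterministically by seed within a 06:00–22:00 activity band.
Failure modes plant problems: `drop-all` (none that day), `reduce-to(k)`,
and `make-incomplete(k)` (keep `k` complete, emit the rest with one
essential member missing; for transfers, `k` is the number of rising
events, so `k = 0` gives a day of sittings with no rise). Jobs interleave
round-robin across variables through the day, with cooking drawn before
alimentation so meals have same-day triggers, and the rising-from-bed
transfer placed first as the morning rise. `reference_week_spec()` freezes
the study's six weekly scenarios (ideal and failure-injected versions of
the ADL, meal, and glucometer weeks) as per-day count specifications.

```{r}
res <- run_pipeline(reference_week("faulty-adl", seed = 1))
glance(res$assessment)
tidy(res$assessment) |> filter(!pass)
```

What the generator deliberately does *not* emulate: statistical realism of
human routines beyond count structure (no circadian distribution beyond
the waking band, no correlated habits, no sensor noise, dropout, or
multi-resident interference). Passing tests therefore demonstrate that the
*recognition and scoring machinery* is correct on data whose ground truth
is known exactly — not that the rules are robust to noisy real-world
deployments, where the anomaly layer and threshold tuning would carry the
load. `random_week()` closes the loop for testing: it draws per-day counts
within given ranges and returns them with the pass/fail labels each day
should receive, so end-to-end recovery (generator truth = analyzer
verdict) is a property checked across many seeds.

## Numerical and degenerate-input choices

* Time is integer seconds; calendar dates exist only at the query-language
  surface, mapped through a configurable epoch date.
* Records sort by `(time, sensor_id)` with stable tie-breaking, fixing the
  order of simultaneous emissions.
* A device still on at the end of the observation window closes at the
  horizon; repeated identical readings collapse to one transition.
* Degenerate intervals: storable, but rejected by `allen_relation()`.
* Out-of-range medical readings are flagged (`in_range = FALSE`), never
  clamped or dropped — they usually indicate sensor faults and must stay
  visible.
* Simultaneity ties in `dominant()` break by earliest start, then
  lexicographic name, making the result total and reproducible.
* Empty scalar query results are signalled (`empty = TRUE`, `NA` scalar),
  distinct from a legitimate zero.

## Anomaly rules

`detect_anomalies()` implements the behavioural/device rules as explicit
predicates over fluent spans and event histograms: devices exceeding a
maximum ON time or on outside allowed hours, doors left open, long gaps
with no movement, irregular urination recurrence, days without wardrobe
use, night wandering, high CO/CO2 readings, leaving the kitchen with the
stove on, and pass-through flood/siren alarms. Every threshold lives in
`anomaly_rules()` with documented defaults (e.g. 8 h maximum light-on
time, 30 min door-open limit); the rules name conditions, the
configuration owns the numbers. Tightening a threshold can only add
firings (monotonicity, covered by a test).

## Scale and problem sizes

All bundled analyses run in seconds on one CPU. The test suite exercises
weeks (about 20 situations per day, roughly 120 records per day) and a
scaling property from 1-day to 90-day scenarios of the full five-variable
routine (about 27,000 records at the top end), checking that analyzer
runtime grows close to linearly in event count — the assembly algorithm
advances consumption pointers per member list, so its work is proportional
to the number of activities except under adversarial overlap patterns the
generator never produces.

## Known limitations

* Single resident: movement is attributed to one person; multi-resident
  disambiguation is out of scope.
* Batch, not streaming: the analyzer consumes a finished log.
* Two-state grading only; no GIR group computation on top of the
  per-variable states.
* The scenario XML dialect is a documented reconstruction
  (`inst/extdata/scenario-schema.md`), not an interchange standard.
* Allen-algebra constraint *propagation* (path consistency over relation
  sets) is not implemented — only classification and constraint checking,
  which is all the recognition rules require.
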