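mk_situations <- function(variable, days, complete = TRUE,
                          situation = variable, gap = 2000) {
  # evenly spaced synthetic situations, one tibble row per instance
  n <- length(days)
  start <- days * 86400 + 30000 + seq_len(n) * gap
  tibble::tibble(situation = situation, variable = variable,
                 start = start, end = start + 600,
                 day = as.integer(days),
                 complete = rep_len(complete, n),
                 n_members = 3L, location = "zone",
                 activities = replicate(n, tibble::tibble(), simplify = FALSE))
}

test_that("evaluate_day applies minimum rules to counted situations", {
  crit <- aggir_criteria()[aggir_criteria()$variable == "toileting", ]
  ok <- mk_situations("toileting", rep(0, 8))
  d <- evaluate_day(crit, ok, 0)
  expect_true(d$pass)
  expect_equal(d$n_detected, 8)
  few <- mk_situations("toileting", rep(0, 2))
  expect_false(evaluate_day(crit, few, 0)$pass)
  none <- mk_situations("dressing", rep(0, 2))
  expect_equal(evaluate_day(crit, none, 0)$n_detected, 0)
})

test_that("incomplete situations are reported but never counted toward the rules", {
  crit <- aggir_criteria()[aggir_criteria()$variable == "toileting", ]
  mix <- dplyr::bind_rows(mk_situations("toileting", rep(0, 2)),
                          mk_situations("toileting", rep(0, 4), complete = FALSE))
  d <- evaluate_day(crit, mix, 0)
  expect_equal(d$n_detected, 6)
  expect_equal(d$n_complete, 2)
  expect_equal(d$n_counted, 2)
  expect_false(d$pass)
})

test_that("transfers require the sitting/rising conjunction", {
  crit <- aggir_criteria()[aggir_criteria()$variable == "transfers", ]
  both <- dplyr::bind_rows(
    mk_situations("transfers", rep(0, 3), situation = "transfer_sitting"),
    mk_situations("transfers", 0, situation = "transfer_rising")
  )
  expect_true(evaluate_day(crit, both, 0)$pass)
  no_rise <- mk_situations("transfers", rep(0, 5), situation = "transfer_sitting")
  expect_false(evaluate_day(crit, no_rise, 0)$pass)
  no_sit <- mk_situations("transfers", rep(0, 2), situation = "transfer_rising")
  expect_false(evaluate_day(crit, no_sit, 0)$pass)
})

test_that("alimentation only counts situations preceded by a complete cooking", {
  crit <- aggir_criteria()[aggir_criteria()$variable == "alimentation", ]
  meals <- mk_situations("alimentation", rep(0, 3), gap = 3000)
  # no cooking anywhere: nothing counts
  d0 <- evaluate_day(crit, meals, 0)
  expect_equal(d0$n_counted, 0)
  expect_false(d0$pass)
  # one cooking before every meal
  cook <- mk_situations("cooking", 0, situation = "cooking", gap = 10)
  d1 <- evaluate_day(crit, dplyr::bind_rows(cook, meals), 0)
  expect_equal(d1$n_counted, 3)
  expect_true(d1$pass)
  # an incomplete cooking does not trigger meals
  cook_bad <- mk_situations("cooking", 0, situation = "cooking", gap = 10,
                            complete = FALSE)
  d2 <- evaluate_day(crit, dplyr::bind_rows(cook_bad, meals), 0)
  expect_equal(d2$n_counted, 0)
})

test_that("pass agrees with an independent predicate on random counts", {
  crit <- aggir_criteria()[aggir_criteria()$variable == "dressing", ]
  set.seed(97)
  for (i in 1:50) {
    n <- sample(0:5, 1)
    sit <- if (n > 0) mk_situations("dressing", rep(0, n)) else
      mk_situations("dressing", integer(0))
    d <- evaluate_day(crit, sit, 0)
    expect_equal(d$pass, n >= 2)
  }
})

test_that("evaluate_week yields C only when all days pass; totals conserve", {
  crit <- aggir_criteria()[aggir_criteria()$variable == "toileting", ]
  all_pass <- dplyr::bind_rows(lapply(0:6, function(d) {
    evaluate_day(crit, mk_situations("toileting", rep(d, 4)), d)
  }))
  w <- evaluate_week(crit, all_pass)
  expect_equal(w$state, "C")
  expect_equal(w$total, 28)
  one_fail <- all_pass
  one_fail$pass[4] <- FALSE
  expect_equal(evaluate_week(crit, one_fail)$state, "A")
  expect_error(evaluate_week(crit, all_pass[1:5, ]), "expected 7")
  # totals equal independent summation on random weeks
  set.seed(101)
  for (i in 1:20) {
    counts <- sample(0:9, 7, replace = TRUE)
    days <- dplyr::bind_rows(lapply(0:6, function(d) {
      evaluate_day(crit, mk_situations("toileting", rep(d, counts[d + 1])), d)
    }))
    expect_equal(evaluate_week(crit, days)$total, sum(counts))
  }
})

test_that("adding a complete situation never flips a passing day to failing", {
  crit <- aggir_criteria()[aggir_criteria()$variable == "toileting", ]
  set.seed(103)
  for (i in 1:30) {
    n <- sample(0:6, 1)
    base <- mk_situations("toileting", rep(0, n))
    more <- dplyr::bind_rows(base, mk_situations("toileting", 0, gap = 50000))
    before <- evaluate_day(crit, base, 0)$pass
    after <- evaluate_day(crit, more, 0)$pass
    expect_true(!before || after)
  }
})

test_that("assessment output state is always two-valued", {
  set.seed(107)
  for (i in 1:10) {
    sit <- mk_situations("dressing", sample(0:6, sample(1:12, 1), replace = TRUE),
                         complete = sample(c(TRUE, FALSE), 1))
    a <- aggir_assess(sit, n_days = 7)
    expect_true(all(a$weeks$state %in% c("A", "C")))
  }
})

test_that("count_problem_days counts failing cells", {
  res <- run_pipeline(reference_week("ideal-adl", seed = 1))
  expect_equal(count_problem_days(res$assessment), 0)
  res2 <- run_pipeline(reference_week("faulty-adl", seed = 1))
  expect_equal(count_problem_days(res2$assessment), 3)
})

test_that("the history log replays to identical week results", {
  res <- run_pipeline(reference_week("faulty-adl", seed = 2))
  an <- detect_anomalies(res$events, res$activities, anomaly_rules(),
                         res$scenario$registry, horizon = res$scenario$duration)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_history_log(res$situations, an, path)
  back <- read_history_log(path)
  expect_equal(nrow(back$situations), nrow(res$situations))
  expect_equal(nrow(back$anomalies), nrow(an))
  replayed <- aggir_assess(back$situations, n_days = 7)
  expect_equal(replayed$days, res$assessment$days)
  expect_equal(replayed$weeks, res$assessment$weeks)
  # empty inputs: a header-only log
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_history_log(res$situations[0, ], NULL, p2)
  expect_equal(length(readLines(p2)), 1)
})

test_that("report totals mirror the assessment and JSON mirrors the report", {
  res <- run_pipeline(reference_week("faulty-adl", seed = 2))
  rep <- render_report(res$assessment)
  g <- glance(res$assessment)
  for (v in g$variable) {
    expect_equal(rep$data$variables[[v]]$total, g$total[g$variable == v])
    expect_equal(rep$data$variables[[v]]$state, g$state[g$variable == v])
    day_sum <- sum(vapply(rep$data$variables[[v]]$days, `[[`, 0, "count"))
    expect_equal(day_sum, g$total[g$variable == v])
  }
  expect_equal(rep$data$problem_days, 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(parsed$problem_days, 3)
  expect_output(print(rep), "Variable: toileting")
})

test_that("tidy/glance/autoplot expose the assessment tidily", {
  res <- run_pipeline(reference_week("ideal-glucose", seed = 1))
  expect_s3_class(tidy(res$assessment), "tbl_df")
  expect_equal(nrow(tidy(res$assessment)), 7)
  expect_s3_class(glance(res$assessment), "tbl_df")
  p <- ggplot2::autoplot(res$assessment)
  expect_s3_class(p, "ggplot")
  p2 <- plot_timeline(res$activities)
  expect_s3_class(p2, "ggplot")
})
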