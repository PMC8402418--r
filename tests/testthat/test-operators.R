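test_that("inside/outside locate the person from the most recent placement", {
  tr <- tibble::tibble(time = c(0, 100), zone = c("kitchen", "bathroom"))
  expect_true(inside(tr, "kitchen", 50))
  expect_false(inside(tr, "bathroom", 50))
  expect_true(inside(tr, "bathroom", 100))
  expect_true(outside(tr, "kitchen", 150))
  expect_error(inside(tr, "kitchen", -1), "precedes")
})

test_that("inside and outside are complements on consistent tracks", {
  set.seed(5)
  zones <- c("kitchen", "bathroom", "bedroom")
  for (i in 1:50) {
    tr <- tibble::tibble(time = sort(sample(0:100, 6)),
                         zone = sample(zones, 6, replace = TRUE))
    tr <- tr[!duplicated(tr$time), ]
    for (t in sample(min(tr$time):120, 10, replace = TRUE)) {
      z <- sample(zones, 1)
      expect_true(xor(inside(tr, z, t), outside(tr, z, t)))
    }
  }
})

test_that("joint only fires on contradictory simultaneous placements", {
  bad <- tibble::tibble(time = c(10, 10), zone = c("kitchen", "bathroom"))
  expect_true(joint(bad, 10))
  ok <- tibble::tibble(time = c(0, 10, 20), zone = c("a", "b", "a"))
  for (t in 0:25) expect_false(joint(ok, t))
})

test_that("planned_task applies the per-day coherence band", {
  rd <- tibble::tibble(
    time = c(3600, 7200, 50000,                      # day 0: 3 readings
             86400 + c(1000, 2000, 3000, 4000)),     # day 1: 4 readings
    device = "glucometer")
  out <- planned_task(rd, "glucometer", c(3, 6), n_days = 2)
  expect_equal(out$count, c(3, 4))
  expect_true(all(out$planned))
  expect_true(attr(out, "all_planned"))

  out2 <- planned_task(rd[1:3, ], "glucometer", c(3, 6), n_days = 2)
  expect_equal(out2$planned, c(TRUE, FALSE))
  expect_false(attr(out2, "all_planned"))
})

test_that("planned_task and recurrence counts match an independent histogram", {
  set.seed(9)
  for (i in 1:25) {
    n_days <- sample(2:7, 1)
    times <- sort(sample(0:(n_days * 86400 - 1), sample(0:20, 1)))
    rd <- tibble::tibble(time = times, device = "glucometer")
    expect_equal(planned_task(rd, "glucometer", c(3, 6), n_days)$count,
                 oracle_day_counts(times, n_days))
    acts <- acts_tbl(rep("toilet_flush", length(times)), times, times + 1)
    expect_equal(recurrence(acts, "toilet_flush", n_days, c(3, Inf))$count,
                 oracle_day_counts(times, n_days))
  }
})

test_that("precedence_ok accepts before/meets chains and rejects order violations", {
  acts <- acts_tbl(c("door", "flush", "wash"), c(0, 12, 15), c(10, 13, 20))
  expect_true(precedence_ok(c("door", "flush", "wash"), acts))
  expect_false(precedence_ok(c("door", "wash", "flush"), acts))
  # exact meeting endpoints count as precedence
  ab <- acts_tbl(c("a", "b"), c(0, 10), c(10, 20))
  expect_true(precedence_ok(c("a", "b"), ab))
})

test_that("precedence_ok agrees with exhaustive chain search on small inputs", {
  brute <- function(sequence, acts) {
    n <- nrow(acts)
    rec <- function(m, prev_end, used) {
      if (m > length(sequence)) return(TRUE)
      for (i in seq_len(n)) {
        if (used[i] || acts$name[i] != sequence[m]) next
        if (acts$start[i] < prev_end) next
        used[i] <- TRUE
        if (rec(m + 1, acts$end[i], used)) return(TRUE)
        used[i] <- FALSE
      }
      FALSE
    }
    rec(1, -Inf, rep(FALSE, n))
  }
  set.seed(13)
  for (i in 1:150) {
    n <- sample(2:6, 1)
    nm <- sample(c("a", "b", "c"), n, replace = TRUE)
    st <- sample(0:30, n, replace = TRUE)
    acts <- acts_tbl(nm, st, st + sample(1:8, n, replace = TRUE))
    seqn <- sample(c("a", "b", "c"), sample(1:3, 1), replace = TRUE)
    expect_equal(precedence_ok(seqn, acts), brute(seqn, acts),
                 info = sprintf("case %d", i))
  }
})

test_that("concurrency equals the pairwise intersection test", {
  acts <- acts_tbl(c("eat", "tv"), c(0, 5), c(10, 15))
  expect_equal(nrow(concurrency(acts)), 1)
  disjoint <- acts_tbl(c("a", "b"), c(0, 20), c(10, 30))
  expect_equal(nrow(concurrency(disjoint)), 0)
  set.seed(17)
  for (i in 1:40) {
    n <- sample(2:7, 1)
    st <- sample(0:40, n, replace = TRUE)
    acts <- acts_tbl(sample(letters[1:4], n, TRUE), st,
                     st + sample(1:10, n, TRUE))
    got <- concurrency(acts)
    expected <- 0L
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (max(acts$start[a], acts$start[b]) < min(acts$end[a], acts$end[b])) {
        expected <- expected + 1L
      }
    }
    expect_equal(nrow(got), expected)
  }
})

test_that("dominant picks the activity with maximal window overlap", {
  acts <- acts_tbl(c("eating", "tv"), c(0, 10), c(30, 20))
  expect_equal(dominant(acts, interval(0, 30))$name, "eating")
  one <- acts_tbl("nap", 5, 25)
  expect_equal(dominant(one, interval(0, 30))$name, "nap")
  expect_error(dominant(acts, interval(100, 200)), "no activity")
  set.seed(19)
  for (i in 1:60) {
    n <- sample(1:6, 1)
    st <- sample(0:30, n, replace = TRUE)
    acts <- acts_tbl(sample(letters[1:5], n, TRUE), st,
                     st + sample(1:15, n, TRUE))
    w <- sort(sample(0:45, 2)); if (w[1] == w[2]) next
    ov <- pmax(0, pmin(acts$end, w[2]) - pmax(acts$start, w[1]))
    if (all(ov <= 0)) next
    got <- dominant(acts, interval(w[1], w[2]))
    expect_equal(got$overlap, max(ov))
  }
})
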