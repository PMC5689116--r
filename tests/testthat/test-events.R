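test_that("event detection merges nearby readings and uses strict thresholds", {
  r <- mk_readings(at(1, c("10:00", "10:10")), c(69, 69))
  ev <- detect_glycemic_events(r, 70, "hypo", merge_gap = 60)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_readings, 2L)
  expect_equal(ev$extremum, 69)

  # exactly at the threshold never qualifies (strict comparisons)
  expect_equal(nrow(detect_glycemic_events(mk_readings(at(1, "10:00"), 70),
                                           70, "hypo")), 0)
  expect_equal(nrow(detect_glycemic_events(mk_readings(at(1, "10:00"), 160),
                                           160, "hyper")), 0)
  expect_equal(nrow(detect_glycemic_events(mk_readings(at(1, "10:00"), 161),
                                           160, "hyper")), 1)

  # far-apart readings stay separate events
  r2 <- mk_readings(at(1, c("08:00", "20:00")), c(69, 69))
  expect_equal(nrow(detect_glycemic_events(r2, 70, "hypo", 60)), 2)

  # merge_gap = 0 reproduces reading-level counting
  expect_equal(nrow(detect_glycemic_events(r, 70, "hypo", 0)), 2)

  expect_equal(nrow(detect_glycemic_events(mk_readings(at(1, "10:00"),
                                                       100)[0, ],
                                           70, "hypo")), 0)
})

test_that("events partition qualifying readings", {
  set.seed(11)
  for (i in 1:10) {
    n <- 40
    ts <- sort(at(1, "00:00") + cumsum(sample(5:300, n, TRUE)) * 60)
    r <- mk_readings(ts, sample(c(50:69, 100:140), n, TRUE))
    ev <- detect_glycemic_events(r, 70, "hypo", 60)
    expect_equal(sum(ev$n_readings), sum(r$value < 70))
    if (nrow(ev) > 1) expect_true(all(diff(as.numeric(ev$start)) > 0))
  }
})

test_that("daily counts assign events to their start day", {
  days <- seq(W0, W0 + 4, by = "day")
  r <- mk_readings(at(c(1, 1, 2), c("09:00", "23:50", "00:30")), c(65, 66, 67))
  ev <- detect_glycemic_events(r, 70, "hypo", 60)
  # 23:50 and 00:30 are 40 min apart -> one event starting day 1
  expect_equal(nrow(ev), 2)
  expect_equal(daily_counts(ev, days), c(2L, 0L, 0L, 0L, 0L))
  expect_equal(daily_counts(ev[0, ], days), rep(0L, 5))
})

test_that("longest qualifying run honors strictness and matches brute force", {
  expect_true(longest_qualifying_run(c(2, 2, 2), 1, 3)$satisfied)
  expect_false(longest_qualifying_run(c(1, 1, 1), 1, 3)$satisfied)
  expect_true(longest_qualifying_run(c(1, 1, 1), 1, 3,
                                     strict = FALSE)$satisfied)

  brute <- function(counts, m, d, strict) {
    if (length(counts) < d) return(FALSE)
    any(vapply(seq_len(length(counts) - d + 1), function(s) {
      w <- counts[s:(s + d - 1)]
      all(if (strict) w > m else w >= m)
    }, logical(1)))
  }
  set.seed(3)
  for (i in 1:200) {
    counts <- sample(0:4, sample(3:20, 1), TRUE)
    m <- sample(0:3, 1); d <- sample(2:5, 1); s <- sample(c(TRUE, FALSE), 1)
    expect_equal(longest_qualifying_run(counts, m, d, s)$satisfied,
                 brute(counts, m, d, s),
                 info = paste(paste(counts, collapse = ","), m, d, s))
  }
})

test_that("preceded_fraction counts opposite events ending within lookback", {
  hypo <- detect_glycemic_events(
    mk_event_readings(1:4, "12:00", 60), 70, "hypo")
  hyper2 <- detect_glycemic_events(
    mk_event_readings(1:2, "10:30", 220), 160, "hyper")
  pf <- preceded_fraction(hypo, hyper2, lookback = 180)
  expect_equal(pf$fraction, 0.5)
  expect_equal(pf$numerator, 2L)

  # only 1 of 4 preceded -> 0.25, which fails a strict >25% test
  hyper1 <- detect_glycemic_events(
    mk_event_readings(1, "10:30", 220), 160, "hyper")
  pf1 <- preceded_fraction(hypo, hyper1, lookback = 180)
  expect_equal(pf1$fraction, 0.25)
  expect_false(pf1$fraction > 0.25)

  # opposite event outside lookback does not count
  pf_far <- preceded_fraction(hypo, detect_glycemic_events(
    mk_event_readings(1, "07:00", 220), 160, "hyper"), lookback = 180)
  expect_equal(pf_far$numerator, 0L)

  # empty denominator flagged
  pf0 <- preceded_fraction(hypo[0, ], hyper1, lookback = 180)
  expect_true(pf0$empty)
  expect_equal(pf0$fraction, 0)

  # monotone non-decreasing in lookback
  set.seed(5)
  for (i in 1:20) {
    p <- detect_glycemic_events(
      mk_event_readings(sample(1:10, 5), "14:00", 60), 70, "hypo")
    o <- detect_glycemic_events(
      mk_event_readings(sample(1:10, 5), sprintf("%02d:00", sample(8:13, 1)),
                        220), 160, "hyper")
    f <- vapply(c(30, 120, 360, 1440), function(lb)
      preceded_fraction(p, o, lb)$fraction, numeric(1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("cartridge cycles compute intervals and delays", {
  pe <- mk_pump(at(c(1, 10), "10:00"), "cartridge_change")
  cyc <- cartridge_cycles(pe, expected_interval = 7)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$interval_days, 9)
  expect_equal(cyc$delay_days, 2)

  pe2 <- mk_pump(at(c(1, 8, 15), "10:00"), "cartridge_change")
  expect_equal(cartridge_cycles(pe2, 7)$delay_days, c(0, 0))

  expect_equal(nrow(cartridge_cycles(mk_pump(at(1, "10:00"),
                                             "cartridge_change"), 7)), 0)
})

test_that("pump stop counts ignore resumes", {
  days <- seq(W0, W0 + 2, by = "day")
  pe <- mk_pump(at(c(1, 1, 1, 1), c("09:00", "09:30", "15:00", "15:30")),
                c("stop", "resume", "stop", "resume"))
  expect_equal(pump_stop_daily_counts(pe, days), c(2L, 0L, 0L))
  expect_equal(pump_stop_daily_counts(pe[0, ], days), rep(0L, 3))
})
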