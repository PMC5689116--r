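# Detector-level tests on hand-constructed logs, including boundary fixtures
# at the exact printed thresholds (strict comparators must not fire at the
# threshold and must fire one unit beyond it).

cfg <- default_pattern_config()

test_that("SD pattern is strict at 70 mg/dL", {
  # mean 100, deviations (+-70, +-70, 0): sample SD exactly 70
  vals70 <- c(30, 30, 170, 170, 100)
  log70 <- mk_log(readings = mk_readings(at(1:5, "08:00"), vals70))
  v <- detect_variability(log70, cfg)
  expect_equal(sd(vals70), 70)
  expect_false(v[[1]]$present)
  # one-unit excursion: deviations +-71
  vals71 <- c(29, 29, 171, 171, 100)
  v71 <- detect_variability(mk_log(readings = mk_readings(at(1:5, "08:00"),
                                                          vals71)), cfg)
  expect_true(v71[[1]]$present)
  expect_gt(sd(vals71), 70)
})

test_that("risk-index patterns flag moderate-or-high categories only", {
  # constant series at the risk-neutral point: both indices ~0, both absent
  v <- detect_variability(mk_log(readings = mk_readings(at(1:4, "08:00"),
                                                        112.5)), cfg)
  expect_false(v[[2]]$present)
  expect_false(v[[3]]$present)
  expect_lt(v[[2]]$evidence$lbgi, 1e-4)

  # deeply hypoglycemic series pushes LBGI into moderate/high
  vlow <- detect_variability(mk_log(readings = mk_readings(at(1:6, "08:00"),
                                                           45)), cfg)
  expect_true(vlow[[2]]$present)
  expect_false(vlow[[3]]$present)

  # fewer than 2 readings: absent with a reason, not an error
  v1 <- detect_variability(mk_log(), cfg)
  expect_false(any(vapply(v1, `[[`, logical(1), "present")))
  expect_match(v1[[1]]$reason, "fewer than 2")
})

test_that("optional %CV pattern appears only when enabled and is strict at 36%", {
  cfg_cv <- cfg
  cfg_cv$variability$cv_enabled <- TRUE
  # cv exactly 36%: mean 100, sd 36 -> devs (+-36, +-36, 0)
  vals <- c(64, 64, 136, 136, 100)
  expect_equal(100 * sd(vals) / mean(vals), 36)
  log <- mk_log(readings = mk_readings(at(1:5, "08:00"), vals))
  d <- run_dashboard(log, cfg_cv)
  expect_true("cv_high" %in% names(d$patterns))
  expect_false(d$patterns$cv_high$present)
  expect_false("cv_high" %in% names(run_dashboard(log, cfg)$patterns))

  vals2 <- c(63, 63, 137, 137, 100)  # one-unit excursion
  d2 <- run_dashboard(mk_log(readings = mk_readings(at(1:5, "08:00"), vals2)),
                      cfg_cv)
  expect_true(d2$patterns$cv_high$present)
})

test_that("hypoglycemic trend needs >1 event/day on 3 consecutive days", {
  two_per_day <- rbind(mk_event_readings(3:5, "02:30", 55),
                       mk_event_readings(3:5, "13:35", 55))
  d <- detect_hypo_patterns(mk_log(readings = two_per_day), cfg)
  expect_true(d[[1]]$present)

  one_per_day <- mk_event_readings(3:5, "02:30", 55)
  d1 <- detect_hypo_patterns(mk_log(readings = one_per_day), cfg)
  expect_false(d1[[1]]$present)

  # the relaxed preset flips exactly this boundary case to present
  relaxed <- preset_config("trend_relaxed")
  d1r <- detect_hypo_patterns(mk_log(readings = one_per_day), relaxed)
  expect_true(d1r[[1]]$present)

  # only 2 consecutive qualifying days: absent
  two_days <- rbind(mk_event_readings(c(3, 4), "02:30", 55),
                    mk_event_readings(c(3, 4), "13:35", 55))
  expect_false(detect_hypo_patterns(mk_log(readings = two_days),
                                    cfg)[[1]]$present)
})

test_that("hypo overcorrection fraction is strict at 25%", {
  hypos <- mk_event_readings(1:4, "12:00", 60)
  one_hyper <- mk_event_readings(1, "10:30", 220)
  d <- detect_hypo_patterns(mk_log(readings = rbind(hypos, one_hyper)), cfg)
  expect_equal(d[[2]]$evidence$fraction, 0.25)
  expect_false(d[[2]]$present)

  two_hyper <- mk_event_readings(1:2, "10:30", 220)
  d2 <- detect_hypo_patterns(mk_log(readings = rbind(hypos, two_hyper)), cfg)
  expect_equal(d2[[2]]$evidence$fraction, 0.5)
  expect_true(d2[[2]]$present)

  # no hypos: absent with explicit reason
  d0 <- detect_hypo_patterns(mk_log(), cfg)
  expect_false(d0[[2]]$present)
  expect_match(d0[[2]]$reason, "no hypoglycemic events")
})

test_that("time-block patterns need >3 in the same block within 7 days", {
  # exactly 3 nocturnal hypo events in a week: absent
  d3 <- detect_hypo_patterns(mk_log(readings = mk_event_readings(1:3, "03:00",
                                                                 60)), cfg)
  expect_false(d3[[3]]$present)
  # 4 in the same block: present
  d4 <- detect_hypo_patterns(mk_log(readings = mk_event_readings(1:4, "03:00",
                                                                 60)), cfg)
  expect_true(d4[[3]]$present)
  expect_equal(d4[[3]]$evidence$block, "nocturnal")
  # 4 spread over >7 days: absent
  dspread <- detect_hypo_patterns(
    mk_log(readings = mk_event_readings(c(1, 5, 9, 13), "03:00", 60)), cfg)
  expect_false(dspread[[3]]$present)
})

test_that("hyper time block uses phase-specific thresholds", {
  # pre-marked 155 exceeds the 150 preprandial threshold; unmarked 155 does not
  pre155 <- mk_readings(at(1:4, "07:30"), 155, mark = "pre")
  d <- detect_hyper_patterns(mk_log(readings = pre155), cfg)
  expect_true(d[[4]]$present)
  none155 <- mk_readings(at(1:4, "07:30"), 155, mark = "none")
  expect_false(detect_hyper_patterns(mk_log(readings = none155),
                                     cfg)[[4]]$present)
  # post-marked 180 exactly: absent (strict); 181 present
  post180 <- mk_readings(at(1:4, "09:30"), 180, mark = "post")
  expect_false(detect_hyper_patterns(mk_log(readings = post180),
                                     cfg)[[4]]$present)
  post181 <- mk_readings(at(1:4, "09:30"), 181, mark = "post")
  expect_true(detect_hyper_patterns(mk_log(readings = post181),
                                    cfg)[[4]]$present)
})

test_that("cartridge delay pattern needs delay >1 day and >50% hyper readings", {
  pump <- mk_pump(at(c(1, 10), "10:00"), "cartridge_change")  # 9-day cycle
  # delay period is day 8 10:00 onward; 3 of 5 readings hyper (60%)
  rd <- mk_readings(at(c(8, 8, 9, 9, 10), c("12:00", "18:00", "08:00",
                                            "15:00", "08:00")),
                    c(200, 200, 200, 120, 120))
  d <- detect_hyper_patterns(mk_log(readings = rd, pump = pump), cfg)
  expect_true(d[[2]]$present)
  # exactly 50% hyper: absent (strict)
  rd50 <- mk_readings(at(c(8, 8, 9, 9), c("12:00", "18:00", "08:00", "15:00")),
                      c(200, 200, 120, 120))
  expect_false(detect_hyper_patterns(mk_log(readings = rd50, pump = pump),
                                     cfg)[[2]]$present)
  # delay exactly 1 day (8-day cycle): absent even if all readings hyper
  pump8 <- mk_pump(at(c(1, 9), "10:00"), "cartridge_change")
  rd8 <- mk_readings(at(c(8, 8), c("12:00", "18:00")), c(200, 200))
  expect_false(detect_hyper_patterns(mk_log(readings = rd8, pump = pump8),
                                     cfg)[[2]]$present)
})

test_that("missed-bolus rule needs >3 qualifying hyperglycemias in the window", {
  mk_missed <- function(n, with_bolus = FALSE, rescue = FALSE, grams = 50) {
    days_idx <- c(1, 4, 7, 10)[seq_len(n)]
    rd <- mk_event_readings(days_idx, "16:45", 210)
    if (rescue) rd <- rbind(rd, mk_event_readings(days_idx, "15:00", 60))
    carbs <- mk_carbs(at(days_idx, "15:30"), grams)
    boluses <- if (with_bolus) mk_boluses(at(days_idx, "15:30")) else NULL
    mk_log(readings = rd, carbs = carbs, boluses = boluses)
  }
  expect_true(detect_hyper_patterns(mk_missed(4), cfg)[[5]]$present)
  expect_false(detect_hyper_patterns(mk_missed(3), cfg)[[5]]$present)
  # a bolus within 2 h of the hyperglycemia clears it
  expect_false(detect_hyper_patterns(mk_missed(4, with_bolus = TRUE),
                                     cfg)[[5]]$present)
  # rescue carbs after a hypoglycemia do not count
  expect_false(detect_hyper_patterns(mk_missed(4, rescue = TRUE),
                                     cfg)[[5]]$present)
  # intake of exactly 20 g does not qualify (strict >20)
  expect_false(detect_hyper_patterns(mk_missed(4, grams = 20),
                                     cfg)[[5]]$present)
  expect_true(detect_hyper_patterns(mk_missed(4, grams = 21),
                                    cfg)[[5]]$present)
})

test_that("usage day-share rules are strict at 50% of days", {
  # 10-day log; deficient day = <3 marked readings
  mk_marks_log <- function(n_deficient) {
    rd <- do.call(rbind, lapply(1:10, function(d) {
      n_marked <- if (d <= n_deficient) 2 else 3
      mk_readings(at(d, c("07:30", "13:00", "19:30")[1:n_marked]), 110,
                  mark = "pre")
    }))
    mk_log(readings = rd, days = 10)
  }
  u6 <- detect_usage_patterns(mk_marks_log(6), cfg)
  expect_true(u6[[1]]$present)            # 60% > 50%
  u5 <- detect_usage_patterns(mk_marks_log(5), cfg)
  expect_false(u5[[1]]$present)           # 50% is not >50%
  expect_equal(u5[[1]]$evidence$day_share, 0.5)

  # record rule mirrors it on bolus+carb counts
  mk_rec_log <- function(n_deficient) {
    bol <- do.call(rbind, lapply(1:10, function(d) {
      n <- if (d <= n_deficient) 1 else 2
      mk_boluses(at(d, c("07:30", "19:30")[1:n]))
    }))
    carbs <- mk_carbs(at(1:10, "13:00"))  # 1 carb/day
    mk_log(boluses = bol, carbs = carbs, days = 10)
  }
  expect_true(detect_usage_patterns(mk_rec_log(6), cfg)[[2]]$present)
  expect_false(detect_usage_patterns(mk_rec_log(5), cfg)[[2]]$present)

  # pump stops: >2/day on >50% of days
  mk_stop_log <- function(n_days) {
    d <- rep(seq_len(n_days), each = 3)
    mk_log(pump = mk_pump(at(d, rep(c("09:00", "12:00", "15:00"),
                                    n_days)), "stop"), days = 10)
  }
  expect_true(suppressWarnings(
    detect_usage_patterns(mk_stop_log(6), cfg))[[3]]$present)
  expect_false(suppressWarnings(
    detect_usage_patterns(mk_stop_log(5), cfg))[[3]]$present)
})

test_that("cartridge frequency share boundary at 30% of changes", {
  mk_cart_log <- function(intervals, days = 90) {
    start_days <- cumsum(c(1, intervals))
    rd <- mk_readings(at(1, "08:00"), 110)
    suppressMessages(patient_log(
      rd, pump_events = mk_pump(at(start_days, "10:00"), "cartridge_change"),
      therapy = "CSII", window = c(W0, W0 + days - 1)))
  }
  # 3 of 10 cycles delayed: 30%, not >30% -> absent
  u30 <- detect_usage_patterns(mk_cart_log(c(8, 8, 8, rep(7, 7))), cfg)
  expect_false(u30[[4]]$present)
  expect_equal(u30[[4]]$evidence$delayed_share, 0.3)
  # 4 of 10 delayed: 40% -> present
  expect_true(detect_usage_patterns(mk_cart_log(c(8, 8, 8, 8, rep(7, 6))),
                                    cfg)[[4]]$present)
})

test_that("adherence rules: BG frequency uses >=80% of days, bolus rules strict 25%", {
  # 10-day log, n days with 3 readings (deficient), rest with 4
  mk_freq_log <- function(n_def) {
    rd <- do.call(rbind, lapply(1:10, function(d) {
      n <- if (d <= n_def) 3 else 4
      mk_readings(at(d, c("07:30", "13:00", "19:30", "22:00")[1:n]), 110)
    }))
    mk_log(readings = rd, days = 10)
  }
  a8 <- detect_adherence_patterns(mk_freq_log(8), cfg)
  expect_true(a8[[1]]$present)         # 80% meets "on 80% of days"
  expect_false(detect_adherence_patterns(mk_freq_log(7), cfg)[[1]]$present)

  # 8 boluses, 2 without prior BG: exactly 25% -> absent; 3 -> present
  mk_bolus_log <- function(n_nobg) {
    rd <- mk_readings(at(1:8, "07:30"), 110)
    bt <- at(1:8, ifelse(seq_len(8) <= n_nobg, "12:00", "07:45"))
    mk_log(readings = rd, boluses = mk_boluses(bt))
  }
  a2 <- detect_adherence_patterns(mk_bolus_log(2), cfg)
  expect_equal(a2[[2]]$evidence$fraction, 0.25)
  expect_false(a2[[2]]$present)
  expect_true(detect_adherence_patterns(mk_bolus_log(3), cfg)[[2]]$present)

  # 8 boluses, 2 manual = 25% absent; 3 manual = 37.5% present
  mk_calc_log <- function(n_manual) {
    rd <- mk_readings(at(1:8, "07:30"), 110)
    calc <- c(rep(FALSE, n_manual), rep(TRUE, 8 - n_manual))
    mk_log(readings = rd, boluses = mk_boluses(at(1:8, "07:45"), 4, calc))
  }
  expect_false(detect_adherence_patterns(mk_calc_log(2), cfg)[[3]]$present)
  expect_true(detect_adherence_patterns(mk_calc_log(3), cfg)[[3]]$present)

  # zero boluses: not evaluable, absent with reason
  a0 <- detect_adherence_patterns(mk_log(), cfg)
  expect_false(a0[[2]]$present)
  expect_match(a0[[2]]$reason, "no boluses")
})

test_that("hypo-cartridge association is strict at 80% of changes", {
  mk_assoc_log <- function(n_hit, n_changes = 5) {
    pump <- mk_pump(at(seq(1, by = 6, length.out = n_changes), "10:00"),
                    "cartridge_change")
    rd <- mk_event_readings(seq(1, by = 6, length.out = n_hit), "12:00", 55)
    mk_log(readings = rd, pump = pump, days = 28)
  }
  a4 <- detect_hypo_patterns(mk_assoc_log(4), cfg)  # 80% exactly
  expect_equal(a4[[4]]$evidence$fraction, 0.8)
  expect_false(a4[[4]]$present)
  expect_true(detect_hypo_patterns(mk_assoc_log(5), cfg)[[4]]$present)
})

test_that("therapy gating: MDI dashboards have 12 applicable patterns", {
  mdi <- generate_baseline_log(generator_params(seed = 2), "MDI")
  d <- run_dashboard(mdi)
  expect_equal(n_applicable(d), 12)
  csii <- generate_baseline_log(generator_params(seed = 2), "CSII")
  expect_equal(n_applicable(run_dashboard(csii)), 19)
  # no CSII-only pattern is applicable (or present) for MDI
  for (id in c("hypo_cartridge", "hyper_cartridge_delay", "missed_bolus",
               "pump_stops", "cartridge_frequency", "bg_before_bolus",
               "calculator_use")) {
    expect_false(d$patterns[[id]]$applicable, info = id)
    expect_false(d$patterns[[id]]$present, info = id)
  }
  # config override re-enables bolus-calculator rules for MDI users
  cfg_mdi <- cfg
  cfg_mdi$mdi_bolus_patterns <- TRUE
  expect_equal(n_applicable(run_dashboard(mdi, cfg_mdi)), 14)
})

test_that("dashboard JSON is deterministic and comparison tracks flips", {
  log <- generate_baseline_log(generator_params(seed = 4), "CSII")
  d1 <- run_dashboard(log)
  d2 <- run_dashboard(log)
  expect_identical(as.character(dashboard_to_json(d1)),
                   as.character(dashboard_to_json(d2)))

  cmp_same <- compare_dashboards(d1, d2)
  expect_true(all(cmp_same$status == "unchanged"))

  d3 <- run_dashboard(inject_pattern(log, "hypo_trend", seed = 1))
  cmp <- compare_dashboards(d1, d3)
  expect_equal(cmp$status[cmp$id == "hypo_trend"], "new")
  expect_equal(sum(cmp$status == "new"), 1)
  back <- compare_dashboards(d3, d1)
  expect_equal(back$status[back$id == "hypo_trend"], "resolved")

  other_cfg <- preset_config("trend_relaxed")
  expect_error(compare_dashboards(d1, run_dashboard(log, other_cfg)),
               "different configurations")
})

test_that("every flagged decision flips at its exact threshold", {
  # evidence is sufficient to recompute the decision: move the evidence
  # value to the threshold and the flag must clear
  log <- inject_pattern(generate_baseline_log(generator_params(seed = 9)),
                        "hypo_overcorrection", seed = 9)
  d <- run_dashboard(log)
  ev <- d$patterns$hypo_overcorrection$evidence
  expect_true(d$patterns$hypo_overcorrection$present)
  expect_true(ev$fraction > 0.25)
  cfg_at <- cfg
  cfg_at$overcorrection$fraction <- ev$fraction  # strict > at own value
  expect_false(run_dashboard(log, cfg_at)$patterns$hypo_overcorrection$present)
})
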