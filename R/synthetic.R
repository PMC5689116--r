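# Seeded generator of realistic SMBG/pump logs: a conservative pattern-free
# baseline (meal-anchored readings, boluses, carbs, weekly cartridge
# changes) plus constructive injectors that modify a log so that exactly one
# target pattern's triggering condition holds by a clear margin.

#' Parameters of the synthetic log generator
#'
#' The conservative defaults describe a well-controlled patient: 28 days,
#' 6–7 readings/day anchored to three meals, glucose drawn lognormal with
#' mean 120 mg/dL and 15\% CV, support clipped to 85–160 mg/dL (pre-prandial
#' readings to 85–150 so that no time-block rule can fire), every bolus
#' calculator-assisted and preceded by a glucose check, cartridge changed
#' every 7 days. Under the default pattern configuration this baseline
#' triggers no pattern.
#'
#' @param days window length in days.
#' @param seed integer seed; each record stream draws from its own derived
#'   sub-seed, so streams are mutually independent.
#' @param start first day of the window.
#' @param mean_bg,cv_percent target lognormal mean (mg/dL) and CV (\%).
#' @param bg_range clipping range, mg/dL; `pre_bg_cap` caps pre-prandial
#'   draws.
#' @param meal_minutes named vector of meal anchor times (minutes after
#'   midnight).
#' @param meal_jitter_min,post_offset_min,post_jitter_min meal-time jitter
#'   and post-prandial reading offset, minutes.
#' @param bedtime_prob probability of an unmarked bedtime reading.
#' @param carb_range meal carbohydrate range, grams.
#' @param cartridge_interval_days cartridge replacement interval, days.
#' @param stop_day_prob probability of one pump stop/resume pair on a day.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(days = 28, seed = 1,
                             start = as.Date("2024-03-01"),
                             mean_bg = 120, cv_percent = 15,
                             bg_range = c(85, 160), pre_bg_cap = 150,
                             meal_minutes = c(breakfast = 450, lunch = 780,
                                              evening_meal = 1170),
                             meal_jitter_min = 20, post_offset_min = 90,
                             post_jitter_min = 15, bedtime_prob = 0.5,
                             carb_range = c(30, 80),
                             cartridge_interval_days = 7,
                             stop_day_prob = 0.3) {
  stopifnot(days >= 1, mean_bg > 0, cv_percent >= 0,
            bg_range[1] < bg_range[2], stop_day_prob >= 0, bedtime_prob >= 0)
  structure(as.list(environment()), class = "generator_params")
}

sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483629)
}

draw_bg <- function(n, mean_bg, cv_percent, lo, hi) {
  cv <- cv_percent / 100
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_bg) - sdlog^2 / 2
  round(pmin(hi, pmax(lo, stats::rlnorm(n, meanlog, sdlog))))
}

min_to_hhmm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

#' Generate a conservative pattern-free baseline log
#'
#' Deterministic for a fixed seed. See [generator_params()] for what the
#' defaults emulate; the returned log passes [patient_log()] validation and
#' yields an all-green dashboard under [default_pattern_config()].
#'
#' @param params a [generator_params()].
#' @param therapy `"CSII"` or `"MDI"`.
#' @return A [patient_log()].
#' @export
generate_baseline_log <- function(params = generator_params(),
                                  therapy = c("CSII", "MDI")) {
  therapy <- match.arg(therapy)
  p <- params
  days <- seq(p$start, by = "day", length.out = p$days)
  n_meals <- length(p$meal_minutes)

  sched <- withr::with_seed(sub_seed(p$seed, 2), {
    meal <- matrix(rep(p$meal_minutes, each = p$days), nrow = p$days) +
      matrix(sample(seq(-p$meal_jitter_min, p$meal_jitter_min),
                    p$days * n_meals, replace = TRUE), nrow = p$days)
    post <- meal + p$post_offset_min +
      matrix(sample(seq(-p$post_jitter_min, p$post_jitter_min),
                    p$days * n_meals, replace = TRUE), nrow = p$days)
    bed_on <- stats::runif(p$days) < p$bedtime_prob
    bed_min <- 1350 + sample(-15:15, p$days, replace = TRUE)
    list(meal = meal, post = post, bed_on = bed_on, bed_min = bed_min)
  })

  day_of <- rep(days, n_meals)
  pre_ts <- day_time(day_of, min_to_hhmm(as.vector(sched$meal) - 5))
  post_ts <- day_time(day_of, min_to_hhmm(as.vector(sched$post)))
  bed_ts <- day_time(days[sched$bed_on],
                     min_to_hhmm(sched$bed_min[sched$bed_on]))

  n_pre <- length(pre_ts); n_post <- length(post_ts); n_bed <- length(bed_ts)
  vals <- withr::with_seed(sub_seed(p$seed, 1), list(
    pre = draw_bg(n_pre, p$mean_bg, p$cv_percent, p$bg_range[1],
                  min(p$pre_bg_cap, p$bg_range[2])),
    post = draw_bg(n_post, p$mean_bg, p$cv_percent, p$bg_range[1],
                   p$bg_range[2]),
    bed = draw_bg(n_bed, p$mean_bg, p$cv_percent, p$bg_range[1],
                  p$bg_range[2])))

  readings <- data.frame(
    timestamp = c(pre_ts, post_ts, bed_ts),
    value = c(vals$pre, vals$post, vals$bed),
    mark = c(rep("pre", n_pre), rep("post", n_post), rep("none", n_bed)),
    source = "meter", stringsAsFactors = FALSE)

  grams <- withr::with_seed(sub_seed(p$seed, 3),
                            sample(p$carb_range[1]:p$carb_range[2],
                                   p$days * n_meals, replace = TRUE))
  meal_ts <- day_time(day_of, min_to_hhmm(as.vector(sched$meal)))
  carbs <- data.frame(timestamp = meal_ts, grams = grams,
                      stringsAsFactors = FALSE)
  boluses <- data.frame(timestamp = meal_ts, units = round(grams / 10, 1),
                        calculator_used = TRUE, stringsAsFactors = FALSE)

  pump <- empty_pump_events()
  if (therapy == "CSII") {
    change_days <- days[seq(1, p$days, by = p$cartridge_interval_days)]
    changes <- data.frame(timestamp = day_time(change_days, "10:00"),
                          kind = "cartridge_change", stringsAsFactors = FALSE)
    stop_on <- withr::with_seed(sub_seed(p$seed, 4),
                                stats::runif(p$days) < p$stop_day_prob)
    stops <- data.frame(
      timestamp = c(day_time(days[stop_on], "14:00"),
                    day_time(days[stop_on], "14:30")),
      kind = rep(c("stop", "resume"), each = sum(stop_on)),
      stringsAsFactors = FALSE)
    pump <- rbind(changes, stops)
  }

  patient_log(readings, boluses, carbs, pump, therapy = therapy,
              window = c(p$start, p$start + p$days - 1))
}

rebuild_log <- function(log, readings = log$readings, boluses = log$boluses,
                        carbs = log$carbs, pump_events = log$pump_events) {
  suppressMessages(patient_log(readings, boluses, carbs, pump_events,
                               therapy = log$therapy, window = log$window))
}

add_readings <- function(log, day_idx, hhmm, values, mark = "none") {
  ts <- day_time(log$window[1] + day_idx - 1, hhmm)
  extra <- data.frame(timestamp = ts, value = values, mark = mark,
                      source = "meter", stringsAsFactors = FALSE)
  rebuild_log(log, readings = rbind(log$readings, extra))
}

set_cartridge_changes <- function(log, ts) {
  keep <- log$pump_events[log$pump_events$kind != "cartridge_change", ,
                          drop = FALSE]
  rebuild_log(log, pump_events = rbind(
    keep, data.frame(timestamp = ts, kind = "cartridge_change",
                     stringsAsFactors = FALSE)))
}

log_days <- function(log) as.integer(log$window[2] - log$window[1]) + 1L

# clock times that never collide with the baseline reading schedule
BLOCK_SAFE_TIMES <- c(nocturnal = "03:30", breakfast = "10:00",
                      lunch = "12:00", evening_meal = "17:45",
                      bedtime = "21:50")

#' Inject a target pattern into a log
#'
#' Constructively modifies a log so that the named pattern's triggering
#' condition holds by a clear margin under [default_pattern_config()],
#' leaving the rest of the log minimally perturbed. Deterministic for a
#' fixed seed. `strength = 0` returns the log unchanged. Pump-only patterns
#' raise an error for MDI logs.
#'
#' @param log a [patient_log()] (typically [generate_baseline_log()]).
#' @param pattern_id one of [pattern_ids()] (or `"cv_high"`).
#' @param strength non-negative; 0 means no injection.
#' @param seed integer seed for placement choices.
#' @return The modified [patient_log()].
#' @export
inject_pattern <- function(log, pattern_id, strength = 1, seed = 0) {
  stopifnot(inherits(log, "patient_log"))
  if (!pattern_id %in% names(PATTERN_BLOCKS))
    stop_smbg("unknown pattern id: ", pattern_id)
  if (strength == 0) return(log)
  if (pattern_id %in% CSII_ONLY_PATTERNS && log$therapy != "CSII")
    stop_smbg("pattern ", pattern_id, " applies to CSII therapy only")
  D <- log_days(log)
  withr::with_seed(sub_seed(seed, 11), switch(
    pattern_id,
    sd_high = {  # 2 high readings/day on 24 days pushes whole-window SD >70
      dsel <- sort(sample(seq_len(D), min(24, D), replace = D < 24))
      add_readings(log, rep(dsel, 2), rep(c("02:10", "04:40"), each = length(dsel)),
                   300)
    },
    cv_high = ,  # same mechanism: large dispersion lifts SD and %CV
    lbgi_risk = {
      if (pattern_id == "lbgi_risk") {
        dsel <- sample(seq_len(D), min(16, D), replace = D < 16)
        tms <- BLOCK_SAFE_TIMES[(seq_along(dsel) - 1) %% 5 + 1]
        add_readings(log, dsel, tms, 40)
      } else {
        dsel <- sort(sample(seq_len(D), min(24, D), replace = D < 24))
        add_readings(log, rep(dsel, 2),
                     rep(c("02:10", "04:40"), each = length(dsel)), 300)
      }
    },
    hbgi_risk = {  # 2 x 250 mg/dL on 24 days: HBGI ~5 while SD stays <70
      dsel <- sort(sample(seq_len(D), min(24, D), replace = D < 24))
      add_readings(log, rep(dsel, 2), rep(c("02:10", "04:40"), each = length(dsel)),
                   250)
    },
    hypo_trend = {  # 2 hypo events/day (different blocks) on 3 consecutive days
      s <- sample(seq_len(max(1, D - 2)), 1)
      dsel <- s:(s + 2)
      add_readings(log, rep(dsel, 2),
                   rep(c("02:30", "13:35"), each = length(dsel)), 55)
    },
    hypo_overcorrection = {  # 4 hypo events, 2 preceded by a hyperglycemia
      dsel <- sample(seq_len(D), 4)
      tms <- c("03:30", "10:00", "17:45", "21:50")
      pre <- c("01:50", "08:20", "16:05", "20:10")
      out <- add_readings(log, dsel, tms, 55)
      add_readings(out, dsel[1:2], pre[1:2], 250)
    },
    hypo_time_block = {  # 5 nocturnal hypo events within one 7-day window
      s <- sample(seq_len(max(1, D - 4)), 1)
      add_readings(log, s:(s + 4), "03:00", 60)
    },
    hypo_cartridge = {  # a hypoglycemia 2 h after every cartridge change
      ch <- log$pump_events$timestamp[log$pump_events$kind == "cartridge_change"]
      if (!length(ch)) stop_smbg("log has no cartridge changes")
      extra <- data.frame(timestamp = ch + 2 * 3600, value = 55,
                          mark = "none", source = "meter",
                          stringsAsFactors = FALSE)
      rebuild_log(log, readings = rbind(log$readings, extra))
    },
    hyper_trend = {  # 3 hyper events/day on 7 consecutive days
      s <- sample(seq_len(max(1, D - 6)), 1)
      dsel <- s:(s + 6)
      add_readings(log, rep(dsel, 3),
                   rep(c("02:15", "05:15", "10:20"), each = length(dsel)), 220)
    },
    hyper_cartridge_delay = {  # one 2.5-day late change, all-hyper delay period
      if (D < 28) stop_smbg("cartridge delay injection needs a 28-day log")
      w0 <- log$window[1]
      out <- set_cartridge_changes(log, c(
        day_time(w0, "10:00"), day_time(w0 + 9, "22:00"),
        day_time(w0 + 16, "22:00"), day_time(w0 + 23, "22:00"),
        day_time(w0 + 26, "10:00")))
      t <- out$readings$timestamp
      in_delay <- t >= day_time(w0 + 7, "10:00") & t <= day_time(w0 + 9, "22:00")
      r <- out$readings
      r$value[in_delay] <- 220
      rebuild_log(out, readings = r)
    },
    hyper_overcorrection = {  # 4 marked hyperglycemias >200, 2 after a hypo
      dsel <- sample(seq_len(D), 4)
      tms <- c("03:30", "10:00", "17:45", "21:50")
      pre <- c("01:50", "08:20", "16:05", "20:10")
      out <- add_readings(log, dsel, tms, 230)
      add_readings(out, dsel[1:2], pre[1:2], 55)
    },
    hyper_time_block = {  # 5 nocturnal hyperglycemias within one 7-day window
      s <- sample(seq_len(max(1, D - 4)), 1)
      add_readings(log, s:(s + 4), "02:30", 190)
    },
    missed_bolus = {  # 4 large intakes with no bolus, each followed by a hyper
      base <- c(2, 9, 16, 23)
      base <- base[base <= D]
      if (length(base) < 4) stop_smbg("missed bolus injection needs >=23 days")
      dsel <- base + sample(0:4, length(base), replace = TRUE)
      dsel <- pmin(dsel, D)
      extra_carbs <- data.frame(
        timestamp = day_time(log$window[1] + dsel - 1, "15:30"), grams = 50,
        stringsAsFactors = FALSE)
      out <- rebuild_log(log, carbs = rbind(log$carbs, extra_carbs))
      add_readings(out, dsel, "16:45", 210)
    },
    marks_usage = {  # wipe pre/post marks on just over half the days
      dsel <- sample(seq_len(D), floor(D / 2) + 1)
      r <- log$readings
      r$mark[log_day_index(r$timestamp, log$window) %in% dsel] <- "none"
      rebuild_log(log, readings = r)
    },
    record_usage = {  # keep only the breakfast carb+bolus on >half the days
      dsel <- sample(seq_len(D), floor(D / 2) + 1)
      keep <- function(df) {
        drop <- log_day_index(df$timestamp, log$window) %in% dsel &
          minute_of_day(df$timestamp) >= 660
        df[!drop, , drop = FALSE]
      }
      rebuild_log(log, boluses = keep(log$boluses), carbs = keep(log$carbs))
    },
    pump_stops = {  # 3 stop/resume pairs on >half the days
      dsel <- sample(seq_len(D), floor(D / 2) + 1)
      d <- log$window[1] + rep(dsel, 3) - 1
      tms <- rep(c("11:00", "15:00", "18:00"), each = length(dsel))
      stops <- data.frame(timestamp = day_time(d, tms), kind = "stop",
                          stringsAsFactors = FALSE)
      resumes <- data.frame(timestamp = day_time(d, tms) + 1800,
                            kind = "resume", stringsAsFactors = FALSE)
      rebuild_log(log, pump_events = rbind(log$pump_events, stops, resumes))
    },
    cartridge_frequency = {  # 2 of 3 changes one day late (not >1 day)
      if (D < 24) stop_smbg("cartridge frequency injection needs >=24 days")
      w0 <- log$window[1]
      set_cartridge_changes(log, day_time(w0 + c(0, 8, 16, 23), "10:00"))
    },
    bg_frequency = {  # at most 3 readings/day on >=80% of days
      dsel <- sample(seq_len(D), ceiling(0.8 * D))
      r <- log$readings
      drop <- log_day_index(r$timestamp, log$window) %in% dsel &
        r$mark != "pre"
      rebuild_log(log, readings = r[!drop, , drop = FALSE])
    },
    bg_before_bolus = {  # extra boluses with no glucose check before them
      nb <- nrow(log$boluses)
      k <- floor(nb / 3) + 1
      dsel <- sample(seq_len(D), k, replace = k > D)
      mins <- 940 + (seq_len(k) - 1) %% 2  # 15:40 / 15:41, away from readings
      extra <- data.frame(
        timestamp = day_time(log$window[1] + dsel - 1, min_to_hhmm(mins)),
        units = 2, calculator_used = TRUE, stringsAsFactors = FALSE)
      rebuild_log(log, boluses = rbind(log$boluses, extra))
    },
    calculator_use = {  # >25% of boluses entered manually
      nb <- nrow(log$boluses)
      k <- floor(nb / 4) + 1
      b <- log$boluses
      b$calculator_used[sample(seq_len(nb), k)] <- FALSE
      rebuild_log(log, boluses = b)
    },
    stop_smbg("no injector for pattern ", pattern_id)))
}

#' Generate a synthetic panel rating table
#'
#' Each rater independently matches the reference rating with probability
#' `rater_accuracy`. Emulates a physician panel judging pattern presence
#' against an automated reference.
#'
#' @param reference logical vector of reference ratings (one per item).
#' @param rater_accuracy probability in \[0, 1\] of agreeing with the
#'   reference.
#' @param n_raters number of raters.
#' @param seed integer seed.
#' @return A [rating_table()].
#' @export
generate_rating_table <- function(reference, rater_accuracy = 0.8,
                                  n_raters = 37, seed = 1) {
  stopifnot(rater_accuracy >= 0, rater_accuracy <= 1, n_raters >= 1)
  reference <- as.logical(reference)
  m <- withr::with_seed(sub_seed(seed, 21), {
    agree <- matrix(stats::runif(n_raters * length(reference)) < rater_accuracy,
                    nrow = n_raters)
    t(apply(agree, 1, function(g) ifelse(g, reference, !reference)))
  })
  if (length(reference) == 1) m <- matrix(m, ncol = 1)
  colnames(m) <- names(reference) %||% paste0("item", seq_along(reference))
  rownames(m) <- paste0("rater", seq_len(n_raters))
  rating_table(stats::setNames(reference, colnames(m)), m)
}
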