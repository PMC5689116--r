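# Temporal primitives shared by the pattern detectors: discrete hypo-/
# hyperglycemic episodes, per-day counts, consecutive-day runs, preceded-by
# fractions and cartridge-change cycles.

#' Detect discrete hypo- or hyperglycemic events
#'
#' Qualifying readings (strictly below the threshold for `kind = "hypo"`,
#' strictly above for `"hyper"`, matching the printed rule comparators) are
#' merged into one clinical episode when consecutive qualifying readings are
#' closer than `merge_gap` minutes. `merge_gap = 0` reproduces reading-level
#' counting.
#'
#' @param readings readings data.frame of a [patient_log()] (time-sorted).
#' @param threshold glucose threshold, mg/dL.
#' @param kind `"hypo"` or `"hyper"`.
#' @param merge_gap minutes; qualifying readings closer than this are one
#'   event.
#' @return data.frame with one row per event: `start`, `end` (POSIXct),
#'   `n_readings`, `extremum` (lowest value for hypo, highest for hyper).
#' @export
detect_glycemic_events <- function(readings, threshold,
                                   kind = c("hypo", "hyper"),
                                   merge_gap = 60) {
  kind <- match.arg(kind)
  empty <- data.frame(start = as.POSIXct(character(), tz = SMBG_TZ),
                      end = as.POSIXct(character(), tz = SMBG_TZ),
                      n_readings = integer(), extremum = numeric())
  if (!nrow(readings)) return(empty)
  q <- if (kind == "hypo") readings$value < threshold else readings$value > threshold
  if (!any(q)) return(empty)
  ts <- readings$timestamp[q]
  val <- readings$value[q]
  gap_min <- c(Inf, diff(as.numeric(ts)) / 60)
  event_id <- cumsum(gap_min >= merge_gap)
  if (merge_gap == 0) event_id <- seq_along(ts)
  agg <- function(f, x) as.vector(tapply(x, event_id, f))
  data.frame(
    start = as.POSIXct(agg(min, as.numeric(ts)), origin = "1970-01-01", tz = SMBG_TZ),
    end = as.POSIXct(agg(max, as.numeric(ts)), origin = "1970-01-01", tz = SMBG_TZ),
    n_readings = as.integer(agg(length, val)),
    extremum = agg(if (kind == "hypo") min else max, val))
}

#' Per-day event counts
#'
#' Each event is assigned to the calendar day of its start (an event spanning
#' midnight counts on its start day only).
#'
#' @param events data.frame from [detect_glycemic_events()].
#' @param days Date vector of consecutive window days.
#' @return integer vector of counts, one per day.
#' @export
daily_counts <- function(events, days) {
  if (!nrow(events)) return(integer(length(days)) + 0L)
  d <- factor(as.character(ts_day(events$start)), levels = as.character(days))
  as.integer(table(d))
}

#' Longest run of days meeting a per-day criterion
#'
#' Satisfied iff some run of at least `days_required` consecutive days each
#' has a count exceeding `min_per_day` (strictly when `strict`, else at least
#' that many).
#'
#' @param counts integer vector of per-day counts on consecutive calendar
#'   days.
#' @param min_per_day per-day threshold.
#' @param days_required minimum run length in days.
#' @param strict logical; `TRUE` for ">" (the printed default), `FALSE` for
#'   ">=" (the relaxed preset).
#' @return list with `satisfied` (logical), `run_start` and `run_length` of
#'   the longest qualifying run (`NA`/0 when none qualifies).
#' @export
longest_qualifying_run <- function(counts, min_per_day, days_required,
                                   strict = TRUE) {
  ok <- cmp_exceeds(counts, min_per_day, strict)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= days_required)
  if (!length(good)) {
    best <- which(r$values)[which.max(r$lengths[r$values])]
    return(list(satisfied = FALSE,
                run_start = if (length(best)) starts[best] else NA_integer_,
                run_length = if (length(best)) r$lengths[best] else 0L))
  }
  i <- good[which.max(r$lengths[good])]
  list(satisfied = TRUE, run_start = starts[i], run_length = r$lengths[i])
}

#' Fraction of primary events preceded by an opposite-side event
#'
#' For each primary event, looks for an opposite event ending before the
#' primary start and within `lookback` minutes of it (strictly within,
#' matching "within <3 h"). A zero denominator is reported as fraction 0
#' with `empty = TRUE` (the pattern is then necessarily absent).
#'
#' @param primary events data.frame (the events being qualified).
#' @param opposite events data.frame searched in the lookback window.
#' @param lookback minutes.
#' @return list with `fraction`, `numerator`, `denominator`, `empty`.
#' @export
preceded_fraction <- function(primary, opposite, lookback) {
  n <- nrow(primary)
  if (!n) return(list(fraction = 0, numerator = 0L, denominator = 0L,
                      empty = TRUE))
  if (!nrow(opposite)) return(list(fraction = 0, numerator = 0L,
                                   denominator = n, empty = FALSE))
  ends <- sort(as.numeric(opposite$end))
  starts <- as.numeric(primary$start)
  # an opposite end in (start - lookback, start)
  hit <- findInterval(starts - 1e-6, ends) -
    findInterval(starts - lookback * 60, ends) >= 1
  list(fraction = sum(hit) / n, numerator = sum(hit), denominator = n,
       empty = FALSE)
}

#' Cartridge-change cycles and their delays
#'
#' Successive `cartridge_change` pump events define cycles; the delay of a
#' cycle is the time beyond the expected replacement interval,
#' `max(0, interval - expected_interval)` in fractional days.
#'
#' @param pump_events pump events data.frame of a [patient_log()].
#' @param expected_interval expected replacement interval in days (label
#'   default: every 7 days).
#' @return data.frame with one row per cycle: `prev_change`, `change`
#'   (POSIXct), `interval_days`, `delay_days`.
#' @export
cartridge_cycles <- function(pump_events, expected_interval = 7) {
  ch <- pump_events$timestamp[pump_events$kind == "cartridge_change"]
  ch <- sort(ch)
  if (length(ch) < 2)
    return(data.frame(prev_change = as.POSIXct(character(), tz = SMBG_TZ),
                      change = as.POSIXct(character(), tz = SMBG_TZ),
                      interval_days = numeric(), delay_days = numeric()))
  interval <- diff(as.numeric(ch)) / 86400
  data.frame(prev_change = ch[-length(ch)], change = ch[-1],
             interval_days = interval,
             delay_days = pmax(0, interval - expected_interval))
}

#' Per-day pump stop counts
#'
#' @param pump_events pump events data.frame.
#' @param days Date vector of consecutive window days.
#' @return integer vector of `stop` event counts per day.
#' @export
pump_stop_daily_counts <- function(pump_events, days) {
  st <- pump_events[pump_events$kind == "stop", , drop = FALSE]
  if (!nrow(st)) return(integer(length(days)) + 0L)
  d <- factor(as.character(ts_day(st$timestamp)), levels = as.character(days))
  as.integer(table(d))
}
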