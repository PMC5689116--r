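# Builders for small hand-constructed logs used across the unit tests.

W0 <- as.Date("2024-03-01")

# POSIXct on day `d` (1-based within the window) at clock time "HH:MM"
at <- function(d, hhmm) {
  as.POSIXct(paste0(format(W0 + d - 1, "%Y-%m-%d"), "T", hhmm),
             format = "%Y-%m-%dT%H:%M", tz = "UTC")
}

mk_readings <- function(ts, value, mark = "none") {
  data.frame(timestamp = ts, value = value, mark = mark, source = "meter",
             stringsAsFactors = FALSE)
}

mk_log <- function(readings = NULL, boluses = NULL, carbs = NULL,
                   pump = NULL, therapy = "CSII", days = 14) {
  if (is.null(readings)) readings <- mk_readings(at(1, "08:00"), 110)
  args <- list(readings = readings, therapy = therapy,
               window = c(W0, W0 + days - 1))
  if (!is.null(boluses)) args$boluses <- boluses
  if (!is.null(carbs)) args$carbs <- carbs
  if (!is.null(pump)) args$pump_events <- pump
  suppressMessages(do.call(patient_log, args))
}

mk_boluses <- function(ts, units = 4, calculator_used = TRUE) {
  data.frame(timestamp = ts, units = units,
             calculator_used = calculator_used, stringsAsFactors = FALSE)
}

mk_carbs <- function(ts, grams = 50) {
  data.frame(timestamp = ts, grams = grams, stringsAsFactors = FALSE)
}

mk_pump <- function(ts, kind) {
  data.frame(timestamp = ts, kind = kind, stringsAsFactors = FALSE)
}

# n glucose events as isolated readings, one per day at a fixed time
mk_event_readings <- function(days_idx, hhmm, value) {
  mk_readings(at(days_idx, hhmm), value)
}
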