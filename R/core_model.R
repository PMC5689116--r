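# Typed data model for device logs: glucose readings, insulin boluses,
# carbohydrate records and pump events, with CSV interchange, calendar-day
# partitioning and time-block assignment.

GLUCOSE_RANGE <- c(10, 600)  # plausible meter range, mg/dL
MARKS <- c("pre", "post", "none")
SOURCES <- c("meter", "pump", "bolus_calculator")
PUMP_KINDS <- c("stop", "resume", "cartridge_change")
THERAPIES <- c("CSII", "MDI")

empty_readings <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = SMBG_TZ),
             value = numeric(), mark = character(), source = character(),
             stringsAsFactors = FALSE)
}

empty_boluses <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = SMBG_TZ),
             units = numeric(), calculator_used = logical(),
             stringsAsFactors = FALSE)
}

empty_carbs <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = SMBG_TZ),
             grams = numeric(), stringsAsFactors = FALSE)
}

empty_pump_events <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = SMBG_TZ),
             kind = character(), stringsAsFactors = FALSE)
}

#' Construct a validated patient device log
#'
#' Bundles the four record streams of a blood-glucose device download —
#' glucose readings, insulin boluses, carbohydrate records and insulin-pump
#' events — for one patient over a closed analysis window of whole calendar
#' days. All streams are time-sorted; records outside the window are dropped
#' (with a message); duplicate reading timestamps keep the first occurrence
#' with a warning; glucose values outside the plausible meter range
#' (10–600 mg/dL) raise an error.
#'
#' @param readings data.frame with columns `timestamp` (POSIXct, minute
#'   resolution), `value` (mg/dL), `mark` (`"pre"`, `"post"` or `"none"`),
#'   `source` (`"meter"`, `"pump"` or `"bolus_calculator"`).
#' @param boluses data.frame with `timestamp`, `units` (insulin units, >= 0),
#'   `calculator_used` (logical).
#' @param carbs data.frame with `timestamp`, `grams` (>= 0).
#' @param pump_events data.frame with `timestamp`, `kind` (`"stop"`,
#'   `"resume"` or `"cartridge_change"`).
#' @param therapy `"CSII"` (insulin pump) or `"MDI"` (multiple daily
#'   injections).
#' @param window length-2 Date vector, first and last day of the analysis
#'   window (closed interval).
#' @return An object of class `patient_log`.
#' @export
patient_log <- function(readings = empty_readings(), boluses = empty_boluses(),
                        carbs = empty_carbs(), pump_events = empty_pump_events(),
                        therapy = c("CSII", "MDI"),
                        window) {
  therapy <- match.arg(therapy)
  window <- as.Date(window)
  if (length(window) != 2 || any(is.na(window)) || window[2] < window[1])
    stop_smbg("`window` must be two ordered dates")

  readings <- as.data.frame(readings, stringsAsFactors = FALSE)
  boluses <- as.data.frame(boluses, stringsAsFactors = FALSE)
  carbs <- as.data.frame(carbs, stringsAsFactors = FALSE)
  pump_events <- as.data.frame(pump_events, stringsAsFactors = FALSE)

  if (nrow(readings)) {
    if (is.null(readings$mark)) readings$mark <- "none"
    if (is.null(readings$source)) readings$source <- "meter"
    readings$mark[is.na(readings$mark)] <- "none"
    bad_mark <- !readings$mark %in% MARKS
    if (any(bad_mark)) stop_smbg("invalid reading mark: ", readings$mark[which(bad_mark)[1]])
    bad_src <- !readings$source %in% SOURCES
    if (any(bad_src)) stop_smbg("invalid reading source: ", readings$source[which(bad_src)[1]])
    if (any(!is.finite(readings$value)))
      stop_smbg("non-numeric glucose value in readings")
    out_rng <- readings$value < GLUCOSE_RANGE[1] | readings$value > GLUCOSE_RANGE[2]
    if (any(out_rng))
      stop_smbg("glucose value outside meter range [10, 600] mg/dL: ",
                readings$value[which(out_rng)[1]])
  }
  if (nrow(boluses)) {
    if (any(!is.finite(boluses$units)) || any(boluses$units < 0))
      stop_smbg("bolus units must be >= 0")
    boluses$calculator_used <- as.logical(boluses$calculator_used)
  }
  if (nrow(carbs) && (any(!is.finite(carbs$grams)) || any(carbs$grams < 0)))
    stop_smbg("carbohydrate grams must be >= 0")
  if (nrow(pump_events)) {
    bad <- !pump_events$kind %in% PUMP_KINDS
    if (any(bad)) stop_smbg("invalid pump event kind: ", pump_events$kind[which(bad)[1]])
  }

  clip <- function(df) {
    if (!nrow(df)) return(df)
    d <- ts_day(df$timestamp)
    keep <- d >= window[1] & d <= window[2]
    dropped <- sum(!keep)
    if (dropped > 0)
      message(dropped, " record(s) outside the analysis window dropped")
    df <- df[keep, , drop = FALSE]
    df[order(df$timestamp), , drop = FALSE]
  }
  readings <- clip(readings)
  boluses <- clip(boluses)
  carbs <- clip(carbs)
  pump_events <- clip(pump_events)

  if (nrow(readings)) {
    dup <- duplicated(readings$timestamp)
    if (any(dup)) {
      warning(sum(dup), " duplicate reading timestamp(s); keeping first")
      readings <- readings[!dup, , drop = FALSE]
    }
  }
  if (nrow(pump_events)) {
    sr <- pump_events$kind[pump_events$kind %in% c("stop", "resume")]
    if (length(sr) > 1 && any(sr[-1] == sr[-length(sr)]))
      warning("pump stop/resume events do not alternate")
  }

  rownames(readings) <- rownames(boluses) <- rownames(carbs) <-
    rownames(pump_events) <- NULL
  structure(list(readings = readings, boluses = boluses, carbs = carbs,
                 pump_events = pump_events, therapy = therapy,
                 window = window),
            class = "patient_log")
}

#' @export
print.patient_log <- function(x, ...) {
  cat(sprintf("<patient_log> %s therapy, %s to %s (%d days)\n", x$therapy,
              x$window[1], x$window[2],
              as.integer(x$window[2] - x$window[1]) + 1L))
  cat(sprintf("  %d glucose readings, %d boluses, %d carb records, %d pump events\n",
              nrow(x$readings), nrow(x$boluses), nrow(x$carbs),
              nrow(x$pump_events)))
  invisible(x)
}

LOG_CSV_COLS <- c("record_type", "timestamp", "value", "mark",
                  "calculator_used", "pump_kind")

#' Read a patient log from CSV
#'
#' The interchange dialect is one record per row with columns `record_type`
#' (`glucose|bolus|carb|pump`), `timestamp` (`YYYY-MM-DDTHH:MM`), `value`
#' (mg/dL, insulin units or grams, by record type), `mark`, `calculator_used`
#' (0/1) and `pump_kind`. Rows outside `window` are dropped with a message.
#'
#' @param path CSV file path.
#' @inheritParams patient_log
#' @return A validated [patient_log()].
#' @export
read_patient_log <- function(path, therapy = c("CSII", "MDI"), window) {
  therapy <- match.arg(therapy)
  if (!file.exists(path)) stop_smbg("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(LOG_CSV_COLS, names(raw))
  if (length(missing_cols))
    stop_smbg("missing mandatory column(s): ",
              paste(missing_cols, collapse = ", "))
  if (!nrow(raw)) stop_smbg("empty patient log file: ", path)

  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  ts <- parse_ts(raw$timestamp)
  if (anyNA(ts))
    stop_smbg("line ", line_no[which(is.na(ts))[1]],
              ": unparseable timestamp '", raw$timestamp[which(is.na(ts))[1]], "'")

  type <- raw$record_type
  bad_type <- !type %in% c("glucose", "bolus", "carb", "pump")
  if (any(bad_type))
    stop_smbg("line ", line_no[which(bad_type)[1]], ": unknown record_type '",
              type[which(bad_type)[1]], "'")

  val <- num_or_na(raw$value)
  needs_val <- type %in% c("glucose", "bolus", "carb")
  bad_val <- needs_val & (is.na(val) | val < 0 |
                            (type == "glucose" & (val < GLUCOSE_RANGE[1] |
                                                    val > GLUCOSE_RANGE[2])))
  if (any(bad_val))
    stop_smbg("line ", line_no[which(bad_val)[1]], ": invalid value '",
              raw$value[which(bad_val)[1]], "' for record_type '",
              type[which(bad_val)[1]], "'")

  g <- type == "glucose"
  if (!any(g)) stop_smbg("no glucose readings in ", path)
  mark <- raw$mark[g]
  mark[is.na(mark) | mark == ""] <- "none"
  readings <- data.frame(timestamp = ts[g], value = val[g], mark = mark,
                         source = "meter", stringsAsFactors = FALSE)

  b <- type == "bolus"
  boluses <- data.frame(
    timestamp = ts[b], units = val[b],
    calculator_used = raw$calculator_used[b] %in% c("1", "TRUE", "true"),
    stringsAsFactors = FALSE)

  k <- type == "carb"
  carbs <- data.frame(timestamp = ts[k], grams = val[k],
                      stringsAsFactors = FALSE)

  p <- type == "pump"
  pk <- raw$pump_kind[p]
  bad_pk <- !pk %in% PUMP_KINDS
  if (any(bad_pk))
    stop_smbg("line ", line_no[p][which(bad_pk)[1]], ": invalid pump_kind '",
              pk[which(bad_pk)[1]], "'")
  pump_events <- data.frame(timestamp = ts[p], kind = pk,
                            stringsAsFactors = FALSE)

  patient_log(readings, boluses, carbs, pump_events, therapy = therapy,
              window = window)
}

#' Write a patient log to CSV
#'
#' Inverse of [read_patient_log()]: the written file re-reads to an equal log
#' (timestamps at minute resolution, numeric values at 0.1 precision).
#'
#' @param log a [patient_log()].
#' @param path output CSV path.
#' @export
write_patient_log <- function(log, path) {
  stopifnot(inherits(log, "patient_log"))
  fmt_num <- function(x) format(round(x, 1), trim = TRUE, scientific = FALSE)
  row_df <- function(type, ts, value = "", mark = "", calc = "", pk = "") {
    if (!length(ts)) return(NULL)
    data.frame(record_type = type, timestamp = format_ts(ts),
               value = value, mark = mark, calculator_used = calc,
               pump_kind = pk, stringsAsFactors = FALSE)
  }
  parts <- list(
    row_df("glucose", log$readings$timestamp, fmt_num(log$readings$value),
           ifelse(log$readings$mark == "none", "", log$readings$mark)),
    row_df("bolus", log$boluses$timestamp, fmt_num(log$boluses$units),
           calc = as.integer(log$boluses$calculator_used)),
    row_df("carb", log$carbs$timestamp, fmt_num(log$carbs$grams)),
    row_df("pump", log$pump_events$timestamp, pk = log$pump_events$kind))
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  out <- out[order(out$timestamp, match(out$record_type,
                                        c("glucose", "carb", "bolus", "pump"))), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Partition a patient log into calendar days
#'
#' Assigns every record to exactly one calendar day by the local-midnight
#' boundary and returns one entry per day of the analysis window, including
#' days without records.
#'
#' @param log a [patient_log()].
#' @return A list with `days` (Date vector spanning the window) and, for each
#'   stream, an integer matrix-free list of row indices per day
#'   (`readings`, `boluses`, `carbs`, `pump_events`).
#' @export
partition_days <- function(log) {
  stopifnot(inherits(log, "patient_log"))
  days <- seq(log$window[1], log$window[2], by = "day")
  idx_by_day <- function(df) {
    f <- factor(as.character(ts_day(df$timestamp)),
                levels = as.character(days))
    split(seq_len(nrow(df)), f)
  }
  list(days = days,
       readings = idx_by_day(log$readings),
       boluses = idx_by_day(log$boluses),
       carbs = idx_by_day(log$carbs),
       pump_events = idx_by_day(log$pump_events))
}

#' Default time-block scheme
#'
#' Five named day segments used by the time-block patterns: nocturnal
#' 00:00–06:00, breakfast 06:00–11:00, lunch 11:00–16:00, evening meal
#' 16:00–21:00, bedtime 21:00–24:00. Intervals are start-inclusive /
#' end-exclusive and cover the 24 h day without overlap.
#'
#' @return A `time_block_scheme` data.frame with columns `name`, `start_min`,
#'   `end_min` (minutes after midnight).
#' @export
default_time_blocks <- function() {
  time_block_scheme(data.frame(
    name = c("nocturnal", "breakfast", "lunch", "evening_meal", "bedtime"),
    start_min = c(0, 360, 660, 960, 1260),
    end_min = c(360, 660, 960, 1260, 1440),
    stringsAsFactors = FALSE))
}

#' Construct and validate a time-block scheme
#'
#' @param blocks data.frame with `name`, `start_min`, `end_min`; intervals
#'   must tile the 24 h day exactly and include a `nocturnal` block.
#' @return The validated scheme, ordered by `start_min`.
#' @export
time_block_scheme <- function(blocks) {
  blocks <- blocks[order(blocks$start_min), , drop = FALSE]
  if (blocks$start_min[1] != 0 || blocks$end_min[nrow(blocks)] != 1440 ||
      any(blocks$start_min[-1] != blocks$end_min[-nrow(blocks)]))
    stop_smbg("time blocks must cover 00:00-24:00 without gaps or overlap")
  if (!"nocturnal" %in% blocks$name)
    stop_smbg("a 'nocturnal' block is required")
  rownames(blocks) <- NULL
  structure(blocks, class = c("time_block_scheme", "data.frame"))
}

#' Assign readings to time blocks and prandial phases
#'
#' Every reading gets exactly one (block, phase) pair. The block is the clock
#' interval containing the timestamp. The phase is the reading's own pre/post
#' mark when present; for unmarked readings it is inferred from nearby
#' carbohydrate records: `pre` if a carb intake follows within `pre_min`
#' minutes, `post` if one precedes by `post_lo`–`post_hi` minutes (pre takes
#' precedence), else `none`.
#'
#' @param readings readings data.frame of a [patient_log()] (or a single-row
#'   subset).
#' @param carbs carb records data.frame used for phase inference.
#' @param scheme a [time_block_scheme()].
#' @param pre_min,post_lo,post_hi inference windows in minutes.
#' @return data.frame with columns `block` and `phase`, one row per reading.
#' @export
assign_time_block <- function(readings, carbs = empty_carbs(),
                              scheme = default_time_blocks(),
                              pre_min = 30, post_lo = 60, post_hi = 120) {
  if (!nrow(readings))
    return(data.frame(block = character(), phase = character(),
                      stringsAsFactors = FALSE))
  mod <- minute_of_day(readings$timestamp)
  block <- scheme$name[findInterval(mod, scheme$start_min)]

  phase <- readings$mark %||% rep("none", nrow(readings))
  if (is.null(readings$mark)) phase <- rep("none", nrow(readings))
  unmarked <- phase == "none"
  if (any(unmarked) && nrow(carbs)) {
    ct <- sort(as.numeric(carbs$timestamp))
    t <- as.numeric(readings$timestamp[unmarked])
    n_before <- function(x) findInterval(x, ct)  # carbs at or before x
    is_pre <- n_before(t + pre_min * 60) - n_before(t) >= 1
    is_post <- n_before(t - post_lo * 60) - n_before(t - post_hi * 60 - 1) >= 1
    phase[unmarked] <- ifelse(is_pre, "pre", ifelse(is_post, "post", "none"))
  }
  data.frame(block = block, phase = phase, stringsAsFactors = FALSE)
}
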