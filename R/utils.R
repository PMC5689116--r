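# Internal helpers shared across modules.

# Comparator helpers: every rule threshold in the engine goes through one of
# these so that strict (">") vs non-strict (">=") semantics are explicit.
cmp_exceeds <- function(x, threshold, strict = TRUE) {
  if (strict) x > threshold else x >= threshold
}

cmp_below <- function(x, threshold, strict = TRUE) {
  if (strict) x < threshold else x <= threshold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive local timestamps: device downloads carry wall-clock time, so all
# POSIXct values in the package are pinned to UTC and never shifted.
SMBG_TZ <- "UTC"

parse_ts <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = SMBG_TZ)
}

format_ts <- function(x) {
  format(x, "%Y-%m-%dT%H:%M", tz = SMBG_TZ)
}

ts_day <- function(x) as.Date(x, tz = SMBG_TZ)

minute_of_day <- function(x) {
  lt <- as.POSIXlt(x, tz = SMBG_TZ)
  lt$hour * 60L + lt$min
}

# POSIXct at `day` (Date) + "HH:MM" clock time.
day_time <- function(day, hhmm) {
  as.POSIXct(paste0(format(day, "%Y-%m-%d"), "T", hhmm),
             format = "%Y-%m-%dT%H:%M", tz = SMBG_TZ)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

stop_smbg <- function(..., class = "smbg_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
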