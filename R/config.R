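# Pattern configuration: every threshold of the 19-rule dashboard with its
# consensus default, JSON (de)serialization with unknown-key rejection, and
# the named presets.

#' Default pattern configuration
#'
#' Returns the consensus default thresholds of the rule engine. All
#' comparisons against these thresholds are strict (">" / "<") exactly as
#' printed in the rule definitions, except the blood-glucose test frequency
#' day share, which is "on 80\% of days" and read as ">= 80\%" (its
#' `strict` flag is exposed).
#'
#' @return An object of class `pattern_config` (a nested named list,
#'   JSON-serializable).
#' @export
default_pattern_config <- function() {
  cfg <- list(
    schema_version = 1L,
    hypo_threshold = 70,        # mg/dL, hypoglycemia: reading < 70
    hyper_threshold = 160,      # mg/dL, hyperglycemia: reading > 160
    merge_gap_min = 60,         # readings closer than this are one episode
    phase_inference = list(pre_min = 30, post_lo_min = 60, post_hi_min = 120),
    variability = list(
      sd_threshold = 70,        # mg/dL, flag if SD > 70
      cv_enabled = FALSE,       # optional %CV pattern (not one of the 19)
      cv_threshold = 36,        # %, flag if %CV > 36 when enabled
      lbgi_bands = c(1.1, 2.5, 5),
      hbgi_bands = c(4.5, 9)),
    hypo_trend = list(min_per_day = 1, strict = TRUE, run_days = 3),
    hyper_trend = list(min_per_day = 2, strict = TRUE, run_days = 7),
    overcorrection = list(
      fraction = 0.25,          # flag if preceded fraction > 25%
      lookback_min = 180,       # "within <3 h"
      hyper_primary_threshold = 200),  # hyperglycemias counted for the hyper rule
    time_block = list(
      window_days = 7,          # rolling window
      count = 3,                # flag if > 3 in the same block
      preprandial = 150,        # mg/dL, hyper threshold for pre-phase readings
      postprandial = 180),      # mg/dL, hyper threshold for post-phase readings
    cartridge = list(
      expected_interval_days = 7,
      assoc_window_hours = 6,   # hypo counted as change-associated within this
      hypo_assoc_fraction = 0.80,
      delay_days = 1,           # delay pattern needs delay > 1 day
      delay_hyper_fraction = 0.50,
      delay_rate = 0.30),       # frequency pattern: > 30% of changes delayed
    missed_bolus = list(
      count = 3,                # flag if > 3 over the window
      carb_grams = 20,          # qualifying intake > 20 g
      bolus_lookback_min = 120, # no bolus in the 2 h before the hyperglycemia
      rescue_exclusion_min = 60),
    usage = list(
      marks_per_day = 3, marks_day_share = 0.50,
      records_per_day = 3, records_day_share = 0.50,
      stops_per_day = 2, stops_day_share = 0.50),
    adherence = list(
      bg_per_day = 4, bg_day_share = 0.80, bg_day_share_strict = FALSE,
      pre_bolus_fraction = 0.25, bolus_bg_window_min = 30,
      calculator_fraction = 0.25),
    mdi_bolus_patterns = FALSE  # bolus BG-check/calculator rules CSII-only
  )
  structure(cfg, class = "pattern_config")
}

#' Named configuration presets
#'
#' `"default"` is [default_pattern_config()]. `"trend_relaxed"` relaxes the
#' two trend rules in the clinically suggested direction: hypoglycemic trend
#' "at least 1 per day over 3 consecutive days" and hyperglycemic trend
#' "2 or more per day over 4 consecutive days".
#'
#' @param name preset name.
#' @return A `pattern_config`.
#' @export
preset_config <- function(name = c("default", "trend_relaxed")) {
  name <- match.arg(name)
  cfg <- default_pattern_config()
  if (name == "trend_relaxed") {
    cfg$hypo_trend$strict <- FALSE    # >= 1 per day, 3 days
    cfg$hyper_trend$strict <- FALSE   # >= 2 per day, 4 days
    cfg$hyper_trend$run_days <- 4
  }
  cfg
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop_smbg("unknown configuration key: ", full)
    if (is.list(base[[key]])) {
      if (!is.list(override[[key]]))
        stop_smbg("configuration key ", full, " must be a group")
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  c(path, key))
    } else {
      val <- override[[key]]
      if (is.list(val)) val <- unlist(val)
      mode(val) <- mode(base[[key]])
      base[[key]] <- val
    }
  }
  base
}

validate_config <- function(cfg) {
  thresholds <- c(cfg$hypo_threshold, cfg$hyper_threshold, cfg$merge_gap_min,
                  cfg$variability$sd_threshold, cfg$variability$cv_threshold,
                  cfg$hypo_trend$min_per_day, cfg$hypo_trend$run_days,
                  cfg$hyper_trend$min_per_day, cfg$hyper_trend$run_days,
                  cfg$overcorrection$fraction, cfg$overcorrection$lookback_min,
                  cfg$overcorrection$hyper_primary_threshold,
                  cfg$time_block$window_days, cfg$time_block$count,
                  cfg$time_block$preprandial, cfg$time_block$postprandial,
                  unlist(cfg$cartridge), unlist(cfg$missed_bolus),
                  unlist(cfg$usage),
                  cfg$adherence$bg_per_day, cfg$adherence$bg_day_share,
                  cfg$adherence$pre_bolus_fraction,
                  cfg$adherence$bolus_bg_window_min,
                  cfg$adherence$calculator_fraction)
  if (any(!is.finite(thresholds)) || any(thresholds < 0))
    stop_smbg("all configuration thresholds must be non-negative numbers")
  if (cfg$hypo_threshold >= cfg$hyper_threshold)
    stop_smbg("hypo_threshold must be below hyper_threshold")
  if (is.unsorted(cfg$variability$lbgi_bands, strictly = TRUE) ||
      is.unsorted(cfg$variability$hbgi_bands, strictly = TRUE))
    stop_smbg("risk band edges must be strictly increasing")
  invisible(cfg)
}

#' Load a pattern configuration
#'
#' Starts from a preset and optionally merges a JSON override file. Every
#' threshold is addressable by its nested key (e.g.
#' `{"variability": {"sd_threshold": 60}}`); unknown keys are rejected with
#' the offending key named.
#'
#' @param path optional JSON file with overrides.
#' @param preset preset name, see [preset_config()].
#' @return A validated `pattern_config`.
#' @export
load_config <- function(path = NULL, preset = "default") {
  cfg <- preset_config(preset)
  if (!is.null(path)) {
    if (!file.exists(path)) stop_smbg("config file not found: ", path)
    override <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    override$schema_version <- NULL
    cfg <- structure(merge_config(unclass(cfg), override),
                     class = "pattern_config")
  }
  validate_config(cfg)
  cfg
}

#' Serialize a pattern configuration to JSON
#'
#' @param cfg a `pattern_config`.
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
config_to_json <- function(cfg, path = NULL) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
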