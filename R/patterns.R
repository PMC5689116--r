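# The rule engine: 19 pattern detectors grouped in 5 blocks (glycemic
# variability, hypoglycemia, hyperglycemia, use of the system, treatment
# adherence), the red/green dashboard, and dashboard comparison.

CSII_ONLY_PATTERNS <- c("hypo_cartridge", "hyper_cartridge_delay",
                        "missed_bolus", "pump_stops", "cartridge_frequency",
                        "bg_before_bolus", "calculator_use")

PATTERN_BLOCKS <- c(
  sd_high = "variability", lbgi_risk = "variability", hbgi_risk = "variability",
  cv_high = "variability",
  hypo_trend = "hypoglycemia", hypo_overcorrection = "hypoglycemia",
  hypo_time_block = "hypoglycemia", hypo_cartridge = "hypoglycemia",
  hyper_trend = "hyperglycemia", hyper_cartridge_delay = "hyperglycemia",
  hyper_overcorrection = "hyperglycemia", hyper_time_block = "hyperglycemia",
  missed_bolus = "hyperglycemia",
  marks_usage = "use_of_system", record_usage = "use_of_system",
  pump_stops = "use_of_system", cartridge_frequency = "use_of_system",
  bg_frequency = "adherence", bg_before_bolus = "adherence",
  calculator_use = "adherence")

#' Pattern identifiers of the default dashboard
#'
#' The 19 rule identifiers, in dashboard order. The optional `%CV` pattern
#' (`cv_high`) is not part of the 19 and appears only when enabled in the
#' configuration.
#'
#' @return character vector of pattern ids.
#' @export
pattern_ids <- function() {
  setdiff(names(PATTERN_BLOCKS), "cv_high")
}

pattern_applicable <- function(id, therapy, config) {
  if (therapy == "CSII") return(TRUE)
  if (!id %in% CSII_ONLY_PATTERNS) return(TRUE)
  # bolus-calculator adherence rules can be re-enabled for MDI users of
  # calculator devices
  if (id %in% c("bg_before_bolus", "calculator_use") &&
      isTRUE(config$mdi_bolus_patterns)) return(TRUE)
  FALSE
}

pattern_result <- function(id, present, applicable = TRUE, evidence = list(),
                           reason = NULL, config = list()) {
  if (!applicable) {
    present <- FALSE
    reason <- reason %||% "not applicable to this therapy mode"
  }
  structure(list(id = id, block = unname(PATTERN_BLOCKS[[id]]),
                 applicable = applicable, present = isTRUE(present),
                 evidence = evidence, reason = reason, config = config),
            class = "pattern_result")
}

not_applicable <- function(id, config = list()) {
  pattern_result(id, FALSE, applicable = FALSE, config = config)
}

# Rolling time-block count: items (day_index, block) are tallied per block
# over every `window_days`-day window inside the analysis window; the rule
# fires when any block in any window strictly exceeds `count`.
rolling_block_count <- function(day_idx, block, n_days, scheme, window_days,
                                count) {
  blocks <- scheme$name
  w <- min(window_days, n_days)
  if (!length(day_idx)) {
    return(list(present = FALSE, max_count = 0L, block = NA_character_,
                window_start_day = NA_integer_))
  }
  m <- matrix(0L, nrow = n_days, ncol = length(blocks),
              dimnames = list(NULL, blocks))
  for (i in seq_along(day_idx))
    m[day_idx[i], block[i]] <- m[day_idx[i], block[i]] + 1L
  cs <- rbind(0L, apply(m, 2, cumsum))
  roll <- cs[(w + 1):(n_days + 1), , drop = FALSE] -
    cs[1:(n_days - w + 1), , drop = FALSE]
  best <- which(roll == max(roll), arr.ind = TRUE)[1, ]
  list(present = cmp_exceeds(max(roll), count, strict = TRUE),
       max_count = as.integer(max(roll)),
       block = blocks[best[["col"]]],
       window_start_day = as.integer(best[["row"]]))
}

log_day_index <- function(ts, window) {
  as.integer(ts_day(ts) - window[1]) + 1L
}

# Shared per-log context so the block detectors compute events and block
# assignments once.
log_context <- function(log, config, scheme = default_time_blocks()) {
  days <- seq(log$window[1], log$window[2], by = "day")
  ph <- config$phase_inference
  blocks <- assign_time_block(log$readings, log$carbs, scheme,
                              pre_min = ph$pre_min, post_lo = ph$post_lo_min,
                              post_hi = ph$post_hi_min)
  list(
    days = days, n_days = length(days), scheme = scheme, blocks = blocks,
    hypo_events = detect_glycemic_events(log$readings, config$hypo_threshold,
                                         "hypo", config$merge_gap_min),
    hyper_events = detect_glycemic_events(log$readings, config$hyper_threshold,
                                          "hyper", config$merge_gap_min),
    hyper_primary_events = detect_glycemic_events(
      log$readings, config$overcorrection$hyper_primary_threshold, "hyper",
      config$merge_gap_min),
    cycles = cartridge_cycles(log$pump_events,
                              config$cartridge$expected_interval_days))
}

#' Glycemic variability patterns
#'
#' Standard deviation above threshold, moderate-or-high LBGI, moderate-or-high
#' HBGI, and (when enabled) percentage coefficient of variation above
#' threshold. With fewer than two readings the patterns are reported absent
#' with an explicit not-evaluable reason.
#'
#' @param log a [patient_log()].
#' @param config a [default_pattern_config()].
#' @param ctx internal shared context (computed when `NULL`).
#' @return list of `pattern_result`s.
#' @export
detect_variability <- function(log, config = default_pattern_config(),
                               ctx = NULL) {
  v <- config$variability
  bands <- list(low = v$lbgi_bands, high = v$hbgi_bands)
  snap <- list(sd_threshold = v$sd_threshold, lbgi_bands = v$lbgi_bands,
               hbgi_bands = v$hbgi_bands)
  n <- nrow(log$readings)
  if (n < 2) {
    reason <- "fewer than 2 glucose readings"
    out <- list(
      pattern_result("sd_high", FALSE, reason = reason, config = snap),
      pattern_result("lbgi_risk", FALSE, reason = reason, config = snap),
      pattern_result("hbgi_risk", FALSE, reason = reason, config = snap))
    if (isTRUE(v$cv_enabled))
      out <- c(out, list(pattern_result("cv_high", FALSE, reason = reason,
                                        config = snap)))
    return(out)
  }
  s <- glucose_summary(log$readings$value, bands)
  out <- list(
    pattern_result("sd_high", cmp_exceeds(s$sd, v$sd_threshold),
                   evidence = list(sd = s$sd, n = s$n,
                                   threshold = v$sd_threshold),
                   config = snap),
    pattern_result("lbgi_risk", s$lbgi_category %in% c("moderate", "high"),
                   evidence = list(lbgi = s$lbgi, category = s$lbgi_category),
                   config = snap),
    pattern_result("hbgi_risk", s$hbgi_category %in% c("moderate", "high"),
                   evidence = list(hbgi = s$hbgi, category = s$hbgi_category),
                   config = snap))
  if (isTRUE(v$cv_enabled))
    out <- c(out, list(pattern_result(
      "cv_high", cmp_exceeds(s$cv_percent, v$cv_threshold),
      evidence = list(cv_percent = s$cv_percent, threshold = v$cv_threshold),
      config = snap)))
  out
}

#' Hypoglycemia patterns
#'
#' Hypoglycemic trend (more than `min_per_day` events per day over
#' `run_days` consecutive days), overcorrection (share of hypoglycemic
#' events preceded by a hyperglycemic event within the lookback), time-block
#' accumulation, and association with cartridge changes (pump therapy only).
#'
#' @inheritParams detect_variability
#' @return list of `pattern_result`s.
#' @export
detect_hypo_patterns <- function(log, config = default_pattern_config(),
                                 ctx = NULL) {
  ctx <- ctx %||% log_context(log, config)
  ev <- ctx$hypo_events
  counts <- daily_counts(ev, ctx$days)

  tr_cfg <- config$hypo_trend
  run <- longest_qualifying_run(counts, tr_cfg$min_per_day, tr_cfg$run_days,
                                tr_cfg$strict)
  trend <- pattern_result(
    "hypo_trend", run$satisfied,
    evidence = list(daily_counts_max = max(counts), run_start = run$run_start,
                    run_length = run$run_length, n_events = nrow(ev)),
    config = tr_cfg)

  oc_cfg <- config$overcorrection
  pf <- preceded_fraction(ev, ctx$hyper_events, oc_cfg$lookback_min)
  overc <- pattern_result(
    "hypo_overcorrection",
    !pf$empty && cmp_exceeds(pf$fraction, oc_cfg$fraction),
    evidence = list(fraction = pf$fraction, numerator = pf$numerator,
                    denominator = pf$denominator),
    reason = if (pf$empty) "no hypoglycemic events in the window",
    config = oc_cfg)

  tb_cfg <- config$time_block
  if (nrow(ev)) {
    mod <- minute_of_day(ev$start)
    blk <- ctx$scheme$name[findInterval(mod, ctx$scheme$start_min)]
    didx <- log_day_index(ev$start, log$window)
  } else blk <- didx <- integer()
  rb <- rolling_block_count(didx, blk, ctx$n_days, ctx$scheme,
                            tb_cfg$window_days, tb_cfg$count)
  tblock <- pattern_result(
    "hypo_time_block", rb$present,
    evidence = list(max_count = rb$max_count, block = rb$block,
                    window_start_day = rb$window_start_day,
                    count_threshold = tb_cfg$count),
    config = tb_cfg)

  ca_cfg <- config$cartridge
  if (!pattern_applicable("hypo_cartridge", log$therapy, config)) {
    cart <- not_applicable("hypo_cartridge", config = ca_cfg)
  } else {
    changes <- sort(log$pump_events$timestamp[
      log$pump_events$kind == "cartridge_change"])
    if (!length(changes)) {
      cart <- pattern_result("hypo_cartridge", FALSE,
                             reason = "no cartridge changes recorded",
                             config = ca_cfg)
    } else {
      win <- ca_cfg$assoc_window_hours * 3600
      starts <- as.numeric(ev$start)
      hit <- vapply(as.numeric(changes), function(ch)
        any(starts >= ch & starts <= ch + win), logical(1))
      frac <- mean(hit)
      cart <- pattern_result(
        "hypo_cartridge", cmp_exceeds(frac, ca_cfg$hypo_assoc_fraction),
        evidence = list(fraction = frac, n_changes = length(changes),
                        n_with_hypo = sum(hit)),
        config = ca_cfg)
    }
  }
  list(trend, overc, tblock, cart)
}

#' Hyperglycemia patterns
#'
#' Hyperglycemic trend, cartridge-change delay with predominant
#' hyperglycemia during the delay, overcorrection (hyperglycemias above the
#' primary threshold preceded by a hypoglycemia within the lookback),
#' time-block accumulation with phase-specific thresholds, and missed-bolus
#' hyperglycemias (pump therapy only).
#'
#' @inheritParams detect_variability
#' @return list of `pattern_result`s.
#' @export
detect_hyper_patterns <- function(log, config = default_pattern_config(),
                                  ctx = NULL) {
  ctx <- ctx %||% log_context(log, config)
  ev <- ctx$hyper_events
  counts <- daily_counts(ev, ctx$days)

  tr_cfg <- config$hyper_trend
  run <- longest_qualifying_run(counts, tr_cfg$min_per_day, tr_cfg$run_days,
                                tr_cfg$strict)
  trend <- pattern_result(
    "hyper_trend", run$satisfied,
    evidence = list(daily_counts_max = max(counts), run_start = run$run_start,
                    run_length = run$run_length, n_events = nrow(ev)),
    config = tr_cfg)

  ca_cfg <- config$cartridge
  if (!pattern_applicable("hyper_cartridge_delay", log$therapy, config)) {
    delay <- not_applicable("hyper_cartridge_delay", config = ca_cfg)
  } else {
    cyc <- ctx$cycles
    delayed <- cyc[cmp_exceeds(cyc$delay_days, ca_cfg$delay_days), ,
                   drop = FALSE]
    best_frac <- 0; best_delay <- if (nrow(cyc)) max(cyc$delay_days) else 0
    hit <- FALSE
    if (nrow(delayed)) {
      t <- as.numeric(log$readings$timestamp)
      for (i in seq_len(nrow(delayed))) {
        period_start <- as.numeric(delayed$prev_change[i]) +
          ca_cfg$expected_interval_days * 86400
        period_end <- as.numeric(delayed$change[i])
        in_p <- t >= period_start & t <= period_end
        if (!any(in_p)) next
        frac <- mean(log$readings$value[in_p] > config$hyper_threshold)
        if (frac > best_frac) best_frac <- frac
        if (cmp_exceeds(frac, ca_cfg$delay_hyper_fraction)) hit <- TRUE
      }
    }
    delay <- pattern_result(
      "hyper_cartridge_delay", hit,
      evidence = list(n_cycles = nrow(cyc), n_delayed = nrow(delayed),
                      max_delay_days = best_delay,
                      max_hyper_fraction = best_frac),
      reason = if (!nrow(cyc)) "fewer than 2 cartridge changes recorded",
      config = ca_cfg)
  }

  oc_cfg <- config$overcorrection
  pf <- preceded_fraction(ctx$hyper_primary_events, ctx$hypo_events,
                          oc_cfg$lookback_min)
  overc <- pattern_result(
    "hyper_overcorrection",
    !pf$empty && cmp_exceeds(pf$fraction, oc_cfg$fraction),
    evidence = list(fraction = pf$fraction, numerator = pf$numerator,
                    denominator = pf$denominator,
                    primary_threshold = oc_cfg$hyper_primary_threshold),
    reason = if (pf$empty)
      "no hyperglycemias above the primary threshold in the window",
    config = oc_cfg)

  tb_cfg <- config$time_block
  thr <- ifelse(ctx$blocks$phase == "pre", tb_cfg$preprandial,
                ifelse(ctx$blocks$phase == "post", tb_cfg$postprandial,
                       config$hyper_threshold))
  q <- log$readings$value > thr
  rb <- rolling_block_count(
    log_day_index(log$readings$timestamp[q], log$window),
    ctx$blocks$block[q], ctx$n_days, ctx$scheme, tb_cfg$window_days,
    tb_cfg$count)
  tblock <- pattern_result(
    "hyper_time_block", rb$present,
    evidence = list(max_count = rb$max_count, block = rb$block,
                    window_start_day = rb$window_start_day,
                    count_threshold = tb_cfg$count),
    config = tb_cfg)

  mb_cfg <- config$missed_bolus
  if (!pattern_applicable("missed_bolus", log$therapy, config)) {
    missed <- not_applicable("missed_bolus", config = mb_cfg)
  } else {
    t_hyper <- as.numeric(log$readings$timestamp[
      log$readings$value > config$hyper_threshold])
    carb_t <- as.numeric(log$carbs$timestamp)
    carb_g <- log$carbs$grams
    bolus_t <- as.numeric(log$boluses$timestamp)
    hypo_t <- as.numeric(log$readings$timestamp[
      log$readings$value < config$hypo_threshold])
    look <- mb_cfg$bolus_lookback_min * 60
    rescue <- mb_cfg$rescue_exclusion_min * 60
    qualifies <- vapply(t_hyper, function(th) {
      in_win <- carb_t >= th - look & carb_t < th & carb_g > mb_cfg$carb_grams
      if (!any(in_win)) return(FALSE)
      # carb intakes shortly after a hypoglycemia are rescue carbs, not meals
      is_rescue <- vapply(carb_t[in_win], function(tc)
        any(hypo_t >= tc - rescue & hypo_t <= tc), logical(1))
      if (!any(!is_rescue)) return(FALSE)
      !any(bolus_t >= th - look & bolus_t <= th)
    }, logical(1))
    n_missed <- sum(qualifies)
    missed <- pattern_result(
      "missed_bolus", cmp_exceeds(n_missed, mb_cfg$count),
      evidence = list(n_missed_bolus_hypers = n_missed,
                      n_hyper_readings = length(t_hyper),
                      count_threshold = mb_cfg$count),
      config = mb_cfg)
  }
  list(trend, delay, overc, tblock, missed)
}

day_share_result <- function(id, per_day, per_day_threshold, day_share,
                             deficient_below = TRUE, share_strict = TRUE,
                             config = list()) {
  flagged <- if (deficient_below) {
    cmp_below(per_day, per_day_threshold, strict = TRUE)
  } else {
    cmp_exceeds(per_day, per_day_threshold, strict = TRUE)
  }
  share <- mean(flagged)
  pattern_result(
    id, cmp_exceeds(share, day_share, strict = share_strict),
    evidence = list(day_share = share, n_days = length(per_day),
                    n_flagged_days = sum(flagged),
                    share_threshold = day_share),
    config = config)
}

#' Use-of-system patterns
#'
#' Insufficient pre-/post-prandial marking, insufficient insulin and
#' carbohydrate records, repeated pump stops, and delayed cartridge changes
#' (the latter two pump therapy only). Each rule combines a per-day
#' deficiency criterion with a share-of-days criterion; every calendar day
#' of the window counts, including days without records.
#'
#' @inheritParams detect_variability
#' @return list of `pattern_result`s.
#' @export
detect_usage_patterns <- function(log, config = default_pattern_config(),
                                  ctx = NULL) {
  ctx <- ctx %||% log_context(log, config)
  u <- config$usage
  part <- partition_days(log)
  marked_per_day <- vapply(part$readings, function(i)
    sum(log$readings$mark[i] != "none"), integer(1))
  marks <- day_share_result("marks_usage", marked_per_day, u$marks_per_day,
                            u$marks_day_share, config = u)

  records_per_day <- vapply(part$boluses, length, integer(1)) +
    vapply(part$carbs, length, integer(1))
  records <- day_share_result("record_usage", records_per_day,
                              u$records_per_day, u$records_day_share,
                              config = u)

  if (!pattern_applicable("pump_stops", log$therapy, config)) {
    stops <- not_applicable("pump_stops", config = u)
  } else {
    stop_counts <- pump_stop_daily_counts(log$pump_events, ctx$days)
    stops <- day_share_result("pump_stops", stop_counts, u$stops_per_day,
                              u$stops_day_share, deficient_below = FALSE,
                              config = u)
  }

  ca_cfg <- config$cartridge
  if (!pattern_applicable("cartridge_frequency", log$therapy, config)) {
    freq <- not_applicable("cartridge_frequency", config = ca_cfg)
  } else if (!nrow(ctx$cycles)) {
    freq <- pattern_result("cartridge_frequency", FALSE,
                           reason = "fewer than 2 cartridge changes recorded",
                           config = ca_cfg)
  } else {
    delayed <- ctx$cycles$delay_days > 0
    share <- mean(delayed)
    freq <- pattern_result(
      "cartridge_frequency", cmp_exceeds(share, ca_cfg$delay_rate),
      evidence = list(delayed_share = share, n_cycles = nrow(ctx$cycles),
                      n_delayed = sum(delayed)),
      config = ca_cfg)
  }
  list(marks, records, stops, freq)
}

#' Treatment-adherence patterns
#'
#' Low blood-glucose test frequency, boluses given without a prior glucose
#' check, and boluses given without the bolus calculator (the bolus rules
#' are pump-therapy only by default). With zero boluses the bolus-based
#' rules are reported absent with an explicit not-evaluable reason.
#'
#' @inheritParams detect_variability
#' @return list of `pattern_result`s.
#' @export
detect_adherence_patterns <- function(log, config = default_pattern_config(),
                                      ctx = NULL) {
  a <- config$adherence
  part <- partition_days(log)
  readings_per_day <- vapply(part$readings, length, integer(1))
  bg_freq <- day_share_result("bg_frequency", readings_per_day, a$bg_per_day,
                              a$bg_day_share,
                              share_strict = isTRUE(a$bg_day_share_strict),
                              config = a)

  n_bolus <- nrow(log$boluses)
  mk_bolus_pattern <- function(id, lacking, frac_threshold) {
    if (!pattern_applicable(id, log$therapy, config))
      return(not_applicable(id, config = a))
    if (!n_bolus)
      return(pattern_result(id, FALSE, reason = "no boluses recorded",
                            config = a))
    frac <- mean(lacking)
    pattern_result(id, cmp_exceeds(frac, frac_threshold),
                   evidence = list(fraction = frac, n_boluses = n_bolus,
                                   n_flagged = sum(lacking)),
                   config = a)
  }

  if (n_bolus) {
    rt <- sort(as.numeric(log$readings$timestamp))
    bt <- as.numeric(log$boluses$timestamp)
    win <- a$bolus_bg_window_min * 60
    no_bg <- findInterval(bt, rt) == findInterval(bt - win - 1, rt)
    manual <- !log$boluses$calculator_used
  } else no_bg <- manual <- logical()

  list(bg_freq,
       mk_bolus_pattern("bg_before_bolus", no_bg, a$pre_bolus_fraction),
       mk_bolus_pattern("calculator_use", manual, a$calculator_fraction))
}

#' Run the full pattern dashboard
#'
#' Runs all five block detectors on a patient log and returns the red/green
#' dashboard: one result per pattern with its present/absent flag,
#' therapy-mode applicability, and the evidence behind the decision. With
#' the default configuration a pump-therapy (CSII) dashboard carries 19
#' applicable patterns and an injection-therapy (MDI) dashboard 12.
#'
#' @inheritParams detect_variability
#' @return object of class `smbg_dashboard`.
#' @export
run_dashboard <- function(log, config = default_pattern_config()) {
  stopifnot(inherits(log, "patient_log"))
  validate_config(config)
  ctx <- log_context(log, config)
  results <- c(detect_variability(log, config, ctx),
               detect_hypo_patterns(log, config, ctx),
               detect_hyper_patterns(log, config, ctx),
               detect_usage_patterns(log, config, ctx),
               detect_adherence_patterns(log, config, ctx))
  names(results) <- vapply(results, `[[`, character(1), "id")
  structure(list(window = log$window, therapy = log$therapy,
                 patterns = results, config = config),
            class = "smbg_dashboard")
}

#' @export
print.smbg_dashboard <- function(x, ...) {
  cat(sprintf("<smbg_dashboard> %s, %s to %s\n", x$therapy, x$window[1],
              x$window[2]))
  for (blk in unique(unname(PATTERN_BLOCKS))) {
    res <- Filter(function(r) r$block == blk, x$patterns)
    if (!length(res)) next
    cat(" ", blk, "\n")
    for (r in res) {
      status <- if (!r$applicable) "  n/a " else if (r$present) "PRESENT"
      else "absent "
      cat(sprintf("    [%s] %s%s\n", status, r$id,
                  if (!is.null(r$reason) && r$applicable)
                    paste0(" (", r$reason, ")") else ""))
    }
  }
  invisible(x)
}

#' Count applicable patterns in a dashboard
#'
#' @param dashboard an `smbg_dashboard`.
#' @return integer.
#' @export
n_applicable <- function(dashboard) {
  sum(vapply(dashboard$patterns, `[[`, logical(1), "applicable"))
}

#' Present pattern ids of a dashboard
#'
#' @param dashboard an `smbg_dashboard`.
#' @return character vector of pattern ids flagged present.
#' @export
present_patterns <- function(dashboard) {
  names(Filter(function(r) r$present, dashboard$patterns))
}

#' Serialize a dashboard to JSON
#'
#' Key order is stable, so identical log and configuration give bit-identical
#' JSON. A run manifest (tool version, config hash, input digests,
#' timestamps, warnings) can be embedded for provenance; it is omitted by
#' default to keep the payload deterministic.
#'
#' @param dashboard an `smbg_dashboard`.
#' @param path optional output file.
#' @param manifest optional manifest list from [run_manifest()].
#' @return JSON string (invisibly when written to `path`).
#' @export
dashboard_to_json <- function(dashboard, path = NULL, manifest = NULL) {
  payload <- list(
    schema_version = 1L,
    window = as.character(dashboard$window),
    therapy = dashboard$therapy,
    patterns = lapply(unname(dashboard$patterns), function(r)
      list(id = r$id, block = r$block, applicable = r$applicable,
           present = r$present, evidence = r$evidence,
           reason = r$reason, config = r$config)),
    config = unclass(dashboard$config))
  if (!is.null(manifest)) payload$manifest <- manifest
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Compare two dashboards of the same patient and configuration
#'
#' @param a,b `smbg_dashboard`s computed under identical configuration and
#'   therapy (e.g. two consecutive analysis windows).
#' @return data.frame with columns `id` and `status` (`"new"` when a pattern
#'   appears in `b`, `"resolved"` when it clears, else `"unchanged"`).
#' @export
compare_dashboards <- function(a, b) {
  stopifnot(inherits(a, "smbg_dashboard"), inherits(b, "smbg_dashboard"))
  if (a$therapy != b$therapy)
    stop_smbg("dashboards have different therapy modes")
  if (!identical(unclass(a$config), unclass(b$config)))
    stop_smbg("dashboards were computed under different configurations")
  ids <- names(a$patterns)
  pa <- vapply(a$patterns, `[[`, logical(1), "present")
  pb <- vapply(b$patterns[ids], `[[`, logical(1), "present")
  data.frame(id = ids,
             status = ifelse(!pa & pb, "new",
                             ifelse(pa & !pb, "resolved", "unchanged")),
             row.names = NULL, stringsAsFactors = FALSE)
}
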