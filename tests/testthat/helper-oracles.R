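# Independent brute-force oracle for two-rater agreement on a 2x2 table:
# expand the table to rating vectors and compute observed and chance
# agreement from empirical category frequencies (no marginal algebra shared
# with the implementation).
kappa_oracle <- function(a, b, c, d) {
  x <- rep(c(1, 1, 0, 0), times = c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), times = c(a, b, c, d))
  p_o <- mean(x == y)
  p_e <- sum(vapply(c(0, 1), function(k) mean(x == k) * mean(y == k),
                    numeric(1)))
  list(p_o = p_o, p_e = p_e,
       kappa = if (p_e >= 1 - 1e-12) NA_real_ else (p_o - p_e) / (1 - p_e))
}

# Per-case panel agreement percentages for the four evaluation cases
# (two pump-therapy, two injection-therapy patients) and the published
# global column; reviewer counts were 35, 36, 37 and 37. CSII-only rows
# carry NA for the injection-therapy cases.
AGREEMENT_CASES <- local({
  df <- read.csv(text = "
pattern,csii1,csii2,mdi1,mdi2,global
sd_high,100,100,83.8,100,95.9
lbgi_risk,97.1,86.1,94.6,81.1,89.7
hbgi_risk,91.4,94.4,94.6,86.5,91.7
hypo_trend,88.6,63.9,89.2,27.0,66.9
hypo_overcorrection,91.4,33.3,64.9,64.9,63.4
hypo_time_block,74.3,55.6,97.3,86.5,78.6
hypo_cartridge,94.3,100,NA,NA,97.2
hyper_trend,2.9,91.7,70.3,10.8,44.1
hyper_cartridge_delay,60.0,77.8,NA,NA,69.0
hyper_overcorrection,85.7,52.8,73.0,64.9,69.0
hyper_time_block,97.1,91.7,24.3,86.5,74.5
missed_bolus,74.3,86.1,NA,NA,80.3
marks_usage,82.9,22.2,73.0,81.1,64.8
record_usage,77.1,66.7,78.4,89.2,77.9
pump_stops,71.4,61.1,NA,NA,66.2
bg_frequency,71.4,69.4,59.5,70.3,67.5
bg_before_bolus,71.4,63.9,NA,NA,67.6
calculator_use,82.9,66.7,NA,NA,74.6
", stringsAsFactors = FALSE)
  df
})
AGREEMENT_N <- c(csii1 = 35, csii2 = 36, mdi1 = 37, mdi2 = 37)
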