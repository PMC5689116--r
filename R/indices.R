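# Glycemic variability statistics and blood-glucose risk indices.
#
# LBGI/HBGI follow the canonical symmetrizing log-power transform of glucose
# (Kovatchev risk space): f(bg) = 1.509 * ((ln bg)^1.084 - 5.381) for bg in
# mg/dL, squared risk r = 10 * f^2, with the low (resp. high) index the mean
# of r over readings on the hypoglycemic (hyperglycemic) side of the
# risk-neutral point f = 0 (~112.5 mg/dL).

#' Symmetrizing blood-glucose risk transform
#'
#' Maps glucose (mg/dL) to a signed risk value `f` — negative below the
#' risk-neutral point (~112.5 mg/dL), positive above, strictly increasing —
#' and a squared risk `r = 10 * f^2`.
#'
#' @param bg numeric vector of glucose values, mg/dL (must be > 0).
#' @return list with numeric vectors `f` and `r`.
#' @export
risk_transform <- function(bg) {
  if (any(!is.finite(bg)) || any(bg <= 0))
    stop_smbg("glucose must be positive for the risk transform")
  f <- 1.509 * (log(bg)^1.084 - 5.381)
  list(f = f, r = 10 * f^2)
}

#' Low and high blood-glucose risk indices
#'
#' LBGI is the mean squared risk over readings below the risk-neutral point;
#' HBGI the mean over readings above it. Both are dimensionless and >= 0; a
#' series entirely above the neutral point has LBGI exactly 0 (and
#' symmetrically).
#'
#' @param readings numeric vector of glucose values, mg/dL.
#' @return named numeric vector `c(lbgi =, hbgi =)`; both `NA` for empty
#'   input.
#' @export
compute_risk_indices <- function(readings) {
  if (!length(readings)) return(c(lbgi = NA_real_, hbgi = NA_real_))
  tr <- risk_transform(readings)
  c(lbgi = mean(tr$r * (tr$f < 0)), hbgi = mean(tr$r * (tr$f > 0)))
}

#' Default risk-category band edges
#'
#' Lower edge inclusive, upper edge exclusive. Low side: minimal < 1.1,
#' low 1.1–2.5, moderate 2.5–5, high >= 5. High side: low < 4.5, moderate
#' 4.5–9, high >= 9. The variability patterns flag when the category is
#' moderate or high.
#'
#' @return list with numeric vectors `low` and `high` of band edges.
#' @export
default_risk_bands <- function() {
  list(low = c(1.1, 2.5, 5), high = c(4.5, 9))
}

#' Categorize a risk-index value
#'
#' @param value LBGI or HBGI value (>= 0).
#' @param side `"low"` for LBGI, `"high"` for HBGI.
#' @param bands band edges as in [default_risk_bands()].
#' @return `"minimal"`, `"low"`, `"moderate"` or `"high"` (`"minimal"` does
#'   not exist on the high side).
#' @export
classify_risk <- function(value, side = c("low", "high"),
                          bands = default_risk_bands()) {
  side <- match.arg(side)
  if (is.na(value)) return(NA_character_)
  stopifnot(value >= 0)
  if (side == "low") {
    c("minimal", "low", "moderate", "high")[findInterval(value, bands$low) + 1L]
  } else {
    c("low", "moderate", "high")[findInterval(value, bands$high) + 1L]
  }
}

#' Summary statistics for a glucose series
#'
#' Mean, sample standard deviation (n-1 denominator), percentage coefficient
#' of variation (100 * SD / mean) and the low/high blood-glucose risk indices
#' with their categories. With fewer than two readings, `sd` and `cv_percent`
#' are `NA` and `sd_defined` is `FALSE` (never silently 0).
#'
#' @param readings numeric vector of glucose values, mg/dL.
#' @param bands risk band edges, see [default_risk_bands()].
#' @return object of class `glucose_summary` (a named list).
#' @export
glucose_summary <- function(readings, bands = default_risk_bands()) {
  n <- length(readings)
  if (n < 1) stop_smbg("glucose_summary needs at least one reading")
  m <- mean(readings)
  s <- if (n >= 2) stats::sd(readings) else NA_real_
  cv <- if (n >= 2 && m > 0) 100 * s / m else NA_real_
  ri <- compute_risk_indices(readings)
  structure(list(
    n = n, mean = m, sd = s, cv_percent = cv, sd_defined = n >= 2,
    lbgi = unname(ri["lbgi"]), hbgi = unname(ri["hbgi"]),
    lbgi_category = classify_risk(unname(ri["lbgi"]), "low", bands),
    hbgi_category = classify_risk(unname(ri["hbgi"]), "high", bands)),
    class = "glucose_summary")
}

#' @export
print.glucose_summary <- function(x, ...) {
  cat(sprintf(
    "<glucose_summary> n=%d mean=%.1f sd=%s cv=%s%% lbgi=%.2f (%s) hbgi=%.2f (%s)\n",
    x$n, x$mean,
    if (x$sd_defined) sprintf("%.1f", x$sd) else "NA",
    if (x$sd_defined) sprintf("%.1f", x$cv_percent) else "NA",
    x$lbgi, x$lbgi_category, x$hbgi, x$hbgi_category))
  invisible(x)
}
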