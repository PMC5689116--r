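# Validation statistics: percent agreement, Cohen's kappa with asymptotic
# 95% CI and interpretation bands, and n-weighted pooling of per-case
# agreement fractions.

#' Observed percent agreement between two binary raters
#'
#' Missing ratings are dropped pairwise. Zero comparable pairs yields `NA`
#' with `empty = TRUE`.
#'
#' @param reference,rater vectors of ratings (logical, 0/1, or
#'   `"present"`/`"absent"`); `NA` allowed.
#' @return list with `fraction`, `matches`, `n`, `empty`.
#' @export
percent_agreement <- function(reference, rater) {
  reference <- as_binary_rating(reference)
  rater <- as_binary_rating(rater)
  if (length(reference) != length(rater))
    stop_smbg("rating vectors must have equal length")
  keep <- !is.na(reference) & !is.na(rater)
  n <- sum(keep)
  if (!n) return(list(fraction = NA_real_, matches = 0L, n = 0L,
                      empty = TRUE))
  matches <- sum(reference[keep] == rater[keep])
  list(fraction = matches / n, matches = matches, n = n, empty = FALSE)
}

as_binary_rating <- function(x) {
  if (is.character(x)) {
    out <- rep(NA, length(x))
    out[x %in% c("present", "1", "TRUE", "true", "yes")] <- TRUE
    out[x %in% c("absent", "0", "FALSE", "false", "no")] <- FALSE
    bad <- !is.na(x) & x != "" & is.na(out)
    if (any(bad)) stop_smbg("invalid rating token: ", x[which(bad)[1]])
    out
  } else {
    as.logical(x)
  }
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Counts follow the usual layout: `a` both raters positive, `d` both
#' negative, `b` and `c` the discordant cells. Chance agreement comes from
#' the row/column marginals; the 95\% CI uses the Fleiss–Cohen large-sample
#' standard error, truncated to \[-1, 1\]. When a marginal is degenerate so
#' that chance agreement equals 1, kappa is undefined and reported `NA`
#' with the observed agreement still attached.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return object of class `agreement_result`: `p_o`, `p_e`, `kappa`,
#'   `se`, `ci95` (length 2), `n`, `interpretation`.
#' @export
cohens_kappa <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_smbg("cell counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop_smbg("at least one paired observation required")
  p <- matrix(counts / n, 2, 2, byrow = TRUE)  # rows: rater 1, cols: rater 2
  p_o <- p[1, 1] + p[2, 2]
  rs <- rowSums(p); cs <- colSums(p)
  p_e <- sum(rs * cs)
  if (p_e >= 1 - 1e-12) {
    res <- list(p_o = p_o, p_e = p_e, kappa = NA_real_, se = NA_real_,
                ci95 = c(NA_real_, NA_real_), n = n,
                interpretation = NA_character_,
                degenerate = TRUE)
    return(structure(res, class = "agreement_result"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
  A <- sum(diag(p) * (1 - (rs + cs) * (1 - kappa))^2)
  B <- (1 - kappa)^2 * (p[1, 2] * (cs[1] + rs[2])^2 +
                          p[2, 1] * (cs[2] + rs[1])^2)
  C <- (kappa - p_e * (1 - kappa))^2
  var_k <- (A + B - C) / (n * (1 - p_e)^2)
  se <- sqrt(max(0, var_k))
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * stats::qnorm(0.975) * se))
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa, se = se, ci95 = ci,
                 n = n, interpretation = interpret_kappa(kappa),
                 degenerate = FALSE),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("<agreement> p_o=%.3f, kappa undefined (degenerate marginals), n=%d\n",
                x$p_o, x$n))
  } else {
    cat(sprintf("<agreement> p_o=%.3f p_e=%.3f kappa=%.3f (95%% CI %.3f, %.3f) n=%d — %s\n",
                x$p_o, x$p_e, x$kappa, x$ci95[1], x$ci95[2], x$n,
                x$interpretation))
  }
  invisible(x)
}

#' Cohen's kappa from two rating vectors
#'
#' Convenience wrapper building the 2x2 table (missing ratings dropped
#' pairwise) and delegating to [cohens_kappa()].
#'
#' @inheritParams percent_agreement
#' @return An `agreement_result`.
#' @export
kappa_from_ratings <- function(reference, rater) {
  reference <- as_binary_rating(reference)
  rater <- as_binary_rating(rater)
  keep <- !is.na(reference) & !is.na(rater)
  x <- reference[keep]; y <- rater[keep]
  cohens_kappa(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
}

#' Pool per-case agreement fractions by evaluation counts
#'
#' Computes the evaluation-weighted mean, i.e. total matching evaluations
#' over total evaluations — identical to percent agreement on the
#' concatenated evaluations.
#'
#' @param fractions per-case agreement fractions in \[0, 1\] (percentages
#'   accepted too; values > 1 are interpreted as percent and the result is
#'   then also on the percent scale).
#' @param n per-case evaluation counts (> 0).
#' @return pooled fraction (or percentage, matching the input scale).
#' @export
pooled_agreement <- function(fractions, n) {
  if (!length(fractions)) stop_smbg("no per-case fractions supplied")
  if (length(fractions) != length(n)) stop_smbg("lengths differ")
  if (any(n <= 0)) stop_smbg("evaluation counts must be positive")
  sum(fractions * n) / sum(n)
}

#' Interpret a kappa value
#'
#' Bands: no agreement (kappa < 0), not significant (0–0.20), medium
#' (0.21–0.40), moderate (0.41–0.60), substantial (0.61–0.80), almost
#' perfect (> 0.80).
#'
#' @param kappa value in \[-1, 1\].
#' @return interpretation label.
#' @export
interpret_kappa <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < -1 - 1e-9 || kappa > 1 + 1e-9)
    stop_smbg("kappa must lie in [-1, 1]")
  if (kappa < 0) "no agreement"
  else if (kappa <= 0.20) "not significant"
  else if (kappa <= 0.40) "medium"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Read a panel rating table from CSV
#'
#' Expected columns: `item_id`, `reference`, `rater_id`, `rating`, with
#' `present`/`absent` tokens (0/1 accepted). Returns the reference vector
#' and a raters-by-items rating matrix with `NA` for missing ratings.
#'
#' @param path CSV file.
#' @return object of class `rating_table`: `items`, `reference` (logical,
#'   named by item), `ratings` (logical matrix, raters x items).
#' @export
read_rating_table <- function(path) {
  if (!file.exists(path)) stop_smbg("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("item_id", "reference", "rater_id", "rating")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_smbg("missing mandatory column(s): ",
              paste(missing_cols, collapse = ", "))
  items <- unique(raw$item_id)
  raters <- unique(raw$rater_id)
  ref <- vapply(items, function(it) {
    v <- unique(raw$reference[raw$item_id == it])
    if (length(v) != 1) stop_smbg("conflicting reference rating for item ", it)
    as_binary_rating(v)
  }, logical(1))
  m <- matrix(NA, nrow = length(raters), ncol = length(items),
              dimnames = list(raters, items))
  for (i in seq_len(nrow(raw)))
    m[raw$rater_id[i], raw$item_id[i]] <- as_binary_rating(raw$rating[i])
  rating_table(ref, m)
}

#' Construct a rating table
#'
#' @param reference named logical vector of reference (automated-tool)
#'   ratings per item.
#' @param ratings logical matrix, raters x items; `NA` for missing.
#' @return A `rating_table`.
#' @export
rating_table <- function(reference, ratings) {
  stopifnot(is.matrix(ratings), length(reference) == ncol(ratings),
            length(reference) >= 1, nrow(ratings) >= 1)
  structure(list(items = colnames(ratings) %||% as.character(seq_along(reference)),
                 reference = reference, ratings = ratings),
            class = "rating_table")
}

#' Agreement of every rater against the reference
#'
#' @param table a [rating_table()].
#' @return data.frame with one row per rater: `rater`, `fraction`, `n`,
#'   `kappa`, `interpretation`.
#' @export
rater_agreement <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  rows <- lapply(rownames(table$ratings), function(r) {
    pa <- percent_agreement(table$reference, table$ratings[r, ])
    kp <- kappa_from_ratings(table$reference, table$ratings[r, ])
    data.frame(rater = r, fraction = pa$fraction, n = pa$n,
               kappa = kp$kappa, interpretation = kp$interpretation %||% NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
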