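---
title: "Rule-based glycemic pattern detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based glycemic pattern detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smbgpatterns)
```

## The problem and the model

Self-monitored blood glucose (SMBG) pattern management screens a patient's
device download — glucose readings with optional pre-/post-prandial marks,
insulin boluses with a calculator-use flag, carbohydrate records, and pump
events — for a fixed battery of clinically defined flags, so that a
clinician reviews a red/green dashboard instead of raw lists. The engine
here is deliberately *not* a statistical model: each pattern is a
deterministic rule with explicit thresholds, because the clinical value of
such dashboards lies in their auditability. Every flag carries the
evidence (counts, fractions, run locations) sufficient to recompute the
decision by hand.

Assumptions about the input data:

* timestamps are naive local wall-clock times at minute resolution, as
  meters record them; calendar days split at local midnight and no
  timezone or DST arithmetic is attempted;
* glucose is in mg/dL and plausible meter output lies in [10, 600];
  values outside that range are rejected as device errors;
* the analysis window is a closed interval of whole days, typically 14 or
  28; all per-day shares are computed over *every* window day, including
  days with no records (a day without readings is a day with fewer than
  four readings — that is the point of the adherence rules).

## Rule semantics and comparator conventions

All thresholds are strict (">" / "<") exactly as the rule definitions are
written: a standard deviation of exactly 70 mg/dL, an overcorrection
fraction of exactly 25%, or a reading of exactly 70 mg/dL never fires a
flag. The one deliberate exception is the blood-glucose-test-frequency
rule, whose day share is phrased "on 80% of days" without a comparator; we
read it as ≥ 80% (the flag describes *insufficient* testing, and a patient
deficient on exactly four days in five plainly qualifies). The flag's
`strict` switch is exposed in the configuration for users who disagree.

Events, not readings, are the unit for the hypo-/hyperglycemia counting
rules: successive qualifying readings closer than `merge_gap` (default 60
minutes) form one clinical episode, since a low reading rechecked twenty
minutes later is one hypoglycemia, not two. Setting `merge_gap = 0`
reproduces reading-level counting for sensitivity analyses. Events are
assigned to the calendar day of their start, which keeps "per day"
well defined for episodes spanning midnight.

Two rules in the battery needed interpretation where the printed
definitions are underspecified, and the choices are exposed as
configuration:

* **Hyperglycemia block threshold.** The battery's hyperglycemia heading
  appears with two different thresholds in different summaries of the same
  system (160 vs 100 mg/dL). 100 mg/dL is clinically implausible as a
  hyperglycemia bound — it sits inside every fasting target range — so 160
  is the default.
* **Insulin/carb record rule.** "<3 records per day" names no day share;
  we mirror the neighboring marking rule (">50% of days").

## Time blocks and prandial phase

The five blocks default to nocturnal 00:00–06:00, breakfast 06:00–11:00,
lunch 11:00–16:00, evening meal 16:00–21:00, bedtime 21:00–24:00. The
block names are standard; the clock boundaries are a package convention
(no published grid exists) and the scheme is fully configurable, with the
constraint that blocks tile the 24-hour day and a nocturnal block exists.

A reading's phase is its own mark when present. Unmarked readings are
inferred from carbohydrate records: *pre* if an intake follows within 30
minutes, *post* if one precedes by 60–120 minutes, else *none*; pre wins
when both hold, because a reading taken between a previous meal's
absorption and the next meal is clinically a pre-prandial check. The
time-block hyperglycemia rule then applies 150 mg/dL to pre-phase
readings, 180 to post-phase, and the block threshold (160) to phase-less
readings. The rolling "over 7 days" window is evaluated at every start day
in the analysis window — the rule anchors no particular week — and a
window shorter than 7 days degrades to the whole window.

## Pump-specific rules

Cartridge cycles are the intervals between successive `cartridge_change`
events; the delay of a cycle is `max(0, interval − expected)`, expected
interval defaulting to 7 days. The delay-hyperglycemia rule examines
readings strictly inside the delay period (from the expected change time
to the actual change). Two windows have no published value and default as
follows: hypoglycemia counts as *associated with* a cartridge change when
an event starts within 6 hours after the change (a pragmatic bound for
set/site problems manifesting quickly), and carbohydrate intake within 60
minutes after a hypoglycemic reading counts as rescue carbs and is
excluded from the missed-bolus rule. Both are configuration keys.

Seven rules apply to pump (CSII) therapy only; for MDI logs they are
reported `applicable = FALSE` and never present. The two bolus-calculator
adherence rules can be re-enabled for MDI patients who use calculator
devices via `mdi_bolus_patterns = TRUE`, since the restriction reflects
the validation study's case mix rather than the rules' logic.

Patterns that cannot be evaluated — no boluses, fewer than two readings,
fewer than two cartridge changes, an empty overcorrection denominator —
render green with an explicit `reason`, never silently.

## Risk indices

The variability block uses the canonical symmetrizing transform of
glucose, f(bg) = 1.509·((ln bg)^1.084 − 5.381) with bg in mg/dL and
squared risk r = 10·f². LBGI is the mean of r over readings with f < 0,
HBGI over f > 0. The transform's root (the risk-neutral glucose) is
≈112.5 mg/dL; the package's tests locate it by root-finding rather than
hard-coding it. Category bands default to the published convention —
LBGI: minimal < 1.1, low 1.1–2.5, moderate 2.5–5, high ≥ 5; HBGI: low
< 4.5, moderate 4.5–9, high ≥ 9 — with lower edges inclusive, and the
pattern fires on moderate-or-high. The standard deviation is the sample
(n−1) SD over the whole window, matching the single whole-window SD
threshold; %CV is 100·SD/mean.

## Agreement statistics

Cohen's κ is computed from the 2×2 table of paired present/absent ratings:
p_o the diagonal mass, p_e from the row/column marginals,
κ = (p_o − p_e)/(1 − p_e). The 95% CI uses the Fleiss–Cohen large-sample
standard error with a normal interval truncated to [−1, 1]; the source
evaluation reports CIs without naming a method, and this is the standard
asymptotic choice. When a marginal is degenerate (p_e = 1), κ is reported
as undefined with p_o attached rather than forced to a number. Pooling
across cases is the evaluation-weighted mean Σfᵢnᵢ/Σnᵢ, which equals
percent agreement on the concatenated evaluations (a property the tests
verify). Statistics are unadjusted: the original evaluation additionally
adjusted for case-sequence and country with an unspecified model, which is
out of scope here and documented as such. Missing ratings are dropped
pairwise.

## The synthetic generator

`generate_baseline_log()` emulates a well-controlled patient over 28 days:
three meals with jittered times, a pre and a post reading per meal
(marked), an occasional unmarked bedtime reading (6–7 readings/day),
carbohydrate and calculator-assisted bolus records at each meal, weekly
cartridge changes, and sparse stop/resume pairs. Glucose is drawn
lognormal (right-skewed, as SMBG marginals are) with mean 120 mg/dL and
15% CV, clipped to 85–160 mg/dL. Pre-prandial draws are clipped to
85–150 mg/dL: pre-prandial glucose runs lower physiologically, and a
clip at 160 would let a pre-marked reading exceed the 150 mg/dL
pre-prandial time-block threshold, making the "conservative" baseline
not actually pattern-free. Under these defaults no rule can fire
structurally (no reading crosses an event threshold, every bolus has a
prior check, every day is fully recorded), which is what makes the
baseline a negative control rather than a lucky draw.

Injectors are constructive, not rejection-sampled: each inserts or edits
records that satisfy its target rule by a clear margin (e.g. two 55 mg/dL
readings per day in different blocks on three consecutive days for the
hypoglycemic trend), so the injection→detection round trip is
deterministic per seed. Some couplings are physically unavoidable and are
documented as a whitelist in the test suite: pushing the whole-window SD
above 70 mg/dL requires values outside the 70–160 band, so the SD injector
also raises HBGI and populates hyperglycemia time blocks; a sustained
hyperglycemic trend (21 events in a week across 5 blocks) necessarily
exceeds the >3-per-block count by pigeonhole. Seeding derives one sub-seed
per record stream from the global seed, so streams are mutually
independent and reproducible.

What the generator does **not** emulate: continuous (CGM) traces,
physiological glucose–insulin dynamics, basal-rate programs, meal-size/
bolus correlation beyond a fixed carb ratio, missing-at-random logging
gaps, or device clock drift. Passing round-trip tests therefore
demonstrate that the detectors implement their rules faithfully on
schedule-realistic data — not that the rules themselves have any
particular sensitivity or specificity on real downloads, which is a
clinical validation question, not a software one.

## Problem sizes and numerical choices

The test suite exercises the full round trip on 19 patterns × 20 seeds
plus 50 baseline seeds (28-day logs, ≈180 readings each), compares κ to a
brute-force oracle on 1,000 random 2×2 tables at 10⁻¹² tolerance, and runs
200-series property checks for risk-index monotonicity; these sizes give
tight behavioral coverage while keeping a full run around a minute.
Boundary tests construct exact-threshold fixtures arithmetically (e.g. a
five-reading series with deviations ±70 whose sample SD is exactly 70) to
avoid floating-point ambiguity at strict comparisons. Duplicate reading
timestamps keep the first record with a warning; pump stop/resume
sequences that do not alternate warn but are not rejected.

## Known limitations

* Three additional patterns advertised for the original platform were
  never publicly defined and are not implemented.
* The battery operates on SMBG snapshots; none of the rules are suitable
  for dense CGM traces without re-deriving event semantics.
* Per-case κ against a fixed single-item reference is degenerate by
  construction (one marginal constant); the package flags this rather
  than emulating any unspecified workaround.
* The CSV dialect is a package convention for interchange, not a vendor
  format.
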