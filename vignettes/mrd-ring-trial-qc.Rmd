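---
title: "Scoring inter-laboratory flow-MRD proficiency trials with mrdqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring inter-laboratory flow-MRD proficiency trials with mrdqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdqc)
```

## The problem

Flow-cytometric minimal residual disease (FCM-MRD) quantification assigns
children with acute lymphoblastic leukemia to treatment-risk groups, so a
multi-centre trial network must demonstrate that dozens of laboratories
produce interchangeable MRD values. Proficiency is assessed in two ways:
*send-arounds*, in which identical list-mode data files (or stabilized
samples) are analysed blindly by every centre, and *twinning maturation*,
in which a trainee laboratory processes a consecutive local case series
under review by an experienced partner until it earns the right to release
results unsupervised. `mrdqc` implements the scoring calculus of both,
together with the exact contingency-table statistics used to summarise
them, and a synthetic-data generator that makes every stage testable
without patient data.

## Scoring rules

**Positivity.** MRD positivity is an event-count rule: at least
`min_events` leukemic events among `denominator_events` nucleated events
(defaults 10 and 3×10⁵). The derived threshold is 100·10/3×10⁵ = 1/300 % of
nucleated cells. Reports conventionally print this truncated, not rounded,
to three decimals (0.003 %); `positivity_threshold_percent(rule,
truncate_digits = 3)` reproduces that view while all comparisons use the
exact fraction.

**Target votes.** The consensus ("target") value of a sample is a median —
over a fixed panel of matured reference laboratories for send-arounds, or
over all submitters for external QA rounds. Three conventions needed
fixing:

* *Negative reports enter the median as 0.* No other convention reproduces
  a negative target when most contributors report negative; it also makes
  the vote a total function of any mix of positive and negative reports.
* *Missing reports are excluded*, not zeroed — an unsubmitted result says
  nothing about the sample.
* The vote is *positive only when the median reaches the positivity
  threshold*; an even number of contributors takes the midpoint of the two
  central values.

Whether a laboratory's own submission should be excluded from the
all-submitters median when evaluating that laboratory is genuinely open;
`mrdqc` includes all submitters, which is simpler, symmetric across
laboratories, and negligible for the panel sizes involved (≥20
contributors). An external QA provider's internal "robust mean" summary is
a different statistic altogether and is deliberately not implemented: the
network's own evaluations are median-based.

**Concordance margin.** A reported value $x$ against a positive target $t$
is concordant when $t/3 \le x \le 3t$ — half a log10 in either direction.
The boundaries are *strict* in the outlier direction ("more than three
times, less than one-third"), so a report at exactly 3× is concordant.
Because quotients of decimal fractions are not exact in binary floating
point (`0.3/0.1 != 3`), the comparison carries a 10⁻⁹ relative guard; a
genuine outlier exceeds the margin by far more than that. A positive
report on a negative target is always a false positive regardless of
magnitude (the ratio to zero is undefined), and conversely for false
negatives. All four non-concordant categories count as "false assessments"
in every downstream rate.

**Flags.** Per laboratory, `false assessments / assessed reports` with
missing submissions excluded from the denominator (they are reported
separately as a completeness metric — a laboratory should not improve its
rate by not submitting). Flags are `pass` (≤10 %), `warning` (>10 %–≤25 %)
and `critical` (>25 %), strict at both boundaries.

## Exact tests

Group comparisons use exact conditional tests, implemented in the package
by full enumeration: for a 2×c table the first-row cell counts are
enumerated over the margin-constrained support, each table weighted by its
multivariate hypergeometric probability computed in log space from a cached
cumulative log-factorial table (accurate at totals of ~1700 where naive
products overflow). The two-sided p-value follows the *point-probability*
convention — the sum over tables no more likely than the observed one, with
a 1+10⁻⁷ relative guard on the comparison — which is the convention of
standard exact-test software. `fisher_2x2()` and `freeman_halton_2xc()`
share this kernel and agree to machine precision on 2×2 inputs; supports
too large to enumerate raise a capacity error rather than being silently
approximated.

One reconstruction issue deserves a plain statement. The multi-year
external-QA evaluation reports outlier counts of 11/487 versus 67/1192
between the two laboratory groups with a two-sided Fisher p of 0.0043.
That value is obtained when the counts are entered as the cells
(outliers, submitted totals) — i.e. the table [[11, 487], [67, 1192]]. The
statistically standard construction (outliers vs concordant,
[[11, 476], [67, 1125]]) gives p = 0.0021; both reject comfortably.
`group_outlier_summary()` exposes both as `table_style = "vs_submitted"`
and `"vs_concordant"` (the default), and the acceptance script uses the
construction that reproduces the published computation. Similarly, the
year-over-year send-around comparison tests the pass/warning/critical flag
counts (19, 4, 8) vs (24, 8, 0) as a 2×3 table; the enumeration reproduces
the published p = 0.005 directly.

## Maturation rules

The acceptance procedure for trainee laboratories states two non-identical
completion criteria: *(a)* no gross error in the most recent 12 cases of a
series of at least 25, and *(b)* three additional consecutive error-free
cases per gross error in the second half (case 14 onward). `mrdqc`
implements both (`rule_variant = "window"` / `"penalty"`), and defaults to
their conjunction, which satisfies either reading. Choices made where the
text is open:

* "The most recent half (i.e., 12 patients)" is fixed at 12 cases even for
  extended series, not ceil(n/2) — the parenthetical quantifies the rule.
* First-half errors (cases 1–13) are counted in the series statistics but
  never delay maturation; the rules gate only on the second half, whose
  purpose is to prove that the intensive first-half training succeeded.
* An error on an extension case (>25) is treated exactly like a second-half
  error.
* B- and T-lineage series are tracked independently.

Under the `window` variant the state machine admits a closed form —
starting from 25, each error at or before the provisional completion case
pushes it to `error + 12` — which the tests verify against replay over 10⁴
random error patterns. Published per-laboratory series lengths (median 28,
range 25–57) are not recomputable without the underlying case logs and are
used only as plausibility bounds for the generator.

## Risk groups

Day-15 blast percentages classify patients as FLR (≤0.1 %), FMR, or FHR
(≥10 %), with no rounding before comparison. For comparing risk-group
distributions across centres the package uses a count-based homogeneity
test — exact (conditional r×3) for totals up to 200 patients, chi-square
above — rather than an ANOVA on per-centre fractions: the natural input is
the per-centre count table, the test is exact where counts are small, and
no per-centre fractions are published to reproduce anyway. This is a
deliberate substitution, recorded in the output's `method` field.

## The generative model

No raw per-laboratory reporting data are deposited for networks of this
kind, so the generator is calibrated to bracket published aggregate rates,
and its closed forms are the oracles the test suite checks against.

* **True MRD.** A sample is truly negative with probability `neg_fraction`
  (default 0.52, matching roughly half-negative QA panels), otherwise
  log-uniform on 0.004–18.16 % — the span of positive levels in such
  panels. Regeneration levels are Beta(2, 2): post-induction marrows
  typically show substantial but variable regeneration.
* **Reporting error.** A positive sample with true level $m$ is reported as
  $m\,e^{\sigma Z}$, $Z \sim N(0,1)$ — multiplicative log-normal error, the
  standard model for cytometric quantification across laboratories. The
  probability of leaving the ×3 margin is $2(1-\Phi(\ln 3/\sigma))$
  (`expected_discordance()`); the default σ = 0.55 puts it at 4.6 %, the
  overall outlier level of the multi-year QA evaluation.
* **False positives.** A truly negative sample is reported positive with
  probability `fp_base · (0.5 + regeneration)`; the default
  `fp_base = 0.19` reproduces specificity near 81 %. Magnitudes are
  log-uniform between the positivity threshold and 0.5 % — hematogone-scale
  artifacts, since regenerating B-cell precursors are the dominant cause of
  false-positive calls.
* **False negatives.** Misses follow a logistic curve in log-distance from
  the detection limit: probability ½ at the threshold, vanishing for
  clearly positive samples — consistent with sensitivity of ~99 % when most
  positives sit well above threshold.
* **Learning curve.** Gross-error probability of maturation case $k$ is
  $e_\infty + (e_0-e_\infty)e^{-k/\tau}$ with defaults (0.147, 0.093, 8)
  bracketing the published early-vs-late failure contrast (14.7 % vs
  9.3 %).
* **Determinism.** One seed drives a dataset; per-laboratory substreams are
  derived by a stable string hash of the laboratory id, so adding a
  laboratory never reshuffles the others' reports, and identical seeds
  produce byte-identical serialized bundles.

What the generator does *not* emulate: event-level cytometry (gating,
compensation, phenotype drift), correlated errors between laboratories
sharing instruments or training, sample-specific difficulty beyond the
regeneration covariate, and submission gaps. Passing tests therefore
demonstrate that the scoring calculus is implemented correctly and behaves
as the closed forms predict — not that real laboratories follow a
log-normal error law.

## Numerical and reporting choices

* Percent scale everywhere (1.0 means 1 %); values carried at full
  precision, with conventional half-up rounding applied only in reporting
  views (1 decimal for rates, whole percent for sensitivity / specificity /
  concordance) — `round_half_up()`, since R's `round()` rounds half to
  even.
* CSV outputs use fixed column order and 6-significant-digit formatting so
  identical inputs re-serialize byte-identically; every stored rate is
  accompanied by its integer numerator and denominator.
* Degenerate exact-test margins (an empty row or column) return p = 1 with
  a warning; malformed tables are errors.

## Problem sizes in the test suite

The suite verifies the exact tests exhaustively over all 2×2 tables with
total ≤30 (≈46 000 tables) against an independent hypergeometric oracle,
exhaustively over 2×3 tables with total ≤8 plus a seeded 300-table random
sweep up to total 30 against a brute-force enumeration oracle; the
maturation closed form over 10⁴ random patterns; and the generator's
discordance law at 10⁵ simulated reports. These sizes make the full suite
run in well under a minute while leaving the estimated Monte-Carlo error an
order of magnitude below every asserted tolerance.

## Limitations

The package scores *reported values*; it does not parse cytometry files or
adjudicate why a laboratory erred (cause labels on flagged samples are
reviewer annotations from a closed vocabulary, never inferred). Correlation
layouts that place negative results on a categorical axis are a display
concern and define no correlation coefficient, so none is computed. Exact
r×c tests for r > 2 beyond the risk-group homogeneity need are out of
scope, as are mid-p variants and odds-ratio confidence intervals.
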