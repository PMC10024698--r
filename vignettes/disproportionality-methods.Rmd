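---
title: "Disproportionality analysis with pvsignal: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntary reports of
suspected adverse drug events. They have no denominator — nobody knows how
many patients took a drug without an event being reported — so absolute
risks cannot be estimated. What *can* be estimated is disproportionality:
whether a drug–event pair is reported more often than one would expect if
the drug and the event were independent within the database. `pvsignal`
implements this screening workflow for flat, FAERS-like report extracts,
with a worked focus on a rare skeletal adverse event (periostitis, a
MedDRA preferred term) against a family of systemic triazole antifungals.

## The data model and its conventions

A database is a table of report versions. Counting is done on *cases*
(patients): `deduplicate_reports()` keeps, per `case_id`, the row with the
highest version, breaking ties by latest quarter and then largest
`report_id`. Both the deduplication rule and the exposure rule below are
deliberate conventions, exposed rather than hidden, because public
analyses rarely state them:

* A report is *exposed* to a drug if the canonical drug name appears in
  its drug list in any role — primary suspect, secondary suspect,
  concomitant or interacting. Restricting to suspect roles would change
  cell `a` for co-medicated cases.
* Drug names are canonicalized through a user-supplied synonym map
  (`synonym_map()`); unmapped strings fall back to lower-cased trimmed
  form, so lookup is total. Duplicate canonical names within one report
  collapse to one entry, keeping the highest-precedence role
  (PS > SS > C > I > unknown).
* Event matching is case-insensitive exact equality on the preferred-term
  string. No dictionary-hierarchy expansion is attempted; choosing the
  preferred term is an upstream decision.

## The 2×2 table and the statistics

For a drug D and event E, every analyzed report falls in exactly one cell:

|                | E        | all other events |
|----------------|----------|------------------|
| D              | a        | c                |
| all other drugs| b        | d                |

with `N = a + b + c + d`. `pvsignal` computes:

* chi-squared: `(ad − bc)² N / ((a+b)(c+d)(a+c)(b+d))`, by default
  without continuity correction; `correct = TRUE` applies the Yates
  correction, which several extraction tools report.
* `PRR = (a/(a+c)) / (b/(b+d))`, `ROR = (a/c)/(b/d)`.
* `RRR`, in two circulating conventions: the rate ratio
  `(a/(a+b))/(c/(c+d))` (the default, matching the formula most papers
  display) and the observed/expected form `aN/((a+b)(a+c))` used by
  BCPNN-style screening tools. The two agree when drug and event are both
  rare; they diverge enough to matter when reconstructing published rows
  (below).
* `IC = log2(RRR)`: the information-component point estimate.

Confidence intervals are Woolf-type log-normal intervals,
`exp(ln(point) ± z·SE)`, with `SE_ROR = sqrt(1/a + 1/b + 1/c + 1/d)`,
`SE_PRR = sqrt(1/a − 1/(a+c) + 1/b − 1/(b+d))` and
`SE_RRR = sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`. Published tables rarely
state their interval method; on reconstructed tables (below) the Woolf
intervals reproduce published PRR and ROR intervals to well under 1%,
which supports the assumption. The IC interval is by default the `log2`
image of the RRR interval; fully Bayesian BCPNN implementations publish
asymmetric credible intervals that this transform does not reproduce, so
IC intervals are reported but never treated as a reproduction target.

A *positive signal* follows the conventional Evans rule: more than 3
cases, chi-squared greater than 4 and PRR greater than 2
(`signal_criteria()`). The rule is also quoted with `>=` thresholds in the
literature, so `strictness = "greater_or_equal"` is available; the strict
form is the default. Undefined statistics (zero denominators) are
reported as `NA` per field and fail the rule conservatively; a `haldane`
option adds 0.5 to all cells of sparse tables on request, but is off by
default because published point estimates are generally uncorrected.

## Subgroups

`stratify()` partitions reports by sex (male, female) or by the age bins
`<18`, `18–65`, `>65`; the boundary ages 18 and 65 belong to the middle
bin, consistent with the bin labels. Reports with a missing stratum
variable are retained in the overall analysis but excluded from every
bin, so per-stratum denominators are the reports with a known stratum
value. Per-stratum cells always sum to the pooled cells of the matched
reports, which is tested as an invariant.

## Reconstructing tables from published rows

Published analyses print `n`, RRR, PRR and ROR but not `b`, `c`, `d`.
`reconstruct_table()` inverts the statistics: substituting
`d = ROR·b·c/a` into the PRR formula gives `c = a(PRR−1)/(ROR−PRR)`
independently of `b`, and the RRR relation then pins `b` (closed forms in
the source). Because printed values are rounded, each relation bounds its
unknown over the rounding window; integer candidates are enumerated and
verified by forward evaluation, so the solution set is exact. When two
target windows overlap (e.g. PRR ≈ ROR) the set is unbounded and the
solver raises a documented search-limit error rather than truncating
silently.

Two findings from applying this to the published overall
voriconazole–periostitis row (n = 143, RRR 583.6, PRR 1808.9, ROR 1831.7)
are worth recording, since the package's acceptance tests assert them:

1. Under the displayed rate-ratio RRR the three printed values admit *no*
   integer table at one printed decimal: the closed form confines
   `b = a(RRR−1)/(ROR−RRR)` to [66.74, 66.76]. Under the
   observed/expected RRR the system is consistent, with `b = 68`
   uniquely. The published numbers were evidently computed with the
   observed/expected convention even though the rate-ratio formula is the
   one displayed — which is why both conventions are first-class here.
2. On the reconstructed tables the uncorrected Pearson chi-squared is
   ≈ 83,271, about 0.7% above the published 82,689.0, while the
   continuity-corrected statistic covers the published value exactly.
   The published chi-squared is therefore the Yates-corrected statistic,
   and `chi_squared()` exposes `correct` so either can be computed.

## The synthetic generator

`generate_reports()` emulates the statistical structure that
disproportionality analysis relies on, with known ground truth. Per
report: demographics are drawn from configurable categorical
distributions; drug exposures are independent Bernoulli draws per drug;
each event is drawn with odds `baseline_odds × theta^(exposed)` for every
configured signal; a configurable fraction of cases emits a superseded
earlier version. Signals act multiplicatively on the reporting *odds*, so
`theta` equals the asymptotic reporting odds ratio exactly — this is what
makes parameter recovery a sharp test. The at-least-one-drug and
at-least-one-reaction constraints are enforced by redrawing whole rows;
because the redraw condition is independent of exposure, it leaves the
odds ratio for any single-signal pair untouched. All draws come from one
seeded Mersenne-Twister stream in a fixed, documented order, so a config
and seed identify a database exactly.

Default conditions (chosen once, as plausible for a large spontaneous
database): 50,000 cases; triazole exposure probabilities between 2×10⁻⁴
and 8×10⁻³ with a dozen common background co-medications; a designated
rare event at baseline reporting probability 10⁻⁴ among ten common
background reactions; one injected signal (voriconazole–periostitis,
θ = 20); sex mix 48/41/11% male/female/unknown; age mix 5/60/25% across
the three bins with 10% missing; 60% US reports; 5% duplicate-version
rate.

What the generator does *not* emulate: reporting-volume time trends,
co-prescription correlation between drugs, event co-occurrence beyond
independence, and notoriety effects. Passing tests therefore demonstrate
that the statistical machinery is correct under the model's assumptions,
not that real FAERS extracts satisfy those assumptions.

## Validation conditions and numerical choices

The stochastic test suite fixes its seeds and uses problem sizes chosen a
priori by power analysis so that each tolerance is a ≥3σ bound:

* Parameter recovery: at 10⁶ reports, exposure 0.2 and baseline event
  probability 5×10⁻³, `|ln(ROR̂) − ln(θ)| < 0.1` for θ ∈ {2, 10, 100}
  (Monte-Carlo SE of ln(ROR̂) ≤ 0.061 at θ = 2).
* Interval calibration: Woolf 95% coverage of θ = 5 across 500 seeded
  replicates of 50,000 reports lies in [93%, 97%].
* Specificity: across 1,000 null drug–event pairs (40 drugs × 25 events,
  no signals) the Evans-rule positive rate stays below 5%, consistent
  with the χ² > 4 component's α ≈ 0.046 bound.
* Oracle equivalence: chi-squared, RRR, PRR, ROR and IC agree with
  independent direct evaluation on 10,000 random tables, and chi-squared
  additionally against `stats::chisq.test(correct = FALSE)`.

Display rounding is half away from zero (`round_half_up()`), matching how
published tables are printed; all computation is done unrounded.

## Limitations

Disproportionality is a hypothesis-generating screen, not a causal
estimate: reporting odds ratios inherit every reporting bias of the
database. The package deliberately excludes full Bayesian BCPNN/EBGM
posterior estimation, multiple-comparison control across pairs, dictionary
hierarchy navigation, and ETL of raw quarterly FAERS files; its inputs
are already-cleaned flat extracts or its own synthetic databases.
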