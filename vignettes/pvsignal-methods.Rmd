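---
title: "Disproportionality-based signal detection with pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality-based signal detection with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems (FAERS, VigiBase, national systems
such as Korea's KAERS) collect individual case safety reports (ICSRs):
one report names a patient, one or more drugs, and one or more adverse-event
preferred terms (PTs). Because there is no denominator of exposed patients,
safety surveillance on such data asks a *relative reporting* question: is
event *y* reported with drug *X* more often than the rest of the database
would predict? pvsignal implements that pipeline end to end — inclusion
filtering, drug–event pair construction, disproportionality statistics,
signal calls, label-expectedness classification, covariate-adjusted reporting
odds ratios, and descriptive summaries — together with a seeded synthetic
ICSR generator used to validate every stage against known ground truth.

## Inclusion filtering

`apply_inclusion_filters()` encodes the inclusion rules typical of national
database analyses:

* WHO-UMC causality in {certain, probable, possible} (configurable);
* initial reports only (follow-ups dropped);
* complete records: non-missing sex and age, at least one ATC-coded drug
  entry and at least one coded event after dropping entries without codes;
* at least one *suspected* drug.

The order in which a failing report is attributed to a rule is fixed and
documented — missing field, then non-initial, then causality, then
no-suspected-drug — so the exclusion log reconciles exactly
(`n_in − n_out = Σ removals`). Missing event codes are treated per event: an
uncoded PT is dropped from its report and only a report left with *no*
coded event is excluded. This preserves partially coded reports, which is
the behaviour the pair-level analysis needs. A report with missing age is
excluded entirely (not merely from demographic tables); that is the stricter
of the two readings of "excluded from the analysis" and is applied
uniformly. Filtering is idempotent, and fully permissive criteria are the
identity.

## Pairs and the 2×2 screening table

`build_pairs()` explodes each retained report into (suspected drug, distinct
event) combinations — the standard one-to-one drug/AE correspondence.
Repeated PT codes within a report are de-duplicated so they cannot
double-count. For a target drug/event, `build_contingency()` tallies

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

with the comparator being *all other drugs in the supplied pair set*; no
external background is fetched. (When the pair set is restricted to two
drugs, the same function expresses a head-to-head comparison instead — both
readings of "comparator" are therefore available.) Age groups use the
reproductive-period cut-points `<20`, `20–39`, `40–59`, `≥60`; the last
group is taken inclusive of 60, the conventional reading of an "older than
60" grouping.

## Disproportionality statistics

For each table the package computes:

* **PRR** `= (a/(a+b)) / (c/(c+d))`, 95% CI
  `exp(ln PRR ± 1.96·SE)`, `SE = √(1/a − 1/(a+b) + 1/c − 1/(c+d))`;
* **ROR** `= ad/bc`, 95% CI with `SE = √(1/a + 1/b + 1/c + 1/d)`;
* **χ²**: Pearson on the 2×2, Yates-corrected by default (`|O−E|` shrunk by
  0.5, floored at 0). The Yates variant is the classical companion of the
  PRR ≥ 2 criterion; the uncorrected statistic is available by flag and is
  the right choice for calibration studies (the null simulations below use
  it, since the correction is deliberately conservative);
* **IC** (BCPNN information component): point estimate
  `log2((a + s)/(E + s))` with `E = (a+b)(a+c)/n` and shrinkage
  pseudo-count `s = 0.5`, so sparse tables are pulled toward 0. The 95%
  interval is a Monte-Carlo credible interval: cell probabilities are drawn
  from a Dirichlet(cells + s) posterior, the IC is recomputed per draw, and
  empirical quantiles are taken. The pseudo-count, draw count, and credible
  level are exposed in `ic_prior()`, so the original Bate (1998)
  parameterization can be configured; the default is the
  observed-vs-expected shrinkage form stated above, and the credible (not a
  normal-approximation) bound is what the signal criterion tests.

Zero cells receive the Haldane–Anscombe +0.5 on all four cells — applied
only when a zero is present, and always flagged in the `corrected` column.
With correction disabled, `a = 0` yields PRR 0 with an undefined CI rather
than a silent number.

All Monte-Carlo output is seeded: `screen(..., seed = )` and
`compute_ic(..., seed = )` are bit-reproducible and restore the caller's RNG
state. The interval estimate carries a batch-means Monte-Carlo standard
error, and a warning is raised when the bound is unstable (SE > 0.05 log2
units) so an under-sampled screen cannot silently feed the signal criterion.

## Signal criteria and expectedness

`evaluate_criteria()` applies the triple criterion with defaults PRR ≥ 2,
ROR ≥ 2, χ² ≥ 4, case count ≥ 3, and IC lower bound > 0 — the
PRR/ROR/count thresholds are inclusive (≥), the IC bound strict (>),
mirroring how the criteria are conventionally stated. A signal requires all
three component criteria. Raising any threshold can only remove signals
(monotonicity is property-tested).

`classify_expectedness()` compares signal events with a per-jurisdiction
label reference: term matching is exact on canonicalized strings
(lower-case, whitespace-collapsed); no synonym or hierarchy expansion is
attempted because none is defined at PT level. The packaged label files
(`labels_kr_synthetic.json`, `labels_us_synthetic.json`) are synthetic
fixtures containing only the handful of terms needed by the worked example —
they are not authoritative label texts.

## Adjusted reporting odds ratios

`build_design()`/`fit_logistic()` implement the case/non-case design: the
unit is the *report* (not the pair), the outcome "report mentions the target
event", the exposure "report names the target drug among its suspected
drugs", with sex and categorical age group as covariates. Pair-level
modelling would pseudo-replicate multi-event reports, which is why the
report level is the standard choice for adjusted RORs; the package documents
this as its interpretation. Age enters as the four groups (reference =
youngest non-empty); empty covariate levels are dropped with a warning. The
fit is maximum-likelihood logistic regression via iteratively reweighted
least squares (tolerance 1e−12, ≤100 iterations) with Wald 95% CIs
`exp(β ± 1.96·SE)`. Separation and non-convergence are *reported*
(`converged = FALSE`, with the captured fitter diagnostics); no Firth or
exact correction is silently substituted.

## The synthetic generator and what it does (not) emulate

`synthetic_config()`/`generate_reports()` produce seeded ICSR datasets with:

* categorical event sampling with weight `baseline × λ(drug, event)` — λ is
  the generative analogue of the reporting-rate disproportionality the
  statistics estimate (λ ≡ 1 is exact independence);
* an odds-parameterized Bernoulli event mechanism
  (`bernoulli_events`) whose within-age-group exposure odds ratio is *exactly*
  the configured value — this gives the adjusted-OR module a sharp ground
  truth to recover;
* an exposure-side confounding knob (`drug_age_mult`) making drug choice
  age-dependent, so crude and conditional ORs separate by design;
* contamination rates planting records that must fail each inclusion rule,
  tagged `contaminant:<rule>` in a provenance column so tests can assert
  exactly which records were removed.

The generator emulates record *structure* and reporting-rate imbalance. It
does not emulate pharmacological plausibility, duplicate reporting, secular
reporting trends, term-coding noise, or within-report event correlation
beyond the mechanisms above — so a passing calibration says the statistics
behave correctly under the stated sampling model, not that real databases
satisfy that model.

`antivegf_fixture()` is the deterministic worked example: an anti-VEGF
(aflibercept/ranibizumab) database slice whose report-level category counts
are back-calculated from published percentages via
`count = round(pct × total / 100)`, each count verified to re-round to the
printed value under half-up rounding (e.g. 23/32 → 71.875 → 71.9). Pair-level
event frequencies in the fixture are invented, since no pair-level
denominators are published; consequently the fixture's detected signal list
is illustrative, while its report-level marginals are exact.

## Numerical and presentation choices

* Percentages print half-up at one decimal (`round_half_up()`); base R's
  round-half-to-even would turn 31.25 into 31.2 and break re-rounding
  checks. Rounding is presentation-only.
* The annual "rate of increase" is the simple year-over-year count ratio.
* Screening problem sizes used by the validation suite: 1000 random tables
  for oracle equivalence; a 50-drug × 50-event independence simulation of
  50,000 single-drug single-event reports (2500 tables, expected cell ≈ 20)
  for null calibration; λ = 8 injected into 20,000 reports for recovery; 100
  replicates of 2,500 confounded reports for adjusted-OR coverage. These
  sizes put every table comfortably in the asymptotic regime of the Wald
  intervals while keeping the default validation run fast.
* IC Monte-Carlo draws default to 100,000 per table for one-off estimates;
  large screens lower `n_mc` explicitly (the IC point estimate and all other
  statistics are unaffected by `n_mc`).

## Known limitations

* PT-level analysis only: no MedDRA/WHO-ART hierarchy roll-ups.
* No multi-item shrinkage (EBGM/MGPS), time-scan statistics, or duplicate
  detection.
* The WHO-UMC causality assessment is consumed as a recorded field, never
  re-derived.
* Label expectedness is as good as the supplied label file; the packaged
  files are demonstration fixtures.
* Published adjusted ORs from the original anti-VEGF analysis (e.g.
  endophthalmitis 6.96) are not reproduction targets: the underlying
  national database records are not public, and the fixture constrains
  report-level marginals only.
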