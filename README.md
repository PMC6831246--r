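# pvsignal

Signal detection for spontaneous adverse-event reporting data.

Spontaneous reporting systems (FAERS, VigiBase, national databases such as
Korea's KAERS) accumulate individual case safety reports — each naming a
patient, one or more drugs, and one or more adverse-event preferred terms
(PTs). With no denominator of exposed patients, safety surveillance asks a
relative question: *is event y reported with drug X disproportionately often
compared with the rest of the database?* pvsignal is for
pharmacoepidemiologists and pharmacovigilance analysts who want that
analysis as a reproducible, testable pipeline rather than a spreadsheet.

For each drug–event pair the package builds the 2×2 screening table
(a = drug & event, b = drug & other events, c = other drugs & event,
d = the rest) and computes

- **PRR** = (a/(a+b)) / (c/(c+d)), CI `exp(ln PRR ± 1.96·SE)`,
  SE = √(1/a − 1/(a+b) + 1/c − 1/(c+d))
- **ROR** = ad/bc, SE = √(1/a + 1/b + 1/c + 1/d)
- **χ²** — Pearson, Yates-corrected by default
- **IC** — the BCPNN information component log₂((a+0.5)/(E+0.5)) with
  E = (a+b)(a+c)/n, and a Dirichlet-posterior Monte-Carlo 95% credible
  interval

and calls a **signal** when PRR ≥ 2, ROR ≥ 2, χ² ≥ 4, a ≥ 3, and the IC
lower bound exceeds 0 (the triple criterion). Signals are classified
expected/unexpected against a drug-label reference, and sex/age-adjusted
reporting odds ratios are estimated by case/non-case logistic regression.
A seeded synthetic ICSR generator (with controllable disproportionality λ
and confounding) backs the validation suite.

## Worked example

The package ships a deterministic worked-example dataset,
`antivegf_fixture()`: a synthetic anti-VEGF (aflibercept `S01LA05`,
ranibizumab `S01LA04`) database slice whose report-level marginals are
back-calculated from published percentages, plus background comparator drugs
and seven planted records that each violate one inclusion rule.

```r
library(pvsignal)

kept <- apply_inclusion_filters(antivegf_fixture())
kept$log
#> ICSR inclusion filter: 502 in, 495 kept, 7 removed
#>   missing_field      4
#>   non_initial        1
#>   causality          1
#>   no_suspected_drug  1

pairs <- build_pairs(kept$reports)
tabs  <- build_all_contingency(pairs, min_a = 3)
res   <- evaluate_criteria(screen(tabs, prior = ic_prior(n_mc = 20000), seed = 42))
res   <- classify_expectedness(res, read_label_reference(
           system.file("extdata", "labels_kr_synthetic.json", package = "pvsignal")))
subset(res, is_signal & drug == "S01LA05",
       select = c(drug, event, n, prr, ror, chi2, ic_l, expectedness))
#>     drug              event  n   prr    ror  chi2  ic_l expectedness
#>  S01LA05     conjunctivitis  5  4.82   5.53  8.86 0.688   unexpected
#>  S01LA05    endophthalmitis 12 14.47  22.55 71.67 2.319     expected
#>  S01LA05  muscae volitantes  4  6.43   7.21  9.24 0.840     expected
#>  S01LA05 ocular haemorrhage  3 98.42 109.98 29.49 2.810     expected
```

Reading the columns: `n` is the co-report count (cell a), `prr`/`ror` the
disproportionality point estimates, `chi2` the Yates-corrected chi-square,
and `ic_l` the IC credible interval's lower bound — all four aflibercept
rows clear every threshold, so `is_signal` is true. Conjunctivitis is absent
from the packaged (synthetic) Korean label file, hence `unexpected`: the
kind of new-AE candidate this analysis exists to surface.

Adjusted reporting odds ratios for those signals:

```r
adjusted_screen(kept$reports, subset(res, is_signal & drug == "S01LA05",
                                     select = c(drug, event)))
#>     drug              event       or ci_l ci_u converged n_used
#>  S01LA05     conjunctivitis 4.41e+00 1.41 13.8      TRUE    495
#>  S01LA05    endophthalmitis 2.30e+01 8.31 63.9      TRUE    495
#>  S01LA05  muscae volitantes 6.51e+00 1.72 24.6      TRUE    495
#>  S01LA05 ocular haemorrhage 1.40e+13 0.00  Inf     FALSE    495
```

Each row is a report-level logistic fit of event on drug exposure adjusted
for sex and age group. Note the last row: with only 3 cases the fit
separates, and the package *reports* that (`converged = FALSE`) instead of
inventing a finite CI.

The whole chain — filter → pairs → tables → screen → signals → adjusted →
descriptives, with a reproducibility manifest — runs as one call,
`run_pipeline(list(input = "fixture", seed = 7), "out/")`, or from the
shell via the thin front-end `inst/cli/pvsignal.R` (subcommands `simulate`,
`fixture`, `filter`, `pairs`, `tables`, `screen`, `signals`, `adjust`,
`describe`, `run`).

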