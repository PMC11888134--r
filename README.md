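# pvror

Case/non-case disproportionality analysis for spontaneous adverse-event
report databases, with a synthetic Individual Case Safety Report (ICSR)
generator for end-to-end calibration.

## The problem

Pharmacovigilance databases (VigiBase, FAERS and their national analogues)
collect spontaneous reports of suspected adverse drug reactions. They have no
denominator of drug users, so risk cannot be estimated — but *reporting
disproportionality* can. In the case/non-case design, reports mentioning the
event of interest (here: hypertension, defined by a flat SMQ-style list of
reaction terms) are the **cases**; all other reports are the **non-cases**.
For each drug the reports are cross-classified into the 2×2 table

|            | case | non-case |
|------------|------|----------|
| exposed    | a    | b        |
| unexposed  | c    | d        |

and the **reporting odds ratio** is

    ROR = (a·d) / (b·c),   95% CI = exp( ln ROR ± 1.959964 · √(1/a + 1/b + 1/c + 1/d) )

(the Woolf log-normal interval; the Haldane–Anscombe +0.5 correction is
applied when a zero cell occurs alongside at least one exposed report, and
drugs with no exposed cases render `NA`). A **signal** is flagged when
ROR > 1 and the lower CI bound > 1, both strictly.

Because reporting odds are confounded by age, sex and co-medication, the
package also computes an **adjusted ROR**: the exponentiated exposure
coefficient of a logistic model of case status on exposure, age band
(reference 18–44), sex (reference female, unknown kept as its own level), a
concurrent-antihypertensive flag (C02 ATC codes) and a flag for drugs known
to induce hypertension. The logistic fit is an internal iteratively
reweighted least squares implementation with explicit convergence and
separation diagnostics.

Around this core the package provides the full analysis set of a
pharmacovigilance signal evaluation: suspect-only and
antidepressant-population (N06A) sensitivity analyses, a median-split
dose-effect analysis with an OLS trend test (suppressed when either stratum
has fewer than 5 exposed cases), and cohort descriptives (demographics,
seriousness, time to onset, positive dechallenge/rechallenge counts).

The intended users are pharmacoepidemiologists and pharmacovigilance
analysts who want a tested, reproducible implementation of this pipeline —
and, because real spontaneous-report databases are proprietary, a synthetic
ICSR generator with *planted* effects and confounding so every stage can be
validated against known ground truth.

## Worked example

```r
library(pvror)

cfg     <- vigibase_like_config(scale = 0.05, seed = 7)  # 50,000 reports
db      <- generate_database(cfg)
vocab   <- synthetic_vocabulary(cfg)
records <- build_analytic_dataset(db, vocab)
signal_table(records)
```

```
           drug   a     b   ror ci_low ci_high  aror signal
1   alaproclate   0     0    NA     NA      NA    NA     NA
2    citalopram 122  5429 1.226  1.010    1.49 1.154   TRUE
3  escitalopram 140  5223 1.506  1.254    1.81 1.429   TRUE
4   etoperidone   0     2    NA     NA      NA    NA     NA
5    fluoxetine 163  6157 1.500  1.263    1.78 1.413   TRUE
6   fluvoxamine  11   676 0.863  0.474    1.57 0.819  FALSE
7    paroxetine 127  4791 1.478  1.222    1.79 1.416   TRUE
8    sertraline 225  7931 1.683  1.444    1.96 1.591   TRUE
9     zimeldine   0    42    NA     NA      NA    NA     NA
10        class 551 23233 1.701  1.482    1.95 1.584   TRUE
```

Each row is one drug–event pair: `a`/`b` are exposed cases and non-cases,
`ror` the crude reporting odds ratio with its Woolf CI, `aror` the
covariate-adjusted estimate, and `signal` the two-bound rule on the crude
estimate. Drugs with no exposed case (here the two withdrawn/rare drugs and
zimeldine at this database size) render `NA`. The `class` row pools exposure
to any target drug, counting co-exposed reports once. The crude estimates
sit above the adjusted ones because the generator plants positive
confounding by design.

A single table is equally direct:

```r
compute_ror(20, 80, 100, 900)
#> ROR 2.25 (95% CI 1.32-3.83)
```

`run_analysis(db, vocab, out_dir = "out")` writes the full table set
(signal tables for the main and both sensitivity analyses, the dose-effect
table, cohort summary, time-to-onset and dechallenge/rechallenge tables,
each with a full-precision `.full.csv` companion) plus a run manifest. The
same pipeline is scriptable through `exec/pvror`
(`simulate` / `analyze` / `validate` subcommands).

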