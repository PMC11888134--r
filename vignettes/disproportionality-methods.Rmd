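---
title: "Methods: case/non-case disproportionality with planted-truth calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/non-case disproportionality with planted-truth calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvror)
```

## The design and its assumptions

Spontaneous-report databases have no user denominator, so `pvror` estimates
*reporting* disproportionality, not risk. In the case/non-case design every
adult report is classified once: a **case** if at least one reaction term
canonically matches the event term set (an SMQ-style flat list), a
**non-case** otherwise. Exposure to each target drug is classified by ATC
prefix match over the report's drug entries, by default regardless of the
entry's role (suspect, concomitant, interacting); the suspect-only
restriction is a sensitivity analysis, not the primary definition, because
concomitant coding practice varies across reporters and countries.

Assumptions worth making explicit:

* **Report-level analysis.** A report with several matching terms, or
  several entries of the same drug, counts once. Co-exposure to two target
  drugs contributes to both drugs' tables but only once to the pooled class
  row.
* **Adult restriction.** Reports with unknown age band are excluded from all
  analyses. The analysis bands are 18–44, 45–64, 65–74, 75+; a raw
  `age_years` column is binned at load time and under-18 values map to
  `unknown` (and are therefore dropped).
* **Unknown sex is retained** as its own adjustment level rather than
  dropped, so the crude and adjusted analyses always use the identical
  record set and their estimates are comparable.
* **Flat term matching.** Term comparison is exact string equality after
  trimming and case-folding — no MedDRA hierarchy traversal. The shipped
  `inst/extdata/vocabulary_synthetic.yaml` is a synthetic stand-in: licensed
  MedDRA content is not distributed, and the hypertension-inducing-drug list
  is an editable placeholder.

## Estimators and numerical choices

**Crude ROR.** `compute_ror` returns `(a d)/(b c)` with the Woolf
(log-normal) 95% interval, `z = 1.959964`. The Woolf interval is the
standard in pharmacovigilance disproportionality and is also exactly the
Wald interval of the saturated 2×2 logistic model, which gives the package a
sharp internal consistency check (see below). Degenerate tables follow a
fixed policy: with `a = 0` (no exposed case) or no exposed reports at all
the estimate is undefined and renders `"NA"`; with any other zero cell the
Haldane–Anscombe +0.5 correction is applied to all four cells before the
logs.

**Signal rule.** `ROR > 1` and lower bound `> 1`, both strict. Because the
interval is two-sided at 95%, the rule is one-sided at the 97.5% quantile:
under a true null its flag rate should be near 2.5%, which the test suite
verifies empirically over 400 simulated databases of 50,000 reports
(accepting 1–4.5%).

**Adjusted ROR.** The adjustment model is a main-effects logistic regression
of case status on the exposure indicator, age-band dummies (reference
18–44), sex dummies (reference female), the concurrent-antihypertensive flag
and the inducer flag — no interactions. Covariate flags are computed from
entries whose code does not match any target drug, so a target is never
counted in its own covariate. The fitter (`fit_logistic`) is an internal
IRLS implementation: start at zero coefficients, weights floored at 1e-12,
convergence when the largest absolute coefficient change is below 1e-8,
capped at 50 iterations, standard errors from the inverse observed
information. Separation is flagged when a fitted probability sits within
1e-10 of 0 or 1 while a coefficient exceeds 10 in absolute value; separated
or non-converged fits render `"NA"` downstream rather than reporting an
unstable number. Covariate columns that are constant in the data are dropped
before fitting, so in the fully degenerate case the model reduces exactly to
the crude 2×2 fit. `stats::glm` is used in the tests as an independent
oracle for this fitter, never as the implementation.

**Dose-effect.** Exposed records with a recorded daily dose (mg/day, assumed
already standardized; no defined-daily-dose conversion is attempted) are
split at the per-drug median, ties to the low stratum. With an even count
the median is the mean of the two central values — so a `[10, 30]` pair
splits at 20. Each stratum's 2×2 table reuses the unexposed `c`/`d` cells of
the main analysis, since stratification concerns only the exposed. The
analysis is evaluated only when both strata hold at least 5 exposed cases;
otherwise every stratum estimate and the trend p-value render `"NA"`. The
trend test is the two-sided OLS slope test of case status on the stratum
indicator; "linear regression" is genuinely under-determined as a
specification, and the OLS-on-indicator reading was chosen as the most
literal one (a logistic slope on log-dose was considered and rejected for
the primary output, as it answers a different question). Its type-I error is
checked empirically: across 200 dose-independent simulations the suite
requires the p < 0.05 rate to fall in 2–9%.

**Descriptives.** Time to onset is the earliest matching-reaction onset date
minus the drug's earliest start date, in whole days, only when both dates
exist and the difference is non-negative — negative values indicate data
errors and are excluded rather than clamped to zero, since clamping would
fabricate same-day onsets. Quartiles use the midpoint-interpolation
convention (`quantile` type 2); published IQRs generally cannot adjudicate
the convention, so it is documented rather than argued. Cohort percentages
are `100·count/denominator` with denominators following the standard table
structure (seriousness criteria over serious reports, everything else over
cases); rendered tables round half-up — not banker's rounding — to 1 decimal
for percentages and 2 for odds ratios, with full precision kept in a
`.full.csv` companion.

## What the synthetic generator emulates — and what it does not

`generate_database` draws, per report: covariates (age band, sex,
antihypertensive and inducer co-medication), per-drug exposures whose logit
is shifted by `exposure_confounding_log_or` times the centered covariate
score (this is what makes crude RORs biased while adjusted RORs recover the
planted effect), a logistic event indicator, one event term per case with an
exponential onset delay after the earliest target-drug start, log-normal
daily doses with configurable missingness, and Bernoulli
dechallenge/rechallenge outcomes for event reports. Random streams are split
per component and per drug, so adding a drug spec leaves all other draws
untouched, and the whole database is a pure function of the config.

`vigibase_like_config()` pins the generator to study-scale conditions: nine
target SRI drugs with exposure prevalences set to their published exposed
report counts per 10⁶ reports, planted per-drug log-ORs equal to the
published adjusted estimates (treating the adjusted value as the
confounder-free effect, with confounding of 0.4 on the logit scale layered
on top), and the baseline event logit calibrated so the implied case rate
among exposed adults is 2.2%. That calibration is deterministic: the implied
rate is computed by exact enumeration over covariate cells and drug-exposure
subsets and solved by `uniroot`, not simulated. The default `scale = 0.1`
(100,000 reports) keeps a full pipeline run under ten seconds while leaving
hundreds of exposed cases for the major drugs; rare drugs then land at zero
exposed reports, which exercises the `NA` paths the same way published
tables show them.

Deliberately **not** modeled: reporting-country structure, duplicate
reports, secular reporting trends, notoriety bias, within-report term
multiplicity, and realistic dose-indication coupling. Time to onset is
exponential because only medians and IQRs are contractually relevant, and a
one-parameter positive skewed distribution suffices; dose is log-normal so
median splits are well defined and ties are rare. Consequently, passing
calibration tests demonstrates that the *estimators* are correct and
unbiased under the planted model — it does not demonstrate robustness to the
data pathologies of real spontaneous-report extracts (duplicates,
notoriety-driven reporting, term coding drift), which no desk-scale
simulation can certify.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `exposure_confounding_log_or` | 0.4 | log-odds per unit covariate score | visible but realistic crude-vs-adjusted gap |
| `baseline_event_logit` | calibrated | log-odds | implied exposed case rate 2.2% |
| `p_dose_missing` | 0.8 | probability | dose fields in spontaneous reports are sparse |
| `p_onset_missing` | 0.9 | probability | matches the small "available information" counts typical of TTO tables |
| `tto_mean_days` | 10 | days | exponential mean giving few-day medians |
| `p_dechallenge_positive` / `p_rechallenge_positive` | 0.07 / 0.003 | probability | order of magnitude of published positive-challenge counts |
| `fit_logistic` `tol` / `max_iter` | 1e-8 / 50 | — | coefficient agreement with `glm` to 1e-6 after exponentiation |
| dose split | median, ties low | mg/day | "at or below the median" is the published stratification |

## Problem sizes used by the test suite

The statistical acceptance checks run at: 400 replicates × 50,000 reports
(null signal rate), 100 × 200,000 (CI coverage of a planted OR 1.5),
20 × 50,000 (confounding correction), 200 × 20,000 (dose-trend type-I
error), plus single databases of 100,000–500,000 reports for consistency and
calibration checks. These sizes were chosen so that Monte-Carlo noise is
small relative to the asserted tolerances (3-sigma bands throughout) while a
full suite run stays in the minutes range on one CPU.

## Known limitations

* Disproportionality is not risk: no incidence, no causality. The package
  deliberately implements no causality scoring and no Bayesian shrinkage
  estimators (IC, EBGM) — the ROR with the two-bound rule is the contract.
* No multiplicity correction across drugs (the run manifest records the
  number of tests performed so users can apply their own).
* Exact-string term matching will miss event reports coded under terms
  absent from the supplied list; the vocabulary is configurable precisely
  because of that.
* The adjusted ROR is a conditional odds ratio; with common events it would
  differ from the marginal one (non-collapsibility) even without
  confounding. At the ~2% event rates targeted here the difference is
  negligible, and the no-confounding test bounds it at 1% empirically.
* Duplicate reports are not detected or merged; the generator never creates
  them, so the pipeline's behavior under duplication is untested.
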