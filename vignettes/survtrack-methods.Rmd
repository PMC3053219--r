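---
title: "Methods: from routine follow-up forms to Kaplan-Meier reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from routine follow-up forms to Kaplan-Meier reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Oncology departments document patient follow-up as part of routine care:
at each visit a form records the initial diagnosis and therapy, the
current disease status and the date it was ascertained. When this
documentation is structured and complete, survival analyses — the core
quality and research instrument in oncology — can be produced directly
from the hospital information system instead of through redundant
re-entry into study databases. `survtrack` implements that pipeline:
parsing generic follow-up forms, harmonizing department-specific status
vocabularies into event indicators, estimating survival, and reporting
the data quality on which any interpretation of the curves depends.

```{r, message = FALSE}
library(survtrack)
```

## The form model and its dialect

A follow-up form carries a 13-attribute common core organized in five
item groups: identity (patient pseudonym, department), diagnosis
(date/text/classification), therapy (date/text/classification), study
participation, and follow-up (date, status, information source, entry
mode, entry timestamp). Documents are serialized in a documented subset
of CDISC ODM 1.3.1: the `MetaDataVersion` defines the item groups and
per-department code lists (each status label annotated with its OS and
EFS flags), and `ClinicalData` holds one `FormData` element per form.
Patient identifiers are treated as already pseudonymized; an optional
keyed hash is available at CSV export for an additional
pseudonymization pass.

Dates may be imprecise: clinicians often know only "October 2008" or
"2007". We store dates as ISO 8601 truncated strings (`2008-10`,
`2007`) so precision travels with the value, and resolve them by the
midpoint convention — month to the 15th, year to July 1. The midpoint
minimizes the maximum resolution error and is symmetric, so durations
are not systematically biased. An interval-censoring treatment of
imprecise dates would be statistically richer but is out of scope; the
midpoint is a documented convention, not an estimate.

## Harmonization

Status vocabularies differ by disease: haematology documents remission
stages of acute myeloid leukaemia, urology documents PSA relapse of
prostate cancer. For survival analysis only two binary indicators
matter, and every label maps unambiguously to them:

* **OS event** — the status constitutes a death (any cause);
* **EFS event** — the status constitutes a relapse/progression or a
  death. By construction every OS event is an EFS event; the
  `status_mapping` constructor rejects mappings violating this.

Each patient accumulates one form per visit. Analysis uses the *most
current* form: the latest resolved follow-up date, ties broken by entry
timestamp, then form id (a total order, so deduplication is
deterministic, idempotent and independent of row order). Observation
time runs from the patient's origin — the earliest therapy start date
by default, optionally the diagnosis date — to the current follow-up
date, in years of 365.25 days. The EFS clock instead stops at the
*earliest* form whose status is EFS-positive: event-free survival
measures time to first event, and relapses are typically recorded on
interim forms that a later "deceased" form supersedes.

Patients that cannot be analyzed — missing origin, missing current
status or date, or a follow-up date before the origin (a data error) —
are excluded and itemized in the `excluded` attribute; exclusion counts
feed the quality report. Negative durations are excluded rather than
clamped, deliberately: silently repaired data errors would be invisible
in quality reporting.

## The survival engine

`km_fit()` implements the product-limit estimator from first
principles: at each distinct observed time \(t_i\) with \(n_i\) at risk
and \(d_i\) events,
\[
\hat S(t) = \prod_{t_i \le t}\Bigl(1 - \frac{d_i}{n_i}\Bigr),
\qquad
\widehat{\mathrm{Var}}[\hat S(t)] = \hat S(t)^2 \sum_{t_i \le t}
\frac{d_i}{n_i(n_i-d_i)} .
\]
Conventions, all configurable or documented:

* **Ties** — events are processed before censorings at a tied time (the
  standard product-limit convention).
* **Confidence intervals** — built on the log scale by default
  (symmetric normal error on \(\log \hat S\), matching the common
  default of reference implementations), with `log-log` and `plain`
  alternatives; all clipped to \([0,1]\). At \(\hat S = 0\) the
  Greenwood accumulator is undefined and the interval collapses.
* **Median** — the smallest observed time with \(\hat S(t) \le 0.5\),
  reported as "not reached" when the curve never gets there.
* **Evaluation** — `survival_at()` is right-continuous with flat
  extension beyond the data; `numbers_at_risk()` counts observation
  times \(\ge t\).

`logrank_test()` compares groups via the hypergeometric model: expected
events \(e_{gj} = n_{gj} d_j / n_j\) at each event time, the
multivariate hypergeometric covariance, and the quadratic form over
\(g-1\) groups using a Moore-Penrose generalized inverse for numerical
safety (a group never at risk contributes nothing but keeps the nominal
degrees of freedom, with a warning). No continuity correction is
applied. The test statistic agrees with `survival::survdiff` to
\(10^{-8}\) on random cohorts; that package serves strictly as an
independent cross-check in the test suite, never as the implementation.

```{r}
fit <- km_fit(c(1, 2, 3, 4), c(1, 0, 1, 0))
summary(fit)
```

## Data-quality reporting

Survival curves from routine data are only interpretable together with
completeness figures. Three measures are implemented:

* **Item completeness** (`item_completeness()`): for the three items a
  Kaplan-Meier analysis needs — therapy start date, follow-up status,
  follow-up date — the fraction of cases with the item documented, per
  entry-mode stratum and in total, plus the joint all-three fraction.
  A "case" is a patient's current form: the wording "cases" is
  ambiguous in registry practice (patients vs forms), so the package
  fixes and documents the patient-level reading. Percentages are
  rounded half away from zero to one decimal.
* **Form completeness** (`form_completeness()`): the fraction of an
  eligible population with at least one form carrying survival
  information (both a follow-up date and a status).
* **Person-time completeness** (`clark_completeness()`): observed
  follow-up person-time as a fraction of potential person-time, where
  potential time ends at death (death closes follow-up) or at the study
  end. A last contact beyond the study end clamps that patient's
  potential time, with a warning.

## The synthetic cohort generator

No patient-level data are distributable, so the package ships a
generator whose defaults describe the cohort the pipeline is designed
for: 965 patients, roughly 90% urology / 10% haematology, origins
uniform over an accrual window from mid-1992 through 2009,
administrative censoring at 2010-05-31, a routine-documentation share
of 21.5%, and per-item missingness of 2.4% / 1.6% / 5.7% for therapy
date, status and follow-up date. Death and relapse are independent
exponentials with default hazards \(\ln 2 / 16.4 \approx 0.042\)/y and
\(\ln 2/7.7 - \ln 2/16.4 \approx 0.048\)/y, chosen once so that median
overall and event-free survival sit near 16.4 and 7.7 years. Death
terminates observation. Forms follow an annual visit schedule: the
final form (at death or last contact) is always present, each interim
annual form is retained with probability 0.05, and the visit at which a
relapse is first seen is always retained — emulating a registry where
historical interim documentation is thin but events are documented.
Imprecise dates (5% by default, two thirds month-, one third
year-precision) and item missingness are injected last.

What the generator deliberately does **not** emulate: PSA kinetics or
remission dynamics, realistic inter-visit gaps, informative censoring,
or department-specific hazards. Passing tests on simulated cohorts
therefore demonstrate the correctness of the pipeline's logic and
estimators under the stated stochastic model, not the clinical
plausibility of any particular curve.

`fixture_from_counts()` complements the simulator with deterministic
documents reconstructed from printed completeness counts: given \(n\)
cases, per-item missing counts and the number of fully complete cases,
it assigns item missingness by wrapping the assignments around the
first patients, which is feasible exactly when
\(\max_i m_i \le n - a \le \sum_i m_i\) (with \(a\) complete cases) and
puts the multiply-missing overlap on the lexicographically first
patients — deterministic and order-independent.

```{r}
doc <- fixture_from_counts(207, c(3, 0, 24), 180, "routine")
item_completeness(doc$forms)
```

Note one subtlety visible above: percentages are recomputed from their
own numerator and denominator (204/207 = 98.6%), which published tables
do not always do consistently.

## The reporting pipeline

`run_pipeline()` chains simulate/parse → harmonize → analyze → quality
→ report, writing curve tables and records as CSV, a PDF with one
Kaplan-Meier panel per endpoint (confidence band, numbers at risk,
log-rank annotation for grouped analyses) plus a data-quality page, and
a machine-readable JSON run summary. Progress is logged to `stderr`
with stage tags; counts are conserved (`patients = analyzed +
excluded`) and identical configuration plus seed reproduces the CSV
outputs byte for byte. Plot appearance is not pinned — tests assert the
structural content through the curve and risk tables, not pixels. A
thin command-line wrapper with `simulate`, `harmonize`, `analyze`,
`quality` and `report` subcommands ships in `inst/cli/survtrack.R`.

## Verification strategy and problem sizes

The test suite checks every estimator against an independent route:
hand-computed product-limit and Greenwood values on a four-observation
example; the empirical survivor function on censoring-free samples; the
closed-form exponential median (within 5% at \(n = 5000\), where the
Monte-Carlo standard error of the median estimate under the default
accrual/censoring design is about 2%); a hand hypergeometric log-rank
computation; log-rank type-I error over 1000 null simulations at 50 per
group (accepted in \([0.03, 0.07]\)) and approximate uniformity of null
p-values over 2000 replicates; and numerical agreement with the
reference `survival` implementation on random censored cohorts.
Completeness metrics are exercised on count-reconstructed fixtures at
the full study sizes (207/758/965 cases), which run in milliseconds.
These sizes keep the whole suite under half a minute on one CPU while
leaving all Monte-Carlo bands at least three standard errors wide.

## Known limitations

* Midpoint resolution of imprecise dates ignores interval censoring;
  month-level imprecision can move an event by up to ±15 days.
* The EFS first-event rule trusts interim forms; a relapse documented
  only in free text (not as a status) is invisible.
* Completeness is measured per patient-current-form; form-level
  completeness of interim documentation is not assessed.
* The log-rank test is unweighted; weighted families
  (Gehan-Breslow-Wilcoxon, Fleming-Harrington) are not implemented.
* `clark_completeness()` requires resolved origin and last-contact
  dates and therefore inherits the midpoint convention.
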