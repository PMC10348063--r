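---
title: "Methods: disproportionality signal detection on JADER-style report tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on JADER-style report tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jpvsignal)
```

## The analysis model

Spontaneous adverse-event databases are collections of case reports, not
cohorts: there is no population at risk, so incidence cannot be
estimated. What can be estimated is *reporting disproportionality* — how
strongly a target drug and a target event co-occur within the database
relative to independence. jpvsignal screens one drug against one or more
event categories using the two classical estimators on a case-level 2×2
table, and declares a signal only when both agree.

The counting unit throughout is the **case** (one demographics row). A
case falls in cell $N_{11}$ when the target drug appears among its
*suspected* drugs and any of its reactions carries a PT code in the
event set; repeated drug or reaction rows within a case never add to the
count. "Other drugs" is the complement — including cases that list no
suspected drug at all — which is what makes the grand total equal the
number of linked cases and the marginal arithmetic of the reported case
population internally consistent.

### Reporting odds ratio

$ROR = N_{11}N_{00} / (N_{10}N_{01})$ with the Woolf log-normal interval
$\exp(\ln ROR \pm 1.96\sqrt{1/N_{11}+1/N_{10}+1/N_{01}+1/N_{00}})$. The
estimate is undefined when any cell is zero. We deliberately report `NA`
in that case rather than silently correcting: in the renal analysis the
lupus-nephritis set has a zero joint cell and is reported with the IC
only. The Haldane–Anscombe correction (+0.5 to all four cells, flagged
on the result) is available behind `correction = TRUE` for users who
prefer a defined estimate.

### Information component

The BCPNN information component is the base-2 log of the ratio between
the joint reporting probability and the product of the margins,
estimated by posterior moments under Dirichlet pseudo-count priors:
marginal pseudo-counts $\alpha_1=\beta_1=1$ with totals $\alpha=\beta=2$,
joint pseudo-count $\gamma_{11}=1$, and the joint prior total set
data-dependently,

$$\gamma = \gamma_{11}\frac{(N+\alpha)(N+\beta)}
{(N_{1+}+\alpha_1)(N_{+1}+\beta_1)},$$

so that the prior expectation of the IC is exactly zero: with no data
the estimator sits at independence, and with sparse data it shrinks
toward it. The interval is the posterior mean ± **2** posterior standard
deviations, the convention of the original BCPNN literature. A
1.96-standard-deviation variant is available (`ic_interval = "z"`); the
two differ in the third decimal at these sample sizes, and the ±2 form
is the package default because it reproduces the published renal-event
bounds exactly at 2-decimal rounding. The priors keep every term
strictly positive, so the IC and its interval are defined even when
$N_{11}=0$ — which is exactly how a zero-count event set still gets an
IC row.

### Signal criterion

`detect_signal()` is the conjunction: lower 95% ROR bound > 1 **and**
lower 95% IC bound > 0. An undefined ROR can never satisfy the
criterion. No multiplicity adjustment is applied — the intended use is a
small number of pre-specified event sets, and the dual criterion is
itself a conservative conjunction; users screening many sets should
adjust externally.

## Ingest and cleaning

The flow order is fixed: (1) exclude cases missing sex or age, (2)
remove exact duplicate drug/reac rows, (3) keep suspected-role drug rows,
(4) link on the case id, dropping (and counting) orphan rows whose case
id has no demographics. Duplicate means *identical on every field*;
rows differing only in a date are distinct reports. Removing exact
duplicates commutes with the role filter, so the chosen order (dedup,
then filter) is not a degree of freedom that can change results. Every
stage reports rows in / kept / removed, and `jpv_run()` writes this
audit to `flow.txt`, so a run against the real database can be checked
stage by stage against a published flow diagram.

Dates are `YYYYMMDD` tokens. Partial dates (`YYYYMM`, `YYYY`) are legal
in the source schema but unusable for day arithmetic, so they parse to
missing; any case whose anchor or onset date is missing lands in the
"Unknown" time-to-onset bin rather than being dropped.

## Time to onset

TTO is the whole-day difference between the anchor administration date
of the target drug and the *earliest* onset among the case's event-set
reactions. Two anchors are provided because the field genuinely uses
both: `first_dose` (the earliest administration date; the default) and
`most_recent_dose` (the latest). For single-dose cases they coincide;
the package surfaces the choice as a config option rather than silently
resolving it. A negative delay (onset before administration — date
errors do occur in spontaneous reports) is classified as unknown with a
counted warning, not an error. Bins are 0, 1, 2 days, 3–28 days
inclusive at both ends, strictly greater than 28 days, and Unknown; the
binning is an exhaustive, disjoint partition (property-tested over
0…1000 and missing). The outcome tally takes each case's outcome from
its earliest event-set reaction row, ties broken by row order.

## The synthetic generator

`simulate_reports()` draws, per case: sex and age from configurable
discrete distributions; target-drug exposure Bernoulli($p$); the target
event with odds $\omega$ for unexposed and $\omega \cdot OR$ for
exposed cases — so `true_odds_ratio` is exactly the population odds
ratio of the implied 2×2 table, and the realized counts are recorded in
`$truth` before missingness or duplicates are injected. Every case gets
one reaction row (a background PT when the target event is absent) and
one drug row; exposed cases carry a vaccination date, and their event
onset is the vaccination date plus a lag from a point-mass + geometric
mixture. Defaults mimic the observed database: exposure prevalence
3.1%, baseline event odds 2×10⁻⁴, odds ratio 6.5, the database's sex and
age frequencies, and an onset-lag mixture with most mass at 0–2 days
and a thin tail past 28 days (the published distribution reports
empirical bins, not a generative law, so the mixture shape is our
modelling choice and every weight is configurable).

What the generator does *not* emulate: reporting dynamics over calendar
time, multiple vaccine doses, correlated comorbidities, polypharmacy
(each case carries one drug), near-duplicate records (injected
duplicates are exact copies, matching the exact-equality dedup rule),
and name variants of the same drug. Passing tests on synthetic data
therefore validate the counting, estimation and bookkeeping machinery —
not robustness to the messiness of real pharmacovigilance data beyond
the specific missingness/duplication mechanisms modelled.

`fixture_from_margins()` is the deterministic counterpart: it lays out
disjoint case blocks so the recount reproduces requested 2×2 margins
exactly (optionally for several event sets at once), which is how the
published margins are turned into an end-to-end regression fixture.

## Numerical choices

- Reported estimates are rounded half *away from zero* to 2 decimals
  (`round_half_up()`), matching how the published tables round;
  all internal computation is double precision, and the CSV reports
  carry full-precision columns alongside the 2-dp display columns.
- Drug-name matching is exact after trimming and case-folding; no fuzzy
  matching, because silent fuzzy matches are unauditable.
- An empty case list makes the contingency table an error (undefined),
  not a zero table.
- Probability validation tolerances: sex/age probabilities must sum to
  1 within 1e-9.

## Test problem sizes

The suite exercises the generator at 10³–2×10⁵ cases, runs the
end-to-end margin fixture at the full 697,885-case size through file
round-trip and the pipeline, checks brute-force recount equivalence at
10⁴ cases, and measures 95% ROR interval coverage over 500 replicates of
50,000 cases at a design odds ratio of 5 (exposure 5%, baseline event
odds 0.002). The coverage replicates are drawn without missingness or
duplicates so the property isolates the interval estimator; the
exclusion machinery is tested separately with exact bookkeeping.

## Limitations

Crude 2×2 disproportionality only: no stratified or regression-adjusted
estimates (confounding by age, sex, comorbidity or co-medication is
untouched), no PRR/EBGM/full-MCMC BCPNN variants, no MedDRA hierarchy
or SMQ expansion (event sets are flat PT-code lists), and no parsing of
the real distribution archives beyond a configurable column-name
mapping. Disproportionality measures reporting behaviour, not risk; a
signal is a hypothesis to investigate, never an incidence estimate.
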