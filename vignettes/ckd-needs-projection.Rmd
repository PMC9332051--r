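---
title: "Projecting CKD secondary to type 2 diabetes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting CKD secondary to type 2 diabetes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdneeds)
```

## The problem

Diabetic nephropathy is the leading route into renal replacement therapy.
For a health system that does not cover dialysis and transplantation for
its uninsured population, the planning question is how many people will
occupy each stage of chronic kidney disease (CKD) in each coming year.
`ckdneeds` answers that question for a diabetic cohort with a discrete-time
multistate model: it seeds the cohort from survey-derived prevalence and
time-since-diagnosis summaries, accrues incident diabetes cases yearly, and
propagates everyone through an annual-cycle Markov chain over a 16-year
horizon (2016–2032 in the shipped default scenario).

## The progression model

Five health states, defined by the albuminuria marker, with a single
absorbing state:

```{r}
ckd_states()
```

Seven annual transitions are admissible: the forward chain
NORMO → MICRO → MACRO → ESRD, and a death transition from every living
state. Stage skipping within one year is impossible by construction. Each
transition carries an interval `[p_min, p_max]` of annual probabilities
(95% confidence bounds from a diabetes cohort study); `build_matrix()`
selects one bound per transition under a *rate policy* (`min`, `max`, or
`midpoint`) and sets each diagonal entry to the complement of its row, so
the matrix is exactly row-stochastic:

```{r}
build_matrix(load_transition_table(), policy = "max")
```

The annual rates are consumed directly as one-cycle transition
probabilities — no exponential hazard conversion — because that is what
annual probabilities from a yearly-cycle cohort study are. Competing risks
within a cycle are handled by direct row construction; outgoing sums stay
well below one (asserted at load time), so stay probabilities are always
positive.

### Glycemic control strata

Only 18.7% of treated patients met the glycemic-control target (HbA1c < 7)
in the baseline year. The cohort is therefore split once, at entry, into a
controlled stratum progressing under the `min` policy and an uncontrolled
stratum (81.3%) progressing under the `max` policy — the stated rationale
for using the highest rates being precisely to reflect the care quality
experienced by uncontrolled patients. Both policies are configurable per
stratum in the scenario; `midpoint` is offered as a cheap, clearly labelled
sensitivity extension beyond the two published bounds.

## Initializing prevalent patients

Prevalent patients have lived with diabetes for some years already. Per age
band, the shipped data give the median and interquartile range of years
since diagnosis. `fit_from_quantiles()` fits a two-parameter gamma — chosen
for positive support and right skew, which the published IQRs clearly show —
with the median matched *exactly* (the scale is solved from the shape for
every candidate) and the quartiles matched in least squares over the shape.
The achieved quartiles are reported back in the fit object: strongly
asymmetric targets (one band has IQR [2, 16] around median 9) are not
exactly representable by any gamma with a pinned median, and the fit makes
that visible rather than hiding it.

When record-level durations exist — for example from the synthetic survey
generator — `fit_kde()` estimates a weighted Gaussian kernel density
instead, reflected at zero so no mass lies below zero, with Silverman's
rule on the weighted sample and a bandwidth floor of 0.1 years to keep tied
samples from collapsing to a spike. The kernel, bandwidth rule and
weighting scheme are declared choices of this package, not inherited ones.

A patient diagnosed `d` years ago is assumed to have entered the chain at
normoalbuminuria at diagnosis and is advanced `floor(d)` completed annual
cycles (someone "5 years since diagnosis" has completed five cycles).
`initialize_from_distribution()` does this analytically: the fitted
duration law is discretized exactly into completed-year probabilities
`P(floor(D) = d)` up to a cap of 60 years (tail mass folded into the cap;
beyond 60 completed years essentially all mass is absorbed anyway), and
the post-diagnosis occupancy vectors are mixed with those weights.

### Pre-baseline deaths

Advancing patients from diagnosis necessarily generates death mass *before*
the assessment's start year. The default keeps that mass: the baseline
cohort is then interpreted as "everyone who developed diabetes and would
have been alive or dead by 2016", and the baseline year already shows a
death share — which is exactly how the published reference projection
behaves (its baseline column reports 12.8% deaths). The alternative
reading, conditioning on survival to baseline (survey respondents are alive
by construction), is implemented behind the `condition_on_survival`
scenario flag; it zeroes the baseline death share and lowers all later
death counts. The carry-forward default was adopted because it is the only
mode consistent with the reference table's own baseline arithmetic.

## Cohort accrual

Yearly cohort sizes can be supplied directly (the shipped default ships the
published 2016–2032 series, making the headline outputs reproducible
without external population projections) or derived with `cohort_series()`
from a total-population projection and an incidence schedule: the
population at risk in year *i* is the total adult population that year
minus the *baseline* prevalent count, new cases are the year's incidence
rate times the population at risk, and the cohort is the baseline plus
cumulative new cases. Incident entrants join at pure normoalbuminuria on
January 1 of their incidence year and transition with everyone else at
year end — the simplest half-open annual convention. How incident cases
distribute across age bands is irrelevant to the chain (entrants start at
the same state under band-independent rates), so no allocation is needed
beyond the entry state.

## Analytic engine, simulation, and the sample-size rule

The default engine is the analytic expectation: occupancy vectors
propagated by matrix multiplication, which is deterministic and exact for
expected counts. The Monte-Carlo engine (`simulate_cohort()`) draws each
individual's next state per year from its current matrix row (one uniform
per individual per year, in input order — documented so fixed seeds are
portable) and is used for what the analytic engine cannot give: variances
and occupancy quantiles, estimated across contiguous blocks of individuals
scaled to the full sample.

The simulation size follows a binomial error-bound rule: the smallest `n`
with `cohort × sqrt(p(1−p)/n)` below a tolerated error in persons at the
worst case `p = 0.5`, rounded up to the next 10,000. At the default bound
of 10,000 persons on the baseline cohort of 5,449,204 this gives
`required_n()` = 80,000 individuals. The test suite verifies that
Monte-Carlo means match the analytic expectation within sampling error at
exactly this rule — the model's own internal validation design.

## The synthetic-data generator

`generate_survey()` emulates the *statistical structure* the pipeline
assumes from a national health survey: individuals aged 20–79 allocated to
bands by weight mass, a diabetes flag at the band's prevalence, years since
diagnosis from the band's fitted duration law (capped at `age − 18`, since
type 2 diagnosis is modelled as an adult-onset event), positive weights
whose band totals are proportional to the published weight masses, and a
social-security flag. It deliberately does **not** emulate a complex survey
design — no strata, no clustering, no calibration weighting — so passing
tests say nothing about design-effect behaviour on real survey microdata.
Ages are uniform within bands because the model uses band membership only.
The default testing scale is 2×10⁵ records: tight enough moments for
3-standard-error checks, seconds of runtime. `generate_population()`
produces a geometric trajectory whose default annual rate compounds to 22%
total growth over 16 years, and `calibrate_incidence()` root-finds the
constant incidence rate under which the accrual accounting reproduces a
target cohort trajectory — the offered stand-in for incidence rates that
the original analysis took from external literature and did not print.

## Numerical choices

* Percentages are converted to fractions once, at load time; all internal
  arithmetic is on fractions.
* Gamma quantile fit: shape optimized on `log` scale over `[log 0.05,
  log 500]`, tolerance 1e-10; degenerate IQR width falls back to a point
  mass at the median with a warning.
* Completed-year discretization evaluates the CDF just below cell
  endpoints so point masses at integers land in their own cell.
* KDE quantiles are found by root-finding the closed-form CDF (tolerance
  1e-9); the bandwidth floor is 0.1 years.
* Row-stochasticity is exact by construction; conservation is asserted to
  1e-9 relative in tests.
* Reported counts are rounded to whole persons and shares to 0.01% only at
  write time.

## Known limitations

* Transition rates are age- and sex-invariant; no background
  non-cardiovascular mortality competes with the chain's single death
  state. Normoalbuminuric diabetic kidney disease (progression with normal
  albuminuria) is outside the state structure.
* The entry state at diagnosis is pure normoalbuminuria, although a small
  fraction of newly diagnosed patients already show renal involvement.
* Under the stated annual bounds, end-stage occupancy is capped near
  macroalbuminuria inflow times the expected time on renal replacement
  (at most about 0.03 × 1/0.14 of the macroalbuminuria count in
  equilibrium). The published reference series carries a baseline
  end-stage share above that ceiling, so this package's end-stage counts —
  and therefore its end-stage and death growth percentages — differ from
  the published ones while the stage shares and the micro/macro growth
  reproduce closely. The consistency tests and the acceptance script
  compute both sides of that comparison rather than reconciling them by
  hand.
* Undiagnosed diabetics are included in prevalence but duration summaries
  describe diagnosed cases; the model samples everyone from the same
  duration law and documents the conflation.

## Problem sizes

The shipped scenario is desk-scale: 5 states × 17 years × 6 age bands,
analytic propagation in milliseconds. The test suite simulates up to
2×10⁵ individuals over 16 annual cycles and generates surveys of 2×10⁵
records; the full suite runs in about a minute and a half on one core.
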