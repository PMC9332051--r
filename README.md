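# ckdneeds

Health-needs projection of chronic kidney disease (CKD) secondary to type 2
diabetes, for a population without social-security health coverage. The
package is aimed at health-services researchers who need yearly counts of
patients at each nephropathy stage — including the demand for renal
replacement therapy — under a "model of care stays as it is" scenario.

## The model

A five-state discrete-time Markov chain over the albuminuria-defined
stages

> normoalbuminuria (N) → microalbuminuria (Mi) → macroalbuminuria (Ma) →
> end-stage renal disease (E), with cardiovascular death (D) reachable
> from every living state and absorbing.

Seven transitions carry annual probability intervals `[p_min, p_max]`
(UKPDS-derived 95% bounds, e.g. N→Mi 1.9–2.2%/yr, E→D 14–24.4%/yr). A
*rate policy* picks one bound per transition; the cohort is split into a
glycemic-controlled stratum (18.7%, minimum rates) and an uncontrolled
stratum (81.3%, maximum rates). The transition matrix P has the selected
bounds off-diagonal and `P[s,s] = 1 − Σ_{t≠s} P[s,t]`, so rows are exactly
stochastic.

Prevalent patients enter having lived with diabetes for `D` years, where
`D` follows a gamma law fitted per age band to published median/IQR
summaries (median matched exactly, quartiles in least squares); their
entry mix is `e_N · P^floor(D)`, averaged analytically over the duration
law. Incident cases enter at pure N each year as the cohort-size
increment. Expected occupancy is propagated analytically; an
individual-level Monte-Carlo engine provides variances and quantiles at a
sample size chosen by a binomial error-bound rule.

## Worked example

```r
library(ckdneeds)

proj <- run_assessment(load_scenario())   # shipped default parameter set
glance(proj)
#>   start_year end_year n_years cohort_start cohort_end progressed_share_end
#> 1       2016     2032      17      5449204   10217299                 43.5

stage_distribution(proj, 2022)
#>   state       count share_pct
#> 1 NORMO    4570545.    64.7
#> 2 MICRO     893253.    12.6
#> 3 MACRO     167469.     2.37
#> 4 ESRD       13911.     0.197
#> 5 DEATH_CV 1418014.    20.1

growth_summary(proj, 2016, 2032)
#>   state    count_y0 count_y1 growth_pct
#> 1 MICRO     594409. 1356346.       128.
#> 2 MACRO      94221.  318194.       238.
#> 3 ESRD        7252.   29880.       312.
#> 4 DEATH_CV  833815. 2739686.       229.
```

Reading: by 2022, 35.3% of the accumulated diabetic cohort has progressed
beyond normoalbuminuria (12.6% early renal involvement, 2.4% overt
nephropathy, 0.2% on renal replacement, 20.1% dead of cardiovascular
causes), rising to 43.5% by 2032; microalbuminuria cases more than double
over the horizon. `autoplot(proj)` draws the stacked stage shares,
`plot_stage_distribution(proj, 2022)` one year's bar chart.

Other entry points: `simulate_cohort()` (Monte-Carlo engine with
`required_n()` for the sample-size rule), `generate_survey()` /
`generate_population()` / `calibrate_incidence()` (synthetic inputs),
`fit_from_quantiles()` / `fit_kde()` (duration models), `cohort_series()`
(incidence-driven cohort accrual). All user-facing functions take and
return tibbles, so results chain with the pipe; fitted objects have
`tidy()` / `glance()` methods.

See the methods vignette (`vignettes/ckd-needs-projection.Rmd`) for the
model's assumptions, numerical choices and limitations.

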