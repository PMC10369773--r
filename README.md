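# confidante

Standardized analysis of confidante-method abortion incidence surveys.

## The problem

Population-representative induced abortion data are hard to collect
directly in legally restrictive or stigmatizing settings. The
*confidante method* asks survey respondents to report abortion
experiences for their one or two closest reciprocal social ties
("confidantes"), yielding a surrogate sample of women whose experiences
are observed only through a third party. Applications of the method in
Côte d'Ivoire, Ethiopia, Ghana, Java, Nigeria, Rajasthan and Uganda have
differed in how they assessed and adjusted for the method's known biases,
which makes their published rates hard to compare.

This package implements one standardized pipeline for analysts working
with confidante data (or evaluating the method itself):

* **Data model** — read, validate and reshape wide-format survey files
  under a per-survey schema mapping (columns, category codes, calendar
  window), truncating the analytic sample to the first two confidantes.
* **Selection bias** — respondent-confidante homophily comparison
  (weighted relation shares + Pearson chi-square on the paired category
  distributions) and density-ratio post-stratification weights from a
  logistic membership model.
* **Barrier effects** — unadjusted prevalence ratios (uPRs) for
  reporting any vs no confidantes, from log-link Poisson regression with
  robust (sandwich) variance.
* **Reporting/recall bias** — telescoping diagnostic comparing the
  full reference-year rate with the annualized partial-year rate.
* **Transmission bias** — abortion visibility (disclosure) estimation
  and three adjustments to the certain-only rate.
* **Reporting** — a deterministic six-bias risk-of-bias checklist
  (study design, transmission, social desirability/recall, selection,
  barrier effects, popularity) rendered as markdown, JSON or delimited
  text.
* **Simulator** — a synthetic-survey generator with known truth, so
  every estimator is testable by parameter recovery.

## The estimator

For population *p* (respondents or pooled confidante reports) and year
*Y*, the one-year incidence rate is

    rate = 1000 * (weighted abortions dated to Y) / (weighted units in p)

Confidante abortions enter the base numerator only when the respondent
was *certain* they occurred. The three transmission-bias treatments are:

* **adj 1a** — additionally count all "less certain" abortions;
* **adj 1b** — count less-certain abortions only when the respondent
  could report the abortion method;
* **adj 2** — multiply the certain-only rate by the visibility
  correction factor `1 / p_any`, where `p_any` is the proportion of
  respondents who self-reported an abortion and had told at least one of
  their reported confidantes. Under symmetric disclosure this restores
  the abortions never visible to respondents, and `adj_2 =
  certain_only / p_any` holds exactly.

Confidence intervals come from a respondent-level (cluster) percentile
bootstrap that refits weights and correction factors inside each
resample.

## Worked example

```r
library(confidante)

params  <- simulation_params(n_respondents = 20000, true_rate_per_1000 = 40,
                             disclosure_prob = 0.5, seed = 42)
sim     <- simulate_survey(params)
records <- sim$records

certain <- base_rate(records, "confidante", year = 2017)
disc    <- disclosure_estimate(records)
adj2    <- adjust_2(certain, disc)
ci      <- bootstrap_ci(function(x) adjust_2(base_rate(x, "confidante", 2017),
                                             disclosure_estimate(x)),
                        records, B = 500, seed = 1)
print(certain)
print(disc)
print(set_bootstrap_ci(adj2, ci))
```

prints

```
confidante abortion incidence, 2017 [certain_only]: 18.4 per 1000
  numerator 350.00 / denominator 19001.00, weights: design
Abortion visibility among self-reporting respondents (weighted)
  disclosed to any confidante: 47.3% (n = 1259)
  confidante 1: 47.3%   confidante 2: 48.1%
  correction factor (1/p_any): 2.116
confidante abortion incidence, 2017 [adj_2]: 39.0 per 1000 (95% CI 34.4-44.0, bootstrap_percentile_B500)
  numerator 740.59 / denominator 19001.00, weights: design
  certain-only rate x correction factor 2.1160 (1/p_any, p_any = 0.4726)
```

Only half of the true events (40 per 1000) are visible to respondents at
a disclosure probability of 0.5, so the certain-only rate sits near 20;
the visibility correction recovers the truth within sampling error. The
same objects feed `build_assessment()` / `render_report()` for the
six-bias checklist, and `exec/confidante` exposes the pipeline as CLI
subcommands (`simulate`, `estimate`, `diagnose`, `report`, `all`).

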