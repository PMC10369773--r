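---
title: "Methods: standardized analysis of confidante-method surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized analysis of confidante-method surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confidante)
```

## The measurement model

A confidante survey observes, for each respondent: her own abortion
history (self-report), and for up to two of her closest reciprocal ties
a third-party abortion report with a certainty grade ("certain" /
"less certain"), an event date, optionally whether the abortion method
could be described, and — when the respondent herself reported an
abortion — whether she had told that confidante about it.

The analytic estimand is the one-year induced abortion incidence per
1000 women aged 15–49:

$$\widehat{r}_Y \;=\; 1000 \times
  \frac{\sum_i w_i \, \mathbf{1}\{\text{abortion of unit } i \text{ dated to } Y\}}
       {\sum_i w_i},$$

with units either respondents (design weights $w_i$) or pooled
confidante reports in positions 1–2 (design weight times an optional
post-stratification weight). The base confidante numerator admits only
"certain" reports. Surveys that elicit three or more confidantes are
truncated at ingest to positions 1 and 2 for cross-survey comparability;
the original count is retained because the zero/any-confidante contrast
drives the barrier-effect diagnostics.

The method rests on assumptions whose failures have names: *selection
bias* (confidantes do not resemble the respondent-represented
population), *barrier effects* (respondents reporting no confidantes
differ systematically from those reporting some), *reporting/recall
bias* (notably backward telescoping of event dates into the recent
window), *transmission bias* (abortions never disclosed to the
respondent are invisible), and *popularity bias* (frequently named women
differ systematically; no assessment method exists, and the checklist
therefore never grades it beyond "not assessed").

## Transmission-bias adjustments

Three treatments of the undercount are implemented, all operating on the
same denominator:

* **1a** counts every less-certain report in the numerator;
* **1b** counts a less-certain report only if the respondent could
  describe the abortion method (surveys that did not collect this field
  give an explicit "not available" result, never a silent zero);
* **2** multiplies the certain-only rate by $1/p_\text{any}$, where
  $p_\text{any}$ is the weighted proportion of respondents who
  self-reported an abortion, reported at least one confidante, and had
  told at least one of them.

By construction `certain_only <= adj_1b <= adj_1a`, and
`adj_2 = certain_only / p_any` is exact algebra. The factor doubles the
rate exactly when $p_\text{any} \le 1/2$. Adjustment 2 identifies the
truth only if the disclosure behaviour of self-reporting respondents
mirrors the visibility of confidantes' abortions to respondents
(symmetric disclosure); this is an assumption about the population, not
a property of the estimator.

## The synthetic-survey generator

Because the real microdata are restricted, the pipeline is tested by
parameter recovery on surveys whose truth is known. `simulate_survey()` draws, per respondent:
covariates from configurable margins (defaults loosely matching the
age/education/residence profiles of women 15–49 in the surveyed
contexts); per-year Bernoulli abortion events over the window from the
year before the reference year through the partially observed fieldwork
year, at an annual rate of `true_rate_per_1000` (default 40, mid-range
of published confidante-method settings) optionally modulated by
multiplicative covariate gradients; a confidante count in {0, 1, 2}
(default margins 0.35/0.35/0.30, giving a zero-confidante share and
mean count inside the published range), optionally dependent on one
covariate — the barrier-effect knob; confidante covariates copied from
the respondent with probability `homophily` (default 0.7) and otherwise
drawn from the margins; and calendar dates uniform within year (the
minimal assumption; nothing in the pipeline uses within-year timing
beyond the partial-year window).

**Disclosure is a woman-level, all-or-none trait.** With probability
`disclosure_prob` (default 0.5, close to the visibility levels observed
across published applications) a woman shares her abortion experience
with her confidante circle: a respondent who disclosed did so to *every*
reported confidante, and a confidante's abortion is visible to the
respondent exactly when the confidante is a discloser. This is a design
decision worth spelling out. The alternative — independent per-pair
disclosure coin flips — makes $p_\text{any} = 1-(1-d)^k$ for a
respondent with $k$ confidantes while the per-pair visibility of
confidante events stays $d$; the $1/p_\text{any}$ correction is then
inconsistent for any design that elicits two confidantes (it would
under-correct by up to a third at $d = 0.5$). The all-or-none trait
makes disclosure symmetric in exactly the sense adjustment 2 assumes:
$p_\text{any} = d$ regardless of the confidante-count distribution, so
the correction is consistent and the generator can serve as a recovery
oracle. Real populations presumably sit between the two regimes;
recovery results under the simulator say nothing about how far a real
population deviates from symmetry.

Visible events are reported "less certain" with probability
`less_certain_prob` (default 0.05: published applications report few
uncertain reports) and carry method information with probability
`method_info_prob` (0.5; `NA` emulates surveys without the item).
Backward telescoping moves a reference-year report into the fieldwork
year with probability `telescope_prob` (default 0 — misdating is a
scenario, not a baseline), with the reported month redrawn inside the
observed window. Respondent self-reports are subject to the same
misdating, and self-underreporting is deliberately *not* simulated:
social-desirability suppression of self-reports has no published
generative description, and simulating it would only rescale the
eligible-sample size for $p_\text{any}$. There is also no shared network
graph — confidantes are generated per respondent without reciprocity
constraints — so popularity bias cannot arise in synthetic data, which
matches its "never auto-assessed" status in the checklist.

Consequently, passing recovery tests demonstrates internal consistency
of the estimators under the stated assumptions; it cannot validate the
assumptions themselves against real populations.

## Selection-bias machinery

The homophily table compares, per characteristic, the weighted
respondent and confidante category distributions over pairs, reporting
relation shares (using exact confidante ages when a survey collected
them, age bands otherwise) and a Pearson chi-square computed on
weight-scaled counts rescaled to the nominal pair count. No
design-effect correction is applied — the published comparisons state
Pearson on weighted data and nothing more — so p-values on strongly
clustered designs are approximate. A survey generated under perfect
homophily makes the comparison degenerate (all pairs "same"); the table
flags this instead of failing.

Post-stratification weights come from a logistic membership model on the
stacked data: reference respondents (weighted by design weights, label
1) versus confidante pairs (label 0). A pair's weight is its fitted odds
of reference membership — a density-ratio weight — normalized to mean
one. The published description ("post-stratification weights created
using multiple logistic regression") names no formula; odds weighting is
the standard estimator matching that description. The default model uses
main effects; `saturated = TRUE` fits the full stratification cells, in
which case weighted confidante margins reproduce the reference margins
exactly (to 1e-9 in the tests, limited only by glm convergence, which is
run at epsilon 1e-10). The model is fit with a quasibinomial family
solely to accept non-integer survey weights; point estimates equal the
binomial fit. Design and post-stratification weights compose
multiplicatively, and that choice is recorded in each estimate's
`weights_applied` label. No weight trimming is performed: extreme
weights are surfaced via max/min and effective sample size
($(\sum w)^2 / \sum w^2$) rather than silently modified, and cells
populated on only one side are a refusal-to-extrapolate error.

## Barrier, telescoping and disclosure diagnostics

Barrier-effect uPRs come from single-covariate log-link Poisson
regression of the any-confidante indicator, with sandwich (HC0) robust
variance for the CIs — the standard prevalence-ratio construction for a
binary outcome, since the published tables print CIs without naming a
variance estimator. For one covariate the Poisson MLE equals the direct
ratio of weighted category prevalences; the tests exploit this as an
independent oracle (agreement to 1e-10, with glm run at epsilon 1e-12 so
solver tolerance does not mask disagreement). Reference categories are
fixed to the customary rows: youngest age band, never attended school,
urban, married/cohabiting, no family-planning use, no children.

The telescoping diagnostic contrasts the full reference-year rate with
the annualized partial-year rate (count scaled by 12/months observed,
same denominator). Its ratio feeds the recall-bias status with cutoffs
1.25 (moderate) and 1.5 (high) — configurable, since the published
assessments are qualitative.

Disclosure proportions are computed among respondents who self-reported
an abortion and reported at least one confidante; respondents whose
disclosure indicators are all missing are excluded as complete cases
(with the exclusion count reported) rather than counted as
non-disclosers. Proportions use respondent design weights by default;
the published figures do not state weighting, so the choice is recorded
in the result and reversible via `weighted = FALSE`. Zero eligible
respondents — the regime seen where well under 1% of respondents
self-report — raises an explicit "transmission adjustment 2
unavailable" error rather than an infinite factor.

## Bootstrap and problem sizes

Confidence intervals are percentile bootstrap over respondent-level
resamples (confidante reports are clustered within respondents), with
weights and correction factors recomputed inside each resample, and a
hard floor of B = 200. Estimator failures in a resample (e.g. an empty
cell) are tolerated up to 20% and reported; beyond that the interval is
refused. The test suite checks nominal coverage with 500 replicate
surveys of 5,000 respondents at B = 200 — sizes chosen to put the
Monte Carlo error of the coverage estimate near one percentage point —
and parameter recovery on a single survey of 50,000 respondents, where
the relative standard error of the corrected rate is under 4%.

## Degenerate inputs and numerical choices

Missingness is explicit end to end: ingest never imputes (hard
invariant violations reject the row with row-indexed diagnostics;
repairable inconsistencies are cleared and logged), and missing
confidantes are never imputed — respondents reporting none simply do
not contribute, which is why the barrier diagnostics exist. Rates are
computed unrounded and printed to one decimal. An empty denominator is
an error; a zero certain-only numerator yields rate 0 and stays 0 under
any weighting. The checklist's "implausibility floor" for the
study-design status defaults to 5 per 1000, an intentionally loose
bound on a plausible certain-only rate, and every checklist threshold
is configurable because the published statuses are qualitative
judgments.

## Known limitations

The pipeline does not attempt multiple-imputation weight construction,
adjusted (multivariable) prevalence ratios, imputation of missing
confidantes, menstrual-regulation separation, or comparison against
model-based country estimates (externally supplied rates can be placed
alongside the estimates table but are never computed). The chi-square
and uPR inferences ignore survey design effects beyond weighting. The
simulator's disclosure symmetry is an assumption, not a finding; and
popularity bias remains unassessable by construction.
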