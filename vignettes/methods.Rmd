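---
title: "Small-area frailty estimation and dose-equity ratios: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area frailty estimation and dose-equity ratios: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailmap)
```

## Overview

`frailmap` estimates, for each administrative area, the number of older
people who are frail, and uses those estimates to measure how equitably an
age-prioritised vaccine roll-out served the frail population. The chain
is: score survey respondents on a deficit-accumulation frailty index,
model the ordinal frailty category as a function of age band, sex and area
deprivation, project the modelled probabilities onto each area's known
age-sex population table, and divide administered first doses by the
resulting at-risk denominators.

This vignette records the statistical model, the assumptions, the tunable
parameters, the numerical choices, and the limitations — including what the
synthetic-data generator does and does not emulate, and therefore what a
passing test suite does and does not demonstrate about real survey data.

## The frailty index

Each respondent's score is the fraction of a fixed schema of $D$ health
deficits they exhibit, $f_i = \sum_j d_{ij} / D$ with every mapped deficit
value $d_{ij} \in [0,1]$. Categories follow the standard cut-points:
robust ($f \le 0.24$), pre-frail ($0.24 < f \le 0.36$), frail
($f > 0.36$). Two deliberate rules:

* **The denominator is always $D$.** Missing items are resolved by
  imputation before scoring, never by rescaling to the observed item
  count. Scoring a table with missing cells is an error, not a silent
  adjustment.
* **Cut-point comparisons are exact closed bounds.** A score of exactly
  0.24 is robust and 0.36 is pre-frail; no epsilon is applied. With the
  default $D = 30$ the cut-points fall between attainable scores
  ($7/30 < 0.24 < 8/30$), so the boundary rules only bind for schemas
  whose $D$ makes them attainable (e.g. $6/25 = 0.24$).

The 30-item binary default schema is a stand-in: the deficit lists used
with real survey data are study-specific, so the schema (item names,
binary/graded kinds, level-to-value mappings) is user-declared
configuration, shipped as YAML.

## Missing items: chained-equations imputation

Deficit items are imputed by chained equations: each incomplete item is
regressed on age band, sex, IMD quintile and all other items; sweeps visit
items in schema order; `m` independent imputations use separate seed
sub-streams. Binary items use a ridge-penalised logistic model with
parameters drawn from the approximate posterior
$N(\hat\beta, (X^\top W X + \lambda I)^{-1})$; graded items use
predictive-mean matching with a donor pool of 5.

Parameter choices, and why:

* `m = 10`, `n_iter = 10` — conventional chained-equations practice;
  results in the test suite are insensitive to doubling either.
* `ridge = 0.1` (never on the intercept) — sparse strata can exhibit
  complete separation, under which the unpenalised posterior is improper
  and draws on the separation direction are unbounded, making imputations
  erratic. A penalty of 0.1 keeps the fit finite and the posterior draws
  stable while barely perturbing well-identified coefficients; the
  separation unit test verifies the penalised fit against an independent
  optimisation of the same penalised likelihood.
* Imputation operates on items, not on the score: the index is a
  deterministic function of the items, so imputing items and then scoring
  propagates item-level uncertainty correctly.

## The ordinal model

The frailty category $Y \in \{\text{robust} < \text{pre-frail} <
\text{frail}\}$ follows a proportional-odds (cumulative logit) model

$$P(Y \le k \mid x) = \operatorname{expit}(\theta_k - x^\top\beta), \qquad
\theta_1 < \theta_2,$$

so a positive coefficient shifts mass towards frailty. Predictors are
indicator-coded categoricals with references 50-54, male, and IMD
quintile 1 (the most deprived). The fit maximises the weighted
log-likelihood $\sum_i w_i \log P(Y_i = y_i \mid x_i)$, with the survey's
inverse-probability weights (rescaled weights leave estimates unchanged;
the suite checks this invariance).

Numerics: the likelihood is maximised by BFGS with the analytic gradient,
with the thresholds kept ordered through a log-gap reparameterisation;
the solution is then polished by damped Newton steps on the natural scale
(numerically differenced Hessian of the analytic gradient, step-halving on
any objective increase) until the gradient max-norm is $\le 10^{-8}$.
This reaches the same stationary point as a pure Newton iteration but is
robust to poor starting values. Starting values are $\beta = 0$ and
thresholds at the logits of the weighted cumulative category shares.

The covariance is the inverse observed information of the weighted
likelihood by default; a sandwich estimator
$A^{-1} (\sum w_i^2 s_i s_i^\top) A^{-1}$ is available via
`vcov_type = "sandwich"` for design-based variance under informative
weights. Which of the two a given survey warrants is a design question
the package leaves to the analyst; both propagate identically through the
bootstrap.

Per-imputation fits are pooled by Rubin's rules: point estimates are means
and the total covariance is $T = \bar W + (1 + 1/m)B$. Interaction checks
use the likelihood-ratio statistic between nested fits; under non-unit
weights this is a pseudo-likelihood ratio and the result is flagged as
approximate. "Interactions between frailty, age and sex" are interpreted
as age-by-sex interaction terms in the outcome model (frailty is the
outcome, so an interaction *with* frailty can only mean non-proportional
effects, which the proportional-odds scope excludes).

## Post-stratification and uncertainty

For area $c$ with population $N_{c,a,s}$ in age band $a$ and sex $s$, and
deprivation quintile $q(c)$ assigned from the IMD rank by
$q = \lceil 5\,\mathrm{rank}/n \rceil$ (rank 1 = most deprived; the
simplest deterministic rule, since official quintiles are defined over
small areas, not the analysis areas), the expected category counts are

$$E[N_{c,k}] = \sum_{a,s} N_{c,a,s}\; p_k(a, s, q(c)).$$

Counts in each area sum to its 50+ population by construction, for the
point estimate and every bootstrap draw; the suite asserts this to
$10^{-8}$ absolute on populations of order $10^5$.

Uncertainty is propagated by a **parametric bootstrap on the pooled
coefficients**: draws from $N(\hat\gamma, T)$ (rejecting the rare draws
with unordered thresholds; an error is raised if rejections exceed half
the draws), each pushed through the probability and sum-product steps,
with percentile 95% intervals. This was chosen over the delta method
because the mapping from coefficients to area counts is nonlinear and the
bootstrap propagates it exactly; `B = 1000` makes the percentile noise
negligible relative to the interval width. Population counts are treated
as fixed constants, matching the use of official mid-year estimates.

## Equity metrics

Per-area ratios divide first-dose counts by: the frail count, the frail +
pre-frail count, the over-50 population, each risk-factor diagnosis
count, and the summed diagnoses over the configured factor set (a person
with several diagnoses counts once per diagnosis). Ratios against
modelled denominators reuse the bootstrap draws (doses fixed, denominator
varying); ratios against fixed counts are reported as points without
intervals. The extreme-ratio factor is the maximum area ratio over the
minimum; its interval recomputes the factor within each joint draw, with
the arg-max and arg-min areas free to vary — the natural definition when
the extremes themselves are uncertain. Display values are rounded to one
decimal; full precision is kept internally.

Quintile assignment for heatmap tables sorts areas by advantage, breaking
ties by area id, and splits them into five groups whose sizes differ by
at most one, the larger groups going to the less-advantaged end; quintile
5 is the most advantaged. The heatmap covers the seven risk factors plus
the frail and pre-frail denominators, ordered by doses per person over 50.

## The synthetic generator

The generator defines the study conditions for every test: 8,355 drawn
respondents aged 50+, a 17.6% expected non-response rate, 5% average item
missingness, and 135 areas with an age-proportional, frailty-blind dose
allocation.

Respondent $i$ draws age band from a fixed distribution declining with
age (6% aged 85+), sex with equal probability, IMD quintile uniformly,
and a latent propensity $u_i \sim N(0, \sigma_u^2)$; given $u_i$ the $D$
deficits are iid Bernoulli with
$\operatorname{logit} \pi_i = \alpha + \gamma_{a(i)} + \gamma_s s_i +
\gamma_{q(i)} + u_i$. Defaults: $\alpha = \operatorname{logit}(0.08)$
(8% baseline deficit prevalence at 50-54, male, most-deprived reference),
age effects rising linearly to 1.6 at 90+, a 0.15 female effect, a 0.6 to
0 deprivation gradient across quintiles, and $\sigma_u = 0.8$. These were
set once, to give realistic marginal frailty prevalences (roughly 12-15%
frail overall, rising steeply with age and deprivation) and realistic
overdispersion of the index; they are not calibrated to any downstream
test. No generative model for deficits is established in this literature —
the survey scoring operates on observed items — so the
Bernoulli-propensity process is this package's own documented stand-in.

Non-response follows a logistic propensity declining with age and rising
with affluence, its intercept calibrated by root-finding so the expected
rate over the drawn covariates equals the target; supplied weights are
inverse true propensities rescaled to mean 1, mirroring the practice of
surveys shipping design/non-response weights with the data (weights are
*supplied*, not estimated by the pipeline). Item missingness depends on
age band only — missing at random by construction — so a correctly
specified imputation model is unbiased and parameter-recovery tests are
interpretable. Area populations are log-normal around a 60,000-person
over-50 mean; doses are population × per-band uptake (rising from 30% at
50-54 to ~95% at 85+); risk-factor prevalences carry a positive
deprivation gradient (log rate ratio 0.12 per quintile step).

Two independent routes to the generator's truth exist: an analytic one
(Gaussian quadrature over $u$, binomial category tails) and a Monte-Carlo
oracle that simulates and scores respondents per stratum. Tests compare
the pipeline against the Monte-Carlo route and the two routes against
each other.

What the generator does **not** emulate: household clustering and the
survey's actual multi-stage design, longitudinal attrition structure,
realistic English geography, item-level not-missing-at-random mechanisms,
and any real deficit-to-deficit correlation beyond the shared latent
propensity. Passing tests therefore demonstrate the pipeline's internal
correctness and its statistical behaviour under a known, favourable
data-generating process — not unbiasedness on real survey data.

## Problem sizes in the test suite

Parameter recovery fits 50,000 complete respondents against a
$10^5$-per-stratum Monte-Carlo oracle; interval calibration runs 200
replicate surveys of 20,000 respondents with 500-draw bootstraps;
imputation checks run the default-size survey at 5% missingness with
$m = 5$.
These sizes make Monte-Carlo error small relative to every tolerance
while keeping the default suite comfortably runnable on one CPU.

## Known limitations

* **The proportional-odds form is an approximation to the generator's
  truth.** The binomial-over-Gaussian deficit process does not satisfy
  proportional odds exactly: the best-achievable proportional-odds
  representation of the true stratum probabilities (obtained by fitting
  the model to the analytic truth itself) differs from that truth by up
  to ~0.02 in individual cell probabilities under the default
  configuration. This approximation error is invisible at survey scale —
  the recovery test's ±0.03 band absorbs it — but it does not shrink with
  sample size, while confidence-interval width does. The calibration
  experiment in the test suite consequently finds that at 20,000
  respondents the nominal 95% bootstrap intervals for area frail counts
  undercover for a substantial minority of areas (per-area coverage
  ranging from roughly 0.80 to 0.97). This is the expected behaviour of
  any parametric interval under fixed model misspecification, not a
  defect of the bootstrap: the smaller the survey, the wider the
  intervals and the smaller the bias-to-width ratio. Users should treat
  the intervals as reflecting sampling uncertainty only.
* **The oldest age band is data-sparse.** Around 1.5% of respondents fall
  in the 90+ band, so its coefficient — and the ten stratum probabilities
  it drives — carries visibly more sampling noise than any other; at
  50,000 respondents the recovery test's ±0.03 band is marginal in those
  cells for this reason alone.
* Printed confidence intervals in published area-level analyses cannot be
  reverse-engineered (the interval method is typically unstated), so the
  bootstrap here is this package's own definition, documented above.
* One deprivation quintile per area ignores within-area deprivation
  heterogeneity.
* The risk-factor denominators count diagnoses, not people; comorbidity
  inflates denominators in high-morbidity areas.
* No spatial smoothing: small areas inherit the full variance of their
  stratum composition.
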