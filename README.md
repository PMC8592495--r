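# frailmap

Small-area frailty estimation and vaccination-equity ratios.

## The problem

Age-based vaccine roll-outs allocate doses in proportion to the older
population of each administrative area. Frailty, however, is not
distributed like age: it concentrates in deprived areas, and it predicts
adverse outcomes more strongly than age alone. An area whose older
population is disproportionately frail therefore receives fewer doses *per
frail person* than an affluent area of the same age profile. Quantifying
that inequity needs an estimate of the frail population of every area —
a quantity no register records directly.

`frailmap` implements the full small-area ("synthetic") estimation
pipeline that produces such estimates from national survey microdata, and
the equity metrics built on them:

1. **Frailty index** — each survey respondent is scored by the
   deficit-accumulation index `f = (number of deficits present) / D` over a
   fixed schema of `D` health deficits, then categorised
   robust (`f ≤ 0.24`), pre-frail (`0.24 < f ≤ 0.36`) or frail (`f > 0.36`).
2. **Missing items** — multiple imputation by chained equations
   (ridge-penalised logistic models per binary item, predictive-mean
   matching for graded items) produces `m` completed datasets.
3. **Ordinal model** — a weighted proportional-odds regression
   `P(Y ≤ k | x) = expit(θ_k − xᵀβ)` of frailty category on age band
   (50-54 … 85-89, 90+), sex and area-deprivation (IMD) quintile, with
   inverse-probability weights for survey non-response; per-imputation fits
   are pooled by Rubin's rules (`T = W̄ + (1 + 1/m)B`).
4. **Post-stratification** — predicted category probabilities for all 90
   (age band × sex × IMD quintile) strata are combined with each area's
   age-sex population table:
   `E[N_frail(c)] = Σ_{a,s} N(c,a,s) · p_frail(a, s, q(c))`,
   with parametric-bootstrap confidence intervals from the pooled
   coefficient distribution.
5. **Equity ratios** — first doses divided by the frail population, the
   frail + pre-frail population, the over-50 population, and per
   risk-factor diagnosis counts; extreme-ratio factors (max/min across
   areas) with bootstrap intervals; quintile heatmap tables.

Because the survey microdata such analyses use are access-restricted, the
package ships a **synthetic-data generator** with a known generative model
(deficits conditionally Bernoulli given a Gaussian respondent propensity,
with age/sex/deprivation gradients, calibrated non-response and
age-graded item missingness) plus analytic and Monte-Carlo oracles for the
true stratum probabilities, so every stage is testable end to end.

## Worked example

```r
library(frailmap)

cfg  <- generator_config(n_respondents = 2000, seed = 42)
sim  <- generate_survey(cfg)          # responders with IPW weights + truth
tabs <- generate_areas(cfg)           # 135 areas, doses, risk factors

imps   <- mice_impute(sim$survey, cfg = mice_config(m = 5, n_iter = 5, seed = 7))
fits   <- lapply(imps, function(t) frailty_po(data = score_survey(t)))
pooled <- pool_rubin(fits)
pooled
#> Rubin-pooled proportional-odds fit (m = 5 imputations)
#>    age_band55-59    age_band60-64    age_band65-69    age_band70-74
#>           0.1115           0.7249           0.8599           1.4452
#>    age_band75-79    age_band80-84    age_band85-89      age_band90+
#>           1.8884           2.0381           2.4382           3.0267
#>        sexfemale    imd_quintile2    imd_quintile3    imd_quintile4
#>           0.1149           0.0496          -0.5529          -0.7295
#>    imd_quintile5 robust|pre_frail  pre_frail|frail
#>          -0.8205           1.3696           2.3167
```

Coefficients are log cumulative-odds shifts towards frailty: they rise
monotonically with age band and fall towards the affluent IMD quintiles
(quintile 1, the most deprived, is the reference), as the generator built
in. Post-stratify onto the areas and compute equity ratios:

```r
est <- bootstrap_area_cis(pooled, tabs$areas, B = 1000, seed = 8)
head(est$estimates[, c("area_id", "imd_rank", "frail", "frail_lo", "frail_hi")])
#>   area_id imd_rank     frail  frail_lo  frail_hi
#> 1    A001       36 19207.401 16470.752 22382.931
#> 2    A002       44 16179.799 13879.919 18885.790
#> 3    A003      135  6983.218  5697.965  8678.299
#> ...

r <- dose_ratio_table(tabs$doses,
       data.frame(area_id = est$estimates$area_id, frail = est$estimates$frail),
       "frail", est$draws$frail)
extreme_factor(r, sweep(1 / est$draws$frail, 2,
  tabs$doses$doses[match(colnames(est$draws$frail), tabs$doses$area_id)], `*`))
#> Extreme-ratio factor: 1.9 (1.7-2.5)  [max A080 / min A034]

cor(r$ratio, est$estimates$imd_rank, method = "spearman")
#> 0.86
```

The best-served area gets 1.9 times more doses per frail person than the
worst-served one, and the strong positive rank correlation with IMD rank
(rank 1 = most deprived) shows the under-served areas are the deprived
ones — the inequity an age-based allocation creates when frailty gradients
are ignored. `run_pipeline()` performs all of the above (plus per-risk-factor
ratios and the heatmap table) in one call and writes every artifact as CSV
with sidecar schemas.

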