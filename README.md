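# resilind

Resilience indicators from daily step-count data for dairy cattle, with
quantitative-genetic evaluation.

## The problem

Sensors on commercial dairy farms record each cow's daily step count for
years. Resilient cows — cows that are minimally affected by disturbances
such as disease or heat and that recover quickly — are expected to keep
their activity close to its undisturbed trajectory, while less resilient
cows show drops, larger fluctuations and slower recovery. If traits
derived from these fluctuation patterns are heritable, they can be used
for genetic selection. `resilind` implements, as a tested and reusable
pipeline, the derivation of nine such resilience indicator traits from
raw step-count tables and their genetic evaluation with repeatability
animal models, together with a pedigreed herd simulator with known true
parameters so that every stage is testable without access to proprietary
sensor data.

It is aimed at quantitative geneticists and livestock data scientists who
want to compute these indicators on their own longitudinal activity data,
or to study the statistical behaviour of the indicator definitions under
a controlled generative model.

## The pipeline

1. **Record editing** (`edit_records`): partial measuring days are scaled
   to whole days by `86400 / seconds_measured`; lactations are kept only
   for parities 1–3 of herd-book cows (≥ 87.5% Holstein) that calved at
   640/855/1070 days of age or later with a calving interval ≥ 215 days;
   records outside days in milk (DIM) −14…450 and days with fewer than
   200 steps are dropped; records adjacent to ≥ 7-day recording gaps are
   trimmed; estrus days (step count above the 10-day rolling mean plus
   2.5 SD, or an insemination day) are removed.
2. **Correction** (`fit_correction_model`): a two-factor fixed-effects
   model `y = HM_j + preg_k + e` removes herd-by-calendar-month and
   pregnancy-status (not pregnant / pregnant / dry / close-up / unknown)
   effects; the residuals `e` are the *corrected steps*.
3. **Indicators** (`derive_indicators`): per lactation, the mean corrected
   steps over four stages (complete DIM 1–450, early 1–28, later 75–450,
   pre-partum −14…−1), and from the residuals around the individual
   0.7-quantile quartic lactation curve
   `y_t = b0 + b1 t + … + b4 t^4` (pinball loss, τ = 0.7): the
   log-variance `LnVar = log s²(e)`, the lag-1 autocorrelation
   `r_auto = Σ(e_t−ē)(e_{t+1}−ē)/Σ(e_t−ē)²` over calendar-adjacent days,
   the mean of all negative residuals, the number of step-count drops
   (runs of ≥ 10 consecutive days with negative residuals) per 100
   recorded days, and the mean residual inside drops. A per-parity 4-SD
   outlier screen follows.
4. **Genetics** (`fit_univariate_repeatability`,
   `fit_bivariate_repeatability`): REML on the repeatability animal model
   `y = Xb + Z1 a + Z2 p + e`, `a ~ N(0, A σ²a)`, `p ~ N(0, I σ²pe)`,
   with A the pedigree relationship matrix; heritability
   `h² = σ²a/(σ²a+σ²pe+σ²e)`, repeatability `r = (σ²a+σ²pe)/(σ²a+σ²pe+σ²e)`,
   and genetic / permanent-environmental correlations from the bivariate
   model with unstructured 2×2 (co)variance matrices.
5. **Association tools**: exploratory four-disease ANOVA per indicator on
   herds with registrations (`disease_associations`), and partial genetic
   correlations `r_xy·z = (r_xy − r_xz r_yz)/√(1−r²xz)√(1−r²yz)` that
   adjust indicator–trait correlations for mean step count
   (`partial_genetic_correlation`, `recompute_partial_table`).

## Worked example

```r
library(resilind)

cfg  <- sim_config(n_herds = 4, n_sires = 25, n_dams_per_sire = 10) # 250 cows
herd <- simulate_herd(cfg, seed = 42)
pipe <- run_resilience_pipeline(herd)
pipe$fit
#> Step-count correction model (herd-month + pregnancy status)
#>   records: 160612, herd-month cells: 48
#>   intercept (reference h1_m1, not_pregnant): 2079.5 steps/day
#>   pregnancy effects:
#> not_pregnant     pregnant          dry     close_up      unknown
#>          0.0       -192.4       -300.3       -307.5        -42.2

pipe$indicators[1:3, c("cow_id", "parity", "mean_complete", "ln_var",
                       "r_auto", "n_drops_per_100d")]
#>    cow_id parity mean_complete   ln_var     r_auto n_drops_per_100d
#> 1:    276      1     1950.7574 12.96719 0.02140382        0.0000000
#> 2:    276      2     1095.4533 13.03069 0.10656148        0.0000000
#> 3:    277      1      631.3021 13.14057 0.06322072        0.3030303

fit_univariate_repeatability(pipe$indicators, "mean_complete", herd$pedigree)
#> Univariate repeatability animal model REML: mean_complete
#>   records 554, animals 525, fixed effects 72
#>          sigma2_a sigma2_pe sigma2_e
#> estimate   134800    285000   138900
#>   h2 = 0.241, repeatability = 0.751
#>   SE(h2) = 0.145, SE(r) = 0.029
```

The pregnancy effects show dry and close-up cows walking ~300 steps/day
less than open cows, and the indicator rows give each lactation's mean
corrected step level, residual log-variance, lag-1 autocorrelation and
drop rate. The heritability of mean step count in this deliberately small
example (250 cows) is estimated at 0.24 with a large standard error
(0.15); at the package's standard scale of 1,000 cows and 100 half-sib
families the estimates concentrate around the simulated truth of 0.45
(see the tests and `scripts/acceptance.R`).

Partial genetic correlations from published pairwise estimates:

```r
recompute_partial_table()
#>                      indicator     UH    HH   KET     LON    FER    BCS
#> 1:          mean_neg_residuals -0.090 0.468 -0.12  0.0261 0.2962  0.343
#> 2:                      ln_var  0.190 0.044  0.14 -0.0178 0.0053 -0.052
#> 3: mean_neg_residuals_in_drops -0.054 0.350  0.26  0.0081 0.3591  0.710
```

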