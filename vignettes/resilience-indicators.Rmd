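---
title: "Resilience indicators from daily step counts: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience indicators from daily step counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(resilind)
```

## Scope and rationale

`resilind` derives resilience indicator traits from daily step-count time
series of dairy cows and estimates their genetic parameters. The premise is
that a resilient cow keeps her activity close to its undisturbed trajectory:
disturbances (mastitis, ketosis, claw and uterine disorders, heat, ration
changes) depress step count for days to weeks, so the *pattern* of deviations
around an individual baseline — not the raw level alone — carries information
about resilience. Because commercial sensor datasets of this kind are
proprietary, the package ships a generative model of a pedigreed herd with
known true parameters; every statistical stage is validated against that
ground truth or against independent oracles.

## The statistical chain

### Editing rules

Raw records are one row per cow-day with a step count and, when known, the
seconds the device actually measured. The editing stage applies, in order:

1. **Lactation assignment.** A record belongs to the lactation in progress,
   except records within 14 days before a calving, which become the
   pre-partum days (DIM −14…−1) of the upcoming lactation. DIM 0 (calving
   day) is never used. The audit trail for each decision is kept in an
   exclusion log that reconciles exactly with the input count.
2. **Rescaling.** Partial measuring days are scaled by `86400/seconds`,
   rounded to integer steps. Unknown seconds are assumed to be whole days.
3. **Inclusion filters.** Parities 1–3 only; herd-book cows with ≥ 87.5%
   Holstein fraction; minimum age at calving 640/855/1070 days for parity
   1/2/3; previous calving interval ≥ 215 days. Missing metadata skips the
   corresponding filter rather than failing.
4. **Window and plausibility.** DIM ≤ 450; records with fewer than 200
   steps/day are treated as device errors and dropped.
5. **Gap trimming.** For each run of ≥ 7 consecutive days without records,
   the last record before and the first after are removed (device likely
   attached/removed part-way through those days). The rule is applied
   one-sidedly at series boundaries, so the first and last record of every
   device episode are also dropped — the conservative reading.
6. **Pregnancy status.** From the reproductive calendar at the record date:
   `unknown` without a known next calving; otherwise `close_up` (< 14 days
   before the next calving), `dry` (after the last milking), `pregnant`
   (within 278 days — gestation length — before the next calving), else
   `not_pregnant`, with precedence close-up > dry > pregnant. The `unknown`
   class is retained on purpose: culled and never-conceiving cows are
   disproportionately non-resilient and must not be filtered out.
7. **Estrus removal.** A day is an estrus day if its step count exceeds the
   mean plus 2.5 sample standard deviations of the cow's previous 10 kept
   records, provided DIM ≥ 14 and the cow is not pregnant, or if she was
   inseminated that day. Flagged days are excluded everywhere, including
   from later baseline windows. Two choices the rule's verbal description
   leaves open are fixed as: the baseline window counts *records* (not
   calendar days), and "not pregnant" means any day not within gestation of
   a known next calving, which also rules the dry and close-up periods out
   of estrus — the biologically coherent reading.

### Correction model

Step counts are corrected for management and reproductive state with a
two-factor fixed-effects model, `y = HM_j + preg_k + e`, where `HM` crosses
herd with calendar month (year-free, months 1–12) and `preg` is the
five-level pregnancy status. The model is fitted by sparse least squares
under treatment constraints (first herd-month cell and `not_pregnant` as
references). Residuals are the *corrected steps*; they average zero in every
design cell, and adding a constant to all records moves only the intercept.
Pre-partum records are corrected jointly with lactation records — they must
be, for the pre-partum indicator to exist on the corrected scale.

### Individual quantile curves and the nine indicators

Four indicators are stage means of corrected steps: complete lactation
(DIM 1–450), early lactation (1–28), later lactation (75–450) and pre-partum
(−14…−1), requiring at least 28 records in the window for the two long
stages and 7 for the two short ones.

Five indicators describe fluctuations around the cow's own expected curve:
a quartic polynomial in DIM fitted by quantile regression at τ = 0.7 on an
orthogonalised basis, using lactation days 1–450 only. The 0.7 quantile
places the curve near an *unperturbed* trajectory: disturbances push step
counts down, so a curve with ~70% of days below it is less affected by the
drops it is meant to expose. From the residuals `e_t = y_t − ŷ_t`:

* `ln_var` — natural log of the sample variance (n−1), fluctuation severity;
* `r_auto` — lag-1 autocorrelation with the global mean, numerator summed
  over calendar-adjacent day pairs only (a missing day contributes no
  pair), clipped to [−1, 1]; slow recovery;
* `mean_neg_residuals` — mean of strictly negative residuals;
* `n_drops_per_100d` — maximal runs of ≥ 10 consecutive days, each with a
  record and a negative residual, per 100 recorded days; a missing day
  breaks a run (a gap carries no evidence that a drop continued);
* `mean_neg_residuals_in_drops` — mean residual inside drops (missing, with
  a reason code, when there is no drop).

"Negative" always means strictly `< 0`; a zero residual is non-negative.
Finally a single-pass outlier screen per parity and indicator removes
values more than 4 sample SDs from the mean (both computed before any
removal); a value at exactly 4 SD is kept.

### Quantitative genetics

The univariate repeatability animal model is
`y = Xb + Z1 a + Z2 p + e` with `a ~ N(0, A σ²a)`, `p ~ N(0, I σ²pe)`,
`e ~ N(0, I σ²e)`; A is built by the tabular method and its sparse inverse
directly from the pedigree (Henderson's rules with inbreeding). Fixed
effects follow the repeatability specification: parity, age at calving in
integer month classes (`floor(days/30.44)`) nested within parity,
year-season of calving (meteorological quarters) nested within parity,
herd-year nested within parity (cells with < 3 records pooled within herd),
and first recorded DIM as a covariate nested within parity; aliased columns
are removed by rank-revealing QR.

REML maximises the restricted likelihood through the mixed-model-equation
identity `−2 l_R = log|R| + log|G| + log|C| + y'Py` (constant omitted),
where `C` is the full MME coefficient matrix. One sparse Cholesky
factorisation per likelihood evaluation — with the symbolic analysis cached,
since the sparsity pattern never changes — makes evaluations cheap, so the
likelihood is maximised by bounded quasi-Newton iterations on
log-variances, followed by a central-difference Newton polish with step
halving. The log parameterisation keeps components positive (floored at
10⁻⁸ of the phenotypic variance by the box constraints); the polish brings
the optimum to the precision needed for the closed-form checks below. An
EM-style fallback was considered and not needed: the bounded quasi-Newton
plus guarded Newton steps never left the feasible region in any test.
Standard errors come from the observed information (finite differences on
the variance scale) and the delta method for `h² = σ²a/(σ²a+σ²pe+σ²e)` and
`r = (σ²a+σ²pe)/(σ²a+σ²pe+σ²e)`. When every animal has a single record,
`σ²pe` and `σ²e` are not separable and the fit refuses to include the
permanent-environment term rather than returning an arbitrary split.

The bivariate model stacks two traits with trait-specific fixed effects and
unstructured 2×2 genetic, permanent-environmental and residual covariance
matrices, each parameterised by its Cholesky factor with log-diagonal so
estimates stay positive semidefinite; the residual covariance acts on
cow-parity units observed for both traits. Correlations at the |r| = 1
boundary are flagged, not silently accepted.

Validation anchors: on balanced paternal half-sib designs REML equals the
closed-form ANOVA estimators (`σ̂²s = (MSB − MSW)/k`) to 10⁻⁶, the
relationship matrix matches a brute-force recursive oracle to 10⁻¹², and
parameter recovery is checked at the published step-level regime
(h² = 0.45, repeatability = 0.74) with 2,000 cows × 3 parities.

### Disease associations and partial correlations

The exploratory ANOVA `indicator ~ parity + mastitis + ketosis + claw +
uterus` is fitted once per disease on that disease's herd subset (herds
with ≥ 1 registration of it and step data for ≥ 5 lactations) — the only
reading consistent with per-disease subsetting — and results carry an
`exploratory` flag because registration is voluntary and incomplete. Herd
is not in the model, mirroring the specification of the analysis; the
possible within-herd confounding is a known limitation.

Partial genetic correlations adjust an indicator's correlation with an
external trait for mean step count:
`r_xy·z = (r_xy − r_xz r_yz)/(√(1−r²xz)√(1−r²yz))`. Inputs whose implied
3×3 correlation matrix is not positive semidefinite can push the result
outside [−1, 1]; it is then returned unclipped with a flag. The packaged
fixtures carry the published pairwise estimates, and reproducing the
published partial-correlation table to ±0.005 (the published rounding) is
part of the acceptance checks.

## The synthetic herd

`sim_config()` defines the study conditions; the defaults are fixed once
and used by all tests:

* **Scale.** 100 unrelated sires × 10 dams = 1,000 recorded cows in 10
  herds, up to 3 parities between 2016-07-01 and 2019-07-01. One hundred
  half-sib families keep the sampling SD of a heritability estimate near
  0.06; with few large families the family-level sampling noise would
  dominate recovery checks.
* **Level.** Baseline 2,200 steps/day; herd effects (SD 150) plus a
  seasonal herd-month cosine with amplitude 350 for grazing herds (July
  peak) and 15% of that for non-grazing herds, emulating the grazing /
  non-grazing contrast seen in commercial herd-month estimates. True
  pregnancy effects 0 / −60 / −180 / −120 steps/day (open / pregnant /
  dry / close-up); stage curve: +550 steps/day at DIM 1 declining linearly
  to the plateau at DIM 75, and a −150 dip on DIM −14…−1.
* **Fluctuations.** Day-to-day noise is normal with baseline SD 650
  steps/day — `log(650²) ≈ 13.0` puts the log-variance indicator in the
  published band around 13.2. The noise family is a modelling choice; the
  source data give no within-cow residual distribution.
* **Genetics.** Three latent cow traits: step level (σ²a = 270,000,
  σ²pe = 170,000, σ²e = 160,000 steps², i.e. h² = 0.45 and repeatability
  0.733, the published regime for mean step count), a log-scale noise
  multiplier (0.020/0.020/0.010) and a log-scale disturbance-rate
  multiplier (0.09/0.06/0.05). Breeding values follow the pedigree
  (parent average + Mendelian sampling with inbreeding-adjusted variance);
  the additive correlation between level and variability is +0.6,
  matching the sign and strength of the published genetic correlation
  between log-variance and mean step count. Correlations involving the
  disturbance-rate latent default to zero: under realistic event depth,
  duration and noise, the detected-drop indicator is almost entirely
  run-length noise (its heritability in the source population was 0.01,
  and its genetic correlation with step level there was *positive*, an
  artifact of the 200-step filter interacting with cow level — behaviour
  this generator reproduces), so a configured correlation on that latent
  is not recoverable from the derived indicators and would only create an
  untestable claim.
* **Disturbances.** Event onsets Poisson at 1.0 per 100 days times the
  cow's multiplier; durations 4 + Poisson(8) days; depths normal around
  −800 steps/day (SD 200, capped at −100); 60% of events carry a disease
  label (mastitis/ketosis/claw/uterus at 20/25/40/15%), emitted only for
  the ~70% of herds that "register" the disease, so the per-disease herd
  subsetting has real work to do.
* **Estrus.** A 21-day cycle anchored at conception (278 days before the
  next calving), spikes of ~2,500 steps; open cows keep cycling.
  Inseminations sit on cycle days, with 30%/12% single/double returns.
  Estrus spikes are added after disturbance depths (additive composition).
* **Artifacts.** 61% of records carry known measuring seconds, 0.6% of
  those are partial days; 0.2% of records become sub-200-step device
  errors; 8% of lactations contain a 7–20-day recording gap; negative
  step counts are truncated at zero and the truncation rate is reported
  (about 1% at the default settings — configs should stay in that regime).

The generator does **not** emulate: autocorrelated day-to-day noise (so the
lag-1 autocorrelation indicator sits near zero instead of the published
~0.3; its machinery is tested through oracles rather than regime
matching), weather or heat-stress covariates, milking-visit-level detail,
within-herd management groups, or real accelerometer noise spectra.
Passing tests therefore demonstrate correctness of the pipeline's
*algorithms* and recoverability of *configured* parameters, not that the
simulator is a complete model of commercial sensor data.

## Numerical choices

* **Quantile fit.** The pinball loss is minimised by iteratively
  reweighted least squares on a smoothed loss (|r| replaced by
  √(r² + ε²)) with ε lowered from the data scale to 10⁻⁸ of it; this
  converges to the linear-programming solution. Residuals within 10⁻⁶ of
  the scale of zero are snapped to exact zero, because interpolated
  points carry an O(ε) bias whose sign must not leak into the
  strictly-negative counts used by the drop detector and the coverage
  bound. The fraction of negative residuals then respects the LP
  optimality band τ ± 5/n (5 = number of polynomial coefficients).
* **Degenerate inputs.** Constant series fit exactly with zero residuals;
  zero-variance residual sets give missing log-variance with reason
  `degenerate`; lactations with fewer than 28 curve points skip the
  fluctuation indicators with reason `min_data`.
* **Tie-breaks.** A record at exactly 200 steps is kept; a calving
  interval of exactly 215 days is kept; an indicator value at exactly
  4 SD is kept; a record exactly 14 days before calving is `pregnant`,
  not `close_up`.
* **Problem sizes.** The test suite runs the half-sib REML identity at
  600 records, direct-simulation recovery at 2,000 cows × 3 parities × 8
  seeds, full-pipeline recovery at 1,000 cows × 5 seeds, quantile
  coverage on 500 lactations, and oracle comparisons on 1,000 random
  sequences — sizes at which each check is statistically meaningful while
  the whole suite stays desk-scale.

## Known limitations

* White day-to-day noise makes `r_auto` nearly uninformative in simulated
  data; an AR(1) noise option would be the natural extension.
* The drop-count indicator is dominated by run-length noise at realistic
  signal-to-noise ratios; its near-zero heritability here mirrors what is
  seen in commercial data, and conclusions about drop-proneness should
  rely on the deviation-severity indicators instead.
* Multi-trait evaluation against external breeding values (health,
  longevity, fertility, body condition) is out of scope; external genetic
  correlations enter only as supplied estimates for the partial
  correlation tools.
* The disease ANOVA omits herd; with voluntary registration this is an
  exploratory screen, not an effect estimate.
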