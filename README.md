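# earlygrowth

Tools for studying how fetal and infant weight trajectories relate to
general, visceral and organ fat in childhood — the analytic core of
population-based birth-cohort studies that follow children from
mid-pregnancy ultrasound to a school-age MRI/DXA visit. It is aimed at
epidemiologists and biostatisticians working with longitudinal growth
data (or teaching/validating these methods on synthetic data, since
individual-level cohort data of this kind are rarely public).

## What it implements

* **Standardization.** Hadlock estimated fetal weight
  (log₁₀ EFW = 1.326 − 0.00326·AC·FL + 0.0107·HC + 0.0438·AC +
  0.158·FL), age- and sex-specific reference charts built from a
  designated reference sample, SDS = (value − mean)/SD with linear
  interpolation in age, and SGA/AGA/LGA classification at the
  5th/95th birth-weight percentiles.
* **Growth patterns.** Weight-SDS change between second trimester and
  birth, and birth to 24 months (falling back to the ~11- and ~6-month
  visits), classified as deceleration / normal / acceleration at the
  ±0.67-SDS centile-crossing rule, crossed into nine combined patterns.
* **Conditional growth.** Standardized residuals of each weight SDS on
  all earlier SDS — growth independent of prior size — and
  critical-period regression models built on them.
* **Trajectory models.** Per-sex Reed1 infant weight curves
  W(t) = A + B·t + C·ln t + D/t with per-child peak weight velocity
  PWV = B + C²/(4D) at t* = 2D/C; a cubic mixed model on log BMI
  (2 weeks–1.5 years) with per-child age and BMI at adiposity peak.
* **Adiposity indices.** Log-log height-power estimation and the
  resulting indices: fat mass/height⁴, fat-free mass/height²,
  visceral and pericardial fat mass/height³ (volumes × 0.9 g/mL),
  mean liver fat fraction; log-transform + SDS outcome panel.
* **Association models.** Basic / main / stratified covariate sets,
  pattern contrasts against normal/normal, a fetal×infant interaction
  test, birth-size-stratified PWV/BMIAP/AGEAP models, chained-equation
  multiple imputation of covariates (m = 5) and Rubin pooling with
  Barnard–Rubin degrees of freedom.
* **Synthetic cohorts.** `simulate_cohort()` generates the whole data
  structure — AR(1)-tracking weight SDS, Hadlock-consistent biometry,
  realistic visit schedule and missingness, configurable true effects —
  so the full pipeline is testable with no external data.

## Worked example

```r
library(earlygrowth)

cfg    <- sim_config(n_children = 3000, seed = 11)
cohort <- simulate_cohort(cfg)
fit    <- run_pipeline(cohort, seed = 11, charts = generating_charts(cfg))
print(fit)
```

```
Growth-pattern analysis pipeline
  children: 3000
  with combined pattern: 2117
  pattern counts:
            normal/normal deceleration/deceleration       normal/deceleration
                      482                        92                       266
acceleration/deceleration       deceleration/normal       acceleration/normal
                      235                       237                       248
deceleration/acceleration       normal/acceleration acceleration/acceleration
                      205                       263                        89
  conditional-eligible n per time point:
 efw2_sds  efw3_sds birth_sds    w6_sds   w11_sds   w24_sds
     2581      2130      2130      1399      1061       835
  birth size:
 SGA  AGA  LGA
 145 2697  158
```

About 70% of children are pattern-classifiable (both a fetal and an
infant growth category), and the conditional-growth n's shrink with age
because each time point requires complete data at all earlier points.
The pooled pattern contrasts for the liver-fat outcome:

```r
subset(fit$results$pattern, outcome == "liver_fat_pct_sds")[,
       c("level", "estimate", "ci_low", "ci_high", "p")]
```

```
                              level estimate ci_low ci_high       p
12 patterndeceleration/acceleration    0.288  0.122   0.454 0.00067
15       patternnormal/acceleration    0.132 -0.022   0.285 0.09274
11       patternacceleration/normal    0.089 -0.067   0.245 0.26169
...
```

Children with fetal weight deceleration followed by infant weight
acceleration have the highest liver fat (here +0.29 SDS against
normal/normal growth; the cohort was generated with a true effect of
0.34, and this single-cohort estimate sits inside its 95% CI). The
trajectory stage reports `mean PWV 12.1 kg/y`, `mean AGEAP 8.3 mo` and
`mean BMIAP 17.5` for the same cohort — the derived peak-velocity and
adiposity-peak measures that feed the birth-size-stratified models in
`fit$results$stratified`.

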