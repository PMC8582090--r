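# fallstrat

Stratified fall-risk assessment for community-dwelling older adults.

Falls are the leading cause of injury in people over 65, and screening
guidelines call for more than a single faller/non-faller threshold: they
ask for *interval reference values* that tell a clinician, a caregiver or
an exercise professional whether a given balance score, body composition,
activity level, health-condition count or household-hazard count places a
person at low, moderate, high or very high risk — and by how much each
factor would have to improve to move down a band. `fallstrat` implements
that pipeline end to end for researchers and methodologists working with
multifactorial fall-risk models.

## The model

Fall probability follows a multivariate binary logistic model over eight
key factors:

π(x) = logit⁻¹( β₀ − 0.053·B − 0.026·L + 0.027·F − 0.012·TPA
                + 0.034·VPA + 0.125·R + 0.112·HC + 0.063·H )

where B is the multidimensional balance score (points), L lean body mass
(kg), F fat body mass (%), TPA/VPA total and vigorous physical activity
(100 MET-min/wk), R the weekday seated rest period (hr/day), HC the
health-condition count and H the environmental-hazard count (β₀ = 0 in
reproduce mode). Risk strata live on the probability scale — low π < 0.25,
moderate up to the Youden cutoff (0.35939 for the reference cohort), high
up to 0.50, very high above — and are inverted into per-factor cutoffs
along a *joint risk profile*: protective factors at percentile p, risk
factors at percentile 100 − p of the cohort distribution. Because π is
strictly decreasing in p, each probability cutoff has a unique percentile
root, and each factor's cutoff is its own quantile there.

The package provides:

- `variable_registry()`, `load_cohort()`, `write_cohort()` — the
  19-variable candidate registry, unit conversions and validated CSV I/O;
- `simulate_cohort()` — a Gaussian-copula generator reproducing the
  published percentile anchors, with faller labels drawn from the model at
  a prevalence-calibrated intercept;
- `fit_logistic()`, `backward_select()`, `hosmer_lemeshow()`,
  `univariate_or_table()`, `odds_ratio_report()` — from-scratch IRLS
  logistic regression with selection and goodness of fit;
- `roc_curve()`, `auc_ci()`, `youden_cutoff()`, `crossval_auc()` — ROC
  analysis, DeLong intervals and 10-fold cross-validation;
- `derive_cutoffs()`, `present_cutoffs()`, `published_cutoffs()` — the
  probability-to-factor inversion and interval presentation;
- `profile_report()`, `classify_factor()`, `improvement_deltas()` — the
  individual risk profiler.

## Worked example

Deriving the stratified cutoff table from the model and the published
anchors, then profiling the worked-example person with a balance score of
29 points:

```r
library(fallstrat)

derive_cutoffs()
#> Stratified fall-risk cutoffs (derived)
#> percentile roots (protective side): low_mod=56.96, mod_high=45.04, high_vhigh=32.39
#> Multidimensional balance score (point): low risk: > 33, moderate risk: 32-33, high risk: 30-31, very high risk: < 30
#> Lean body mass (kg): low risk: > 44, moderate risk: 42-44, high risk: 40-41, very high risk: < 40
#> Fat body mass (%): low risk: < 37, moderate risk: 37-38, high risk: 39-41, very high risk: > 41
#> ...

person <- c(multidimensional_balance = 29, lean_body_mass = 42.2,
            fat_body_mass = 38.3, total_pa = 2473, vigorous_pa = 0,
            rest_period_weekdays = 4.3, health_conditions = 3,
            environmental_hazards = 6)
profile_report(cutoff_table = published_cutoffs(), measurements = person)
#> Individual fall-risk profile
#>   fall probability: 0.344 -> overall moderate risk
#>   multidimensional_balance   very high  (value 29)  improve: +1 to high, +3 to moderate, +5 to low
#>   lean_body_mass             moderate   (value 42.2)  improve: +2 to low
#>   fat_body_mass              moderate   (value 38.3)  improve: -2 to low
#>   total_pa                   moderate   (value 2473)  improve: +400 to low
#>   rest_period_weekdays       moderate   (value 4.3)  improve: -0.4 to low
#>   health_conditions          moderate   (value 3)  improve: -1 to low
#>   environmental_hazards      high       (value 6)  improve: -1 to moderate, -2 to low
```

The probability cutoffs translate into the reference boundaries: the
π = 0.25 inversion lands at the 56.96th percentile (lean mass 44 kg,
balance 33 points), the π = 0.50 inversion at the 32.39th (fat mass 42 %,
hazards 8) — and the profile percentile p = 45 evaluates to π = 0.3599,
the Youden cutoff of the reference cohort. A person scoring 29 balance
points sits at very high balance risk and needs +1 point to reach the
high band, +3 for moderate and +5 for low.

## The analysis workflow

Numbered drivers under `analysis/` run the full study sequence on a
simulated cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # n = 500 cohort, 37.2% fallers
Rscript analysis/02_fit_model.R         # univariate ORs, backward selection, HL test
Rscript analysis/03_discrimination.R    # ROC/AUC, Youden cutoff, 10-fold CV
Rscript analysis/04_derive_cutoffs.R    # reproduce + re-derive cutoff tables
Rscript analysis/05_risk_profiles.R     # individual profiles
```

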