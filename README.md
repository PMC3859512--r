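# tmdemand

Long-term forecasting of red-cell demand from a cohort of
transfusion-dependent thalassemia-major (TM) patients — for blood services and
biostatisticians planning supply a decade ahead.

A few hundred chronically transfused patients can absorb close to a tenth of a
city's blood supply, and their aggregate demand shifts as children grow,
the cohort ages past its peak transfusion intensity, patients die, and new
cases are born into the population. `tmdemand` implements the full analysis
pipeline:

* **Demand model** — Poisson generalized estimating equations (log link) for
  annual per-patient units, `E[y_it] = exp(x_it' β)`, with independent or
  exchangeable working correlation, Pearson scale, and Liang–Zeger sandwich
  covariance. Exponentiated coefficients are relative demands (per year of
  age, per kg, female vs male, splenectomised vs not); quadratic age and
  weight terms capture the inverted-U demand profile with peak at `−β₁/(2β₂)`.
* **Model selection** — leave-one-out cross-validation over a 16-cell variant
  grid (predictor sets × working correlations) scored by mean absolute error,
  with a parsimony rule that drops predictors earning only negligible MAE.
* **Growth curves** — LMS (Box–Cox power / median / CV) z-score transforms,
  weight imputation from age-group peer z-scores, and forward weight
  projection under a constant-z assumption, frozen from age 20.
* **Forecast** — existing patients aged forward with deterministic mortality
  attrition, plus incident cases from age/sex-specific incidence applied to a
  stratified population projection; delta-method 95% prediction intervals
  combining coefficient and population-forecast uncertainty; sensitivity
  scenarios with mortality reduced linearly by 40% or 80% over ten years.
* **Synthetic data** — a registry-scale cohort generator (overdispersed,
  within-patient-correlated demand via gamma frailties; LMS-consistent
  weights; mortality, incidence, and data-quality quirks) so the entire
  pipeline is reproducible without confidential patient records.

## Worked example

```r
library(tmdemand)

lms    <- generate_lms_reference()
cohort <- generate_cohort(generator_config(seed = 7), lms)
panel  <- backfill_weights(apply_exclusions(cohort$panel)$panel, lms)

fit <- fit_demand_model(panel, model_variant(c("age2", "weight2")))
fit
#> Poisson GEE fit (independent working correlation)
#>    1563 patient-years, 330 patients; scale = 1.631
#>          term     rr  ci_lo  ci_hi         p
#> 1         age 1.0424 1.0329 1.0519 4.270e-19
#> 2      weight 1.0392 1.0340 1.0444 3.085e-51
#> 3      female 0.9428 0.9155 0.9709 8.582e-05
#> 4 splenectomy 0.8311 0.8073 0.8556 8.915e-36
#> 5        age2 0.9992 0.9990 0.9993 6.037e-25
#> 6     weight2 0.9997 0.9997 0.9997 4.956e-51

round(peak_covariate(fit, "age"), 1)      # 25.1 — age of maximal demand (years)
round(peak_covariate(fit, "weight"), 1)   # 64.9 — weight of maximal demand (kg)
```

Demand rises about 4% per year of age and per kg early in life (RR 1.04), but
the negative quadratic terms bend both profiles into an inverted U; females
need ~6% and splenectomised patients ~17% fewer units. The scale 1.63 means
demand variance exceeds the Poisson mean — which is why the sandwich
covariance, not the naive one, backs every interval.

```r
pop <- generate_population_projection(2005:2024)
fc  <- run_scenarios(fit, patient_state(panel, lms), lms,
                     estimate_incidence(cohort$panel, pop), pop,
                     estimate_mortality(cohort$panel),
                     horizon = 15, base_year = 2009)
fc[fc$scenario == "baseline" & fc$year %in% c(2010, 2017, 2024), ]
#>    scenario year existing_units newcase_units total_units pi_lo pi_hi
#> 1  baseline 2010          12665           112       12776 12600 12952
#> 8  baseline 2017          12629          1316       13945 13733 14157
#> 15 baseline 2024          11307          3575       14881 14603 15160
```

Demand from the existing cohort slowly declines (ageing past the demand peak
plus adult mortality) while accumulating new cases more than make up for it.
`total_units = existing_units + newcase_units` holds exactly in every row.

The whole pipeline — simulate, exclusions, weight completion, LOOCV grid,
selection, fit, incidence/mortality estimation, scenario forecasts, CSV/JSON
reports — runs as one call:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "tmdemand"),
             out_dir = "demo_out")
```

or from a shell via `Rscript inst/scripts/tmdemand.R pipeline --config
cfg.yaml --out dir --seed 1`.

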