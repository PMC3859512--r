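---
title: "Forecasting cohort blood demand: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting cohort blood demand: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdemand)
```

## The problem

Thalassemia-major (TM) patients need red-cell transfusions for life, typically
starting in the first year of life, and a few hundred such patients can absorb
a substantial share of a city's blood supply. A blood service planning a decade
ahead needs to know how the aggregate demand from this cohort will evolve as
children grow (demand scales with body size), the cohort ages past its peak
transfusion intensity, some patients die, and new patients are born into the
population. `tmdemand` implements that forecasting pipeline: a marginal count
model for annual per-patient demand, predictive model selection, growth-curve
weight projection, and a cohort-component demand forecast with uncertainty.

Because real transfusion registries are confidential, the package ships a
synthetic-cohort generator with the statistical structure the analysis
assumes. Every stage is exercised and tested on generated data; none of the
package's claims depend on access to patient records.

## Demand model: Poisson GEE with a log link

The unit of analysis is the patient-year: patient $i$ in calendar year $t$
demands $y_{it}$ units with covariates $x_{it}$ (age, weight, sex, splenectomy
status, optionally years since first transfusion, quadratic and interaction
terms). The marginal mean model is

$$ E[y_{it}] = \mu_{it} = \exp(x_{it}'\beta), $$

estimated by generalized estimating equations: solve
$\sum_i D_i' V_i^{-1}(y_i - \mu_i) = 0$ with $D_i = A_i X_i$,
$V_i = A_i^{1/2} R(\alpha) A_i^{1/2}$, and $A_i = \mathrm{diag}(\mu_i)$.
Two working correlation structures $R(\alpha)$ are supported: independent and
exchangeable, the latter with $\alpha$ re-estimated each iteration by the
moment estimator on Pearson residuals. The scale parameter
$\phi = \chi^2_{\text{Pearson}}/(N - p)$ measures overdispersion relative to
the Poisson variance. Coefficient uncertainty always uses the Liang–Zeger
sandwich $B^{-1} M B^{-1}$, which is consistent under arbitrary within-patient
correlation and overdispersion even when the working structure is wrong; a
useful corollary, tested in the suite, is that the sandwich is algebraically
invariant to $\phi$. With the independent working structure the GEE root is
exactly the pooled Poisson maximum-likelihood estimate, which gives the test
suite an independent oracle (a hand-written Newton solver, and
`sandwich::vcovCL` for the clustered covariance).

Exponentiated coefficients read as relative demand: $e^{\beta_j}$ multiplies
expected annual units per unit of covariate $j$. Covariates enter *uncentred*,
so these ratios are per-year-of-age and per-kg at the natural origin; centring
would change the linear coefficients but not predictions or the location of
the demand peak $-\beta_1/(2\beta_2)$ for a covariate with linear and
quadratic terms ($\beta_2 < 0$).

Inference is Wald-type throughout: 95% intervals $\exp(\hat\beta \pm 1.96\,
\widehat{se})$ and two-sided normal p-values on robust standard errors. The
interval multiplier is fixed at 1.96 rather than `qnorm(0.975)`; the
difference is irrelevant at the reported precision and keeps printed intervals
reproducible by hand.

### Exclusion filters

Registry panels are messy in two specific ways the pipeline handles before
fitting. Patient-years below age 1 are dropped (transfusion therapy typically
begins between 6 and 12 months, so infant rows are unrepresentative of
steady-state demand). Patients whose *active* years (units > 0) are not
contiguous are excluded as irregularly transfused: a zero-demand or missing
year strictly inside the first-to-last active span. The published analyses
this pipeline follows describe such patients only loosely ("e.g. every other
year"); the contiguity rule is our operational definition, and it is a
deliberate design choice documented here rather than in the code. Patients
with no recoverable weight are excluded last, after the weight-completion step
has had its chance.

## Weights: the LMS method and the constant-z assumption

Growth references tabulate, per sex and age in months, a Box–Cox power $L$,
median $M$, and coefficient of variation $S$; a weight $x$ maps to
$z = ((x/M)^L - 1)/(LS)$ (or $\log(x/M)/S$ when $L = 0$), and back via the
exact algebraic inverse. The package interpolates $L, M, S$ linearly in age
within sex and clamps (with a warning) beyond the tabulated range. Real CDC
weight-for-age tables are read unchanged; the bundled synthetic reference has
a strictly increasing median built from two logistic components (childhood and
pubertal) with comparable magnitudes.

Forward projection assumes each patient's z-score is constant: convert the
latest observed weight to z at the current age, read the curve at the target
age. Growth is treated as negligible from age 20 — lookups are capped at 240
months and an adult's observed weight is carried forward unchanged (the
age-20 reference values are used only when an adult's weight must be imputed,
since the tables end there). Missing weights are completed at constant z from
the patient's nearest observed year; patients with no observation at all get
the mean z of their age-group peers (1-year bins below 20, one adult bin,
nearest non-empty bin as fallback). Imputation is translation-consistent:
shifting all peers' z by $\delta$ shifts the imputed z by $\delta$ — a
property test in the suite.

## Model selection: leave-one-out cross-validation

Candidate predictor sets — the base set (age, weight, sex, splenectomy) plus
combinations of age², weight², and years-of-transfusion, each crossed with the
two working correlations — are scored by leave-one-out cross-validation at the
patient-year level: every row is held out in turn, the model refit on the
rest, and the held-out demand predicted; the score is the mean absolute error
in units. The held-out unit is a single observation rather than a whole
patient, reading "all but one observations" literally; patient-level holdout
would penalise the within-patient information the GEE is designed to use.

Each fold warm-starts at the full-data coefficients; scores are invariant to
the warm start within solver tolerance (tested) — it only buys speed. The
exchangeable $\alpha$ is re-estimated inside each fold.

The final model is not the raw argmin: among variants within
`parsimony_delta` (default 0.01 MAE units) of the best score, the fewest
predictors win, with ties broken by dropping years-of-transfusion first, then
interactions. The default delta encodes the judgement that an extra predictor
earning less than a hundredth of a unit of MAE is noise for a 15-year
forecast; on published LOOCV tables of this kind the year-of-transfusion gap
is of exactly that size.

## The forecast

**Existing patients.** Each survivor of the baseline year is aged forward;
weight follows the constant-z curve; demand is
$\sum_i s_i(t)\exp(x_i(t)'\hat\beta)$ where $s_i(t) = \prod_{u \le t}(1 - m_u)$
multiplies the survival probability over the patient's adult years. Mortality
is a deterministic expectation (survival weights), not sampled deaths; a
Monte-Carlo mode (`project_existing_mc`) exists purely as a test oracle and
agrees with the deterministic path within Monte-Carlo error in the suite.
Mortality applies only at ages 20+ — pediatric TM survival is high and
long-term adult data are thin, so a single constant adult rate, estimated as
adult deaths over adult person-years in the panel (deaths placed at the end of
their year), is the supportable choice.

**New cases.** Incidence is estimated per sex × age-group (0–4, 5–9, 10–19,
20–59) as first-ever-transfused entrants over stratum person-years, using
panel years after the first (entrants "observed" in the first year are
prevalent, not incident). Applied to a stratified population projection, each
year's expected entrants form a cohort that enters at the midpoint age of its
stratum on 1 January (the data say nothing about entry timing; a full first
year of demand is the simple convention), carries the stratum's mean z-score
and splenectomy prevalence (entered as a fraction, not resampled), grows along
the LMS curve, and is attrited by adult mortality. Demand accumulates across
entry cohorts.

**Prediction intervals.** The delta method propagates two error sources: GEE
coefficient uncertainty, via the gradient of the total demand
($g'\,\hat\Sigma_\beta\, g$, with the existing- and new-case gradients summed
so their dependence on the shared $\hat\beta$ is carried, not ignored), and
population-forecast error on entrant counts, via a per-stratum coefficient of
variation (default 0.02) treated as independent across strata and years.
Intervals are point ± 1.96·SE. The suite checks the half-widths against a
10⁴-draw parametric bootstrap of $\beta$.

**Scenarios.** Sensitivity runs reduce the adult mortality rate linearly to
$(1-r)$ of baseline over a 10-year ramp ($r$ = 0.4, 0.8 by default), applied
to adults only (mortality is adult-only throughout). Totals are monotone
non-decreasing in $r$, and `total = existing + new` holds exactly in every
year — both are asserted in the tests.

## The synthetic cohort generator

The generator emulates the features the analysis needs and nothing more:

* ~340 prevalent patients observed over five annual panels, plus incident
  entrants at 0.13 per 100,000 population per year entering at age 1;
* log-linear demand with an inverted-U in age and weight (peaks near 24.5
  years and 65 kg under the default coefficients, the natural logs of relative
  demands 1.04, 0.9992, 1.04, 0.9997, 0.94, 0.85), female and splenectomy
  demand reductions, and a mean of ~38.7 units/patient-year — the intercept is
  calibrated at generation time so the cohort-average expected demand hits
  that target exactly under whatever covariate draw the seed produced;
* overdispersion (Pearson scale 1.71) and within-patient correlation via two
  multiplicative mean-one gamma frailties: a patient-level frailty whose
  variance is set from the correlation dial `within_corr`, and a
  patient-year-level frailty that tops total dispersion up to `scale`. The
  two dials are independent within the feasible region
  `within_corr <= (scale-1)/scale`; the default correlation 0.2 is a free
  choice (published analyses of this kind select an independent working
  structure and never report the magnitude), picked as "present but modest";
* ~1%/yr adult mortality (deaths at year end), and data-quality injections at
  registry-like rates: 8.1% of patients given an interior zero-demand year,
  3.1% with all weights missing.

The GEE stage is never told the frailty mechanism — it sees only counts.

What the generator does *not* emulate: secular trends in per-patient demand,
incident splenectomies (the flag is fixed per patient, as registries that
record only "status by end of window" force), transfusion scheduling within a
year, hemoglobin targets, emigration, or cure. Passing tests therefore show
the estimators recover the structure *this* data-generating process has; they
cannot show the model is correctly specified for any real registry.

## Numerical choices

* GEE convergence: maximum relative coefficient change ≤ 1e-8, at most 100
  Fisher-scoring iterations, step-halving when the score norm diverges, and a
  linear-predictor cap (η ≤ 30) against overflow on wild starts.
* Initialisation: least squares on log(y + 0.5); LOOCV folds warm-start at the
  full-data fit.
* Exchangeable α is clamped to [0, 0.99]; the moment estimator can go slightly
  negative in small samples where negative exchangeable correlation is not
  meaningful for counts.
* Rank-deficient designs error immediately, naming the collinear columns;
  degenerate outcomes (all zeros, non-integers) error before iteration.
* LMS interpolation clamps out-of-range ages to the nearest tabulated entry
  with a warning rather than extrapolating a Box-Cox power.
* Variance inflation factors are computed on every design and reported, never
  enforced: with uncentred quadratics the VIFs of age/age² pairs are large by
  construction while the base-model VIFs stay small; both facts are visible in
  the pipeline log.

## Problem sizes in the test suite

The suite favours many small, sharply targeted checks: oracle equivalences on
cohorts of 40–80 patients; coverage of the generating coefficients over 200
replicates at 80 patients; LOOCV ranking over 50 seeds at 50 patients;
dispersion and correlation moment checks at ≥ 10⁴ patient-years; Monte-Carlo
oracles at 10⁴ replicates. The bundled demonstration scenario runs the full
pipeline at registry scale (340 prevalent patients, ~1,600 modelled
patient-years) with a compact variant grid. These sizes are the package's own
choices, balancing Monte-Carlo resolution against a test suite a contributor
will actually run.

## Worked example

```{r, eval = FALSE}
lms <- generate_lms_reference()
cohort <- generate_cohort(generator_config(seed = 7), lms)
panel <- backfill_weights(apply_exclusions(cohort$panel)$panel, lms)

scores <- run_variant_grid(panel)          # 16-cell LOOCV grid
final <- select_final(scores)              # parsimony rule
fit <- fit_demand_model(panel, final)
relative_demand_table(fit)                 # RRs, robust CIs, p-values
peak_covariate(fit, "age")

pop <- generate_population_projection(2005:2024)
forecast <- run_scenarios(fit, patient_state(panel, lms), lms,
                          estimate_incidence(cohort$panel, pop), pop,
                          estimate_mortality(cohort$panel),
                          horizon = 15, base_year = 2009)
```

Or in one call: `run_pipeline(system.file("extdata", "demo_config.yaml",
package = "tmdemand"), out_dir = "demo_out")`.

## Limitations

* The forecast conditions on the fitted mean model; structural breaks
  (curative therapy, changed transfusion policy) are out of scope, as are
  donor-supply and costing questions.
* Existing patients never emigrate or stop transfusion; the only attrition is
  adult mortality.
* Entrant-count errors are treated as independent across strata and years; a
  real census forecast-error model would induce correlation and widen the
  intervals somewhat.
* The incidence window is short in the bundled scenarios, so the incidence
  estimate is noisy (a handful of entrants per year); the package reports it
  with its inputs so users can substitute registry-grade rates.
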