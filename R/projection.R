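#' Estimate age- and sex-specific incidence of new transfusion-dependent cases
#'
#' A patient's entry year is their first year with recorded demand. Entries in
#' the first panel year are prevalent (left-truncated), so incidence is counted
#' over the later window years: rate = incident entries / stratum person-years
#' from the population history.
#'
#' @param panel patient panel (pre- or post-exclusion).
#' @param population population counts (a `population_projection`) covering the
#'   incidence window years.
#' @param window years over which to count incident cases; defaults to all
#'   panel years after the first.
#' @return list of class `incidence_rates`: `rates` (data.frame `sex`,
#'   `age_group`, `rate` per person-year), `overall_per_100k`, `n_cases`,
#'   `person_years`.
#' @export
estimate_incidence <- function(panel, population, window = NULL) {
  years <- sort(unique(panel$year))
  if (is.null(window)) window <- years[years > min(years)]
  first <- tapply(panel$year, panel$patient_id, min)
  entry_age <- tapply(panel$age_years, panel$patient_id, function(a) a[1])
  ord <- vapply(split(seq_len(nrow(panel)), panel$patient_id), function(i)
    i[which.min(panel$year[i])], integer(1))
  new <- data.frame(year = panel$year[ord], sex = panel$sex[ord],
                    age = panel$age_years[ord])
  new <- new[new$year %in% window, , drop = FALSE]
  new$age_group <- age_group(new$age)

  pop <- population[population$year %in% window, , drop = FALSE]
  if (nrow(pop) == 0) stop("population history does not cover the incidence window")
  py <- stats::aggregate(count ~ sex + age_group, data = pop, FUN = sum)
  names(py)[names(py) == "count"] <- "person_years"

  grid <- expand.grid(sex = c("male", "female"), age_group = AGE_GROUPS,
                      stringsAsFactors = FALSE)
  counts <- if (nrow(new) > 0) {
    cnt <- stats::aggregate(rep(1, nrow(new)) ~ sex + age_group, data = new,
                            FUN = sum)
    names(cnt)[3] <- "n"
    cnt
  } else data.frame(sex = character(), age_group = character(), n = numeric())
  rates <- merge(merge(grid, py, all.x = TRUE), counts, all.x = TRUE)
  rates$n[is.na(rates$n)] <- 0
  zero_py <- is.na(rates$person_years) | rates$person_years == 0
  if (any(zero_py & rates$n > 0))
    warning("strata with cases but zero person-years; rate set to 0")
  rates$rate <- ifelse(zero_py, 0, rates$n / rates$person_years)
  total_py <- sum(rates$person_years, na.rm = TRUE)
  structure(list(
    rates = rates[, c("sex", "age_group", "rate")],
    overall_per_100k = sum(rates$n) / total_py * 1e5,
    n_cases = sum(rates$n), person_years = total_py),
    class = "incidence_rates")
}

#' Estimate the annual adult mortality rate from the observed panel
#'
#' Deaths at ages 20+ divided by adult person-years at risk. Deaths are taken
#' to occur at the end of the death year (the death year carries a demand row
#' and counts as a year at risk), so adult person-years equal the adult panel
#' rows.
#'
#' @param panel patient panel with a `death_year` column.
#' @return annual death probability for ages >= 20.
#' @export
estimate_mortality <- function(panel) {
  at_risk <- sum(panel$age_years >= ADULT_AGE)
  if (at_risk == 0) stop("no adult person-years observed")
  per_patient <- !duplicated(panel$patient_id)
  deaths <- sum(!is.na(panel$death_year[per_patient]) &
                  panel$death_year[per_patient] <= max(panel$year))
  deaths / at_risk
}

# effective adult mortality in projection year t under a linear reduction r
# phased in over `ramp` years
effective_mortality <- function(rate, t, reduction = 0, ramp = 10) {
  rate * (1 - reduction * pmin(t, ramp) / ramp)
}

#' Snapshot of patient covariates at the projection baseline
#'
#' Takes each surviving patient's last observed panel row and records the
#' covariates needed to project them forward, including the LMS z-score of the
#' last observed weight (evaluated at min(age, 20)).
#'
#' @param panel filtered patient panel with complete weights.
#' @param lms an [lms_reference()].
#' @param base_year baseline calendar year (default: last panel year).
#' @return data.frame, one row per surviving patient: `patient_id`, `sex`,
#'   `age`, `weight`, `z`, `female`, `splenectomy`, `year_tx`.
#' @export
patient_state <- function(panel, lms, base_year = max(panel$year)) {
  alive <- is.na(panel$death_year) | panel$death_year > base_year
  panel <- panel[alive & panel$year <= base_year, , drop = FALSE]
  last <- vapply(split(seq_len(nrow(panel)), panel$patient_id), function(i)
    i[which.max(panel$year[i])], integer(1))
  first_active <- tapply(ifelse(panel$units > 0, panel$year, NA),
                         panel$patient_id,
                         function(x) if (all(is.na(x))) NA else min(x, na.rm = TRUE))
  s <- panel[last, , drop = FALSE]
  # carry age/weight to the baseline year if the last row is earlier
  gap <- base_year - s$year
  age0 <- s$age_years + gap
  w0 <- project_weight(s$weight_kg, s$sex, s$age_years, age0, lms)
  p <- lms_params(lms, s$sex, pmin(age0, ADULT_AGE) * 12)
  data.frame(patient_id = s$patient_id, sex = s$sex, age = age0, weight = w0,
             z = lms_z(w0, p$L, p$M, p$S),
             female = as.numeric(s$sex == "female"),
             splenectomy = as.numeric(s$splenectomy),
             year_tx = base_year - unname(first_active[s$patient_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Project aggregate demand from existing patients
#'
#' Each surviving patient is aged forward year by year; weight follows the LMS
#' reference at the patient's constant z-score (capped at the age-20 values);
#' mortality enters as a deterministic survival weight, the product of
#' `1 - m_u` over the adult years up to each horizon year. Year t demand is
#' `sum_i s_i(t) exp(x_i(t)' beta)`; the gradient with respect to `beta`
#' (`sum_i s_i(t) mu_i(t) x_i(t)`) is retained for delta-method intervals.
#'
#' @param fit a `gee_fit` with `$variant` set (see [fit_demand_model()]).
#' @param state baseline covariates from [patient_state()].
#' @param lms an [lms_reference()].
#' @param mortality_rate annual adult death probability.
#' @param horizon number of years to project.
#' @param reduction fractional mortality reduction reached linearly over
#'   `ramp` years (0 = constant mortality).
#' @param ramp phase-in period of the reduction, years.
#' @return list: `units` (length-`horizon` vector), `gradient`
#'   (`horizon x p` matrix), `years_ahead`.
#' @export
project_existing <- function(fit, state, lms, mortality_rate, horizon,
                             reduction = 0, ramp = 10) {
  if (is.null(fit$variant)) stop("fit must carry its variant; use fit_demand_model()")
  p <- length(fit$beta)
  units <- numeric(horizon)
  grad <- matrix(0, horizon, p, dimnames = list(NULL, fit$terms))
  surv <- rep(1, nrow(state))
  weight <- state$weight
  for (t in seq_len(horizon)) {
    age_t <- state$age + t
    grow <- age_t <= ADULT_AGE & state$age < ADULT_AGE
    if (any(grow)) {
      pr <- lms_params(lms, state$sex[grow], pmin(age_t[grow], ADULT_AGE) * 12)
      weight[grow] <- lms_inverse(state$z[grow], pr$L, pr$M, pr$S)
    }
    m_t <- effective_mortality(mortality_rate, t, reduction, ramp)
    surv <- surv * ifelse(age_t >= ADULT_AGE, 1 - m_t, 1)
    values <- list(age = age_t, weight = weight, female = state$female,
                   splenectomy = state$splenectomy,
                   year_tx = state$year_tx + t)
    X <- design_from_values(fit$terms, values)
    mu <- as.vector(exp(X %*% fit$beta))
    units[t] <- sum(surv * mu)
    grad[t, ] <- colSums(X * (surv * mu))
  }
  list(units = units, gradient = grad, years_ahead = seq_len(horizon))
}

#' Per-stratum mean covariates of the fitted cohort
#'
#' Group means used to represent incident cases: mean weight z-score and
#' splenectomy prevalence per sex x age-group stratum, computed from the
#' baseline patient state. Empty strata fall back to the overall mean with a
#' warning.
#'
#' @param state baseline covariates from [patient_state()].
#' @param lms an [lms_reference()].
#' @return data.frame: `sex`, `age_group`, `z`, `splenectomy`, `female`,
#'   `n` (patients informing the stratum).
#' @export
stratum_covariates <- function(state, lms) {
  g <- age_group(state$age)
  grid <- expand.grid(sex = c("male", "female"), age_group = AGE_GROUPS,
                      stringsAsFactors = FALSE)
  grid$z <- NA_real_; grid$splenectomy <- NA_real_; grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- state$sex == grid$sex[i] & as.character(g) == grid$age_group[i]
    grid$n[i] <- sum(sel)
    if (any(sel)) {
      grid$z[i] <- mean(state$z[sel])
      grid$splenectomy[i] <- mean(state$splenectomy[sel])
    }
  }
  if (any(grid$n == 0)) {
    grid$z[grid$n == 0] <- mean(state$z)
    grid$splenectomy[grid$n == 0] <- mean(state$splenectomy)
  }
  grid$female <- as.numeric(grid$sex == "female")
  grid
}

# midpoint entry age of each age-group stratum
ENTRY_AGE <- c("0-4" = 2, "5-9" = 7, "10-19" = 14.5, "20-59" = 39.5)

#' Project aggregate demand from incident cases
#'
#' Expected entrants in stratum g of year s are `rate_g x population_g(s)`.
#' Each entry cohort enters at the midpoint age of its stratum, contributes a
#' full year of demand in its entry year, then ages forward with weight along
#' the LMS curve at the stratum mean z-score and adult mortality attrition;
#' demand accumulates across entry cohorts. The variance of the entrant counts
#' (from the population forecast CV) is propagated: each cohort's contribution
#' variance in year t is (per-entrant demand)^2 x Var(n).
#'
#' @param fit a `gee_fit` with `$variant` set.
#' @param incidence an `incidence_rates` object from [estimate_incidence()].
#' @param population a `population_projection` covering the horizon years.
#' @param group_covariates stratum means from [stratum_covariates()].
#' @param lms an [lms_reference()].
#' @param mortality_rate annual adult death probability.
#' @param horizon number of years to project.
#' @param base_year baseline calendar year (entrants appear from
#'   `base_year + 1`).
#' @param reduction,ramp mortality-reduction scenario as in
#'   [project_existing()].
#' @return list: `units`, `gradient` (`horizon x p`), `count_var`
#'   (per-year variance of demand from entrant-count forecast error),
#'   `years_ahead`.
#' @export
project_new_cases <- function(fit, incidence, population, group_covariates,
                              lms, mortality_rate, horizon, base_year,
                              reduction = 0, ramp = 10) {
  if (is.null(fit$variant)) stop("fit must carry its variant; use fit_demand_model()")
  p <- length(fit$beta)
  units <- numeric(horizon)
  grad <- matrix(0, horizon, p, dimnames = list(NULL, fit$terms))
  count_var <- numeric(horizon)
  rates <- incidence$rates
  for (i in seq_len(nrow(rates))) {
    rate_g <- rates$rate[i]
    if (rate_g == 0) next
    sx <- rates$sex[i]; ag <- rates$age_group[i]
    cov_g <- group_covariates[group_covariates$sex == sx &
                                group_covariates$age_group == ag, , drop = FALSE]
    if (nrow(cov_g) == 0 || is.na(cov_g$z))
      stop("missing stratum covariates for ", sx, " ", ag)
    entry_age <- ENTRY_AGE[[ag]]
    for (s in seq_len(horizon)) {
      yr <- base_year + s
      pg <- population[population$year == yr & population$sex == sx &
                         population$age_group == ag, , drop = FALSE]
      if (nrow(pg) == 0)
        stop("population projection does not cover ", sx, " ", ag, " in ", yr)
      n_gs <- rate_g * pg$count[1]
      var_n <- (rate_g * pg$count[1] * pg$cv[1])^2
      if (n_gs == 0 && var_n == 0) next
      # per-entrant expected demand path from entry year s to the horizon
      surv <- 1
      for (t in s:horizon) {
        age_t <- entry_age + (t - s)
        m_t <- effective_mortality(mortality_rate, t, reduction, ramp)
        if (t > s) surv <- surv * (if (age_t >= ADULT_AGE) 1 - m_t else 1)
        pr <- lms_params(lms, sx, pmin(age_t, ADULT_AGE) * 12)
        w_t <- lms_inverse(cov_g$z, pr$L, pr$M, pr$S)
        values <- list(age = age_t, weight = w_t, female = cov_g$female,
                       splenectomy = cov_g$splenectomy, year_tx = t - s)
        X <- design_from_values(fit$terms, values)
        mu <- as.vector(exp(X %*% fit$beta))
        d <- surv * mu
        units[t] <- units[t] + n_gs * d
        grad[t, ] <- grad[t, ] + n_gs * d * X[1, ]
        count_var[t] <- count_var[t] + d^2 * var_n
      }
    }
  }
  list(units = units, gradient = grad, count_var = count_var,
       years_ahead = seq_len(horizon))
}

#' Delta-method prediction interval for an aggregate demand total
#'
#' First-order variance of the total: `g' Sigma g` from the GEE coefficient
#' uncertainty plus the independent entrant-count forecast variance. The 95%
#' interval uses z = 1.96.
#'
#' @param point projected total (units).
#' @param gradient gradient of the total with respect to the coefficients.
#' @param robust_cov sandwich covariance of the coefficients.
#' @param count_var additional variance from entrant-count forecast error.
#' @param level coverage level (default 0.95).
#' @return named vector `c(lo, hi)`.
#' @export
delta_method_pi <- function(point, gradient, robust_cov, count_var = 0,
                            level = 0.95) {
  gradient <- as.numeric(gradient)
  ev <- eigen(robust_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance matrix is not positive semi-definite")
  v <- as.numeric(t(gradient) %*% robust_cov %*% gradient) + count_var
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm((1 + level) / 2)
  half <- z * sqrt(max(v, 0))
  c(lo = point - half, hi = point + half)
}

#' Run baseline and mortality-reduction forecast scenarios
#'
#' Produces the full forecast decomposition (existing patients, incident
#' cases, total, 95% prediction interval) for each mortality scenario. The
#' reduction is phased in linearly over `ramp` years; scenario `r = 0` is the
#' baseline. Coefficient uncertainty is shared between the existing and
#' new-case components (their gradients are summed before the delta method);
#' entrant-count forecast error is added independently.
#'
#' @param fit a `gee_fit` with `$variant` set.
#' @param state baseline covariates from [patient_state()].
#' @param lms an [lms_reference()].
#' @param incidence an `incidence_rates` object.
#' @param population a `population_projection` covering the horizon.
#' @param mortality_rate annual adult death probability.
#' @param horizon projection length in years.
#' @param base_year baseline calendar year.
#' @param reductions mortality-reduction fractions, one scenario each.
#' @param ramp reduction phase-in years.
#' @return data.frame of class `cohort_forecast`: `scenario`, `year`,
#'   `existing_units`, `newcase_units`, `total_units`, `pi_lo`, `pi_hi`.
#' @export
run_scenarios <- function(fit, state, lms, incidence, population,
                          mortality_rate, horizon, base_year,
                          reductions = c(0, 0.4, 0.8), ramp = 10) {
  group_cov <- stratum_covariates(state, lms)
  out <- list()
  for (r in reductions) {
    ex <- project_existing(fit, state, lms, mortality_rate, horizon,
                           reduction = r, ramp = ramp)
    nc <- project_new_cases(fit, incidence, population, group_cov, lms,
                            mortality_rate, horizon, base_year,
                            reduction = r, ramp = ramp)
    pis <- vapply(seq_len(horizon), function(t)
      delta_method_pi(ex$units[t] + nc$units[t],
                      ex$gradient[t, ] + nc$gradient[t, ],
                      fit$robust_cov, nc$count_var[t]),
      numeric(2))
    lab <- if (r == 0) "baseline" else sprintf("mortality-%d", round(100 * r))
    out[[length(out) + 1]] <- data.frame(
      scenario = lab, year = base_year + seq_len(horizon),
      existing_units = ex$units, newcase_units = nc$units,
      total_units = ex$units + nc$units,
      pi_lo = pis[1, ], pi_hi = pis[2, ], stringsAsFactors = FALSE)
  }
  fc <- do.call(rbind, out)
  rownames(fc) <- NULL
  class(fc) <- c("cohort_forecast", "data.frame")
  fc
}

#' Total and annualized growth between two demand levels
#'
#' @param start_units,end_units demand totals (units).
#' @param n_years number of years between them.
#' @return list: `percent_change` (total, %) and `annual_rate`
#'   (geometric, %/yr).
#' @export
growth_summary <- function(start_units, end_units, n_years) {
  if (start_units == 0) stop("start_units must be non-zero")
  if (n_years <= 0) stop("n_years must be positive")
  list(percent_change = (end_units - start_units) / start_units * 100,
       annual_rate = ((end_units / start_units)^(1 / n_years) - 1) * 100)
}

#' @describeIn growth_summary growth between two years of a forecast table
#'   (totals may also come from observed data for the start year).
#' @param forecast a `cohort_forecast`.
#' @param start_year,end_year calendar years present in the forecast (or
#'   `start_units` supplied directly via `start_override`).
#' @param scenario scenario label to use.
#' @param start_override optional observed total for `start_year` when it
#'   predates the forecast.
#' @export
forecast_growth <- function(forecast, start_year, end_year,
                            scenario = "baseline", start_override = NULL) {
  fc <- forecast[forecast$scenario == scenario, , drop = FALSE]
  endv <- fc$total_units[fc$year == end_year]
  if (length(endv) != 1) stop("end_year not in forecast")
  startv <- if (!is.null(start_override)) start_override else
    fc$total_units[fc$year == start_year]
  if (length(startv) != 1) stop("start_year not in forecast and no override given")
  growth_summary(startv, endv, end_year - start_year)
}

#' Share of total demand contributed by incident cases
#'
#' @param total_units total demand.
#' @param existing_units demand from existing patients.
#' @return percentage share of new cases, `(total - existing)/total * 100`.
#' @export
newcase_share <- function(total_units, existing_units) {
  (total_units - existing_units) / total_units * 100
}

#' Monte-Carlo check of the deterministic mortality weighting
#'
#' Simulates individual adult deaths as Bernoulli draws and accumulates
#' realized demand; used to validate that the survival-weight expectation in
#' [project_existing()] matches the stochastic process. Not part of the
#' forecasting path.
#'
#' @inheritParams project_existing
#' @param n_rep Monte-Carlo replicates.
#' @return list: `mean` (per-year mean of simulated totals), `se` (per-year
#'   Monte-Carlo standard errors).
#' @export
project_existing_mc <- function(fit, state, lms, mortality_rate, horizon,
                                n_rep = 10000, reduction = 0, ramp = 10) {
  # deterministic per-patient demand paths without mortality
  mu_path <- matrix(0, nrow(state), horizon)
  adult_year <- matrix(FALSE, nrow(state), horizon)
  weight <- state$weight
  for (t in seq_len(horizon)) {
    age_t <- state$age + t
    grow <- age_t <= ADULT_AGE & state$age < ADULT_AGE
    if (any(grow)) {
      pr <- lms_params(lms, state$sex[grow], pmin(age_t[grow], ADULT_AGE) * 12)
      weight[grow] <- lms_inverse(state$z[grow], pr$L, pr$M, pr$S)
    }
    values <- list(age = age_t, weight = weight, female = state$female,
                   splenectomy = state$splenectomy, year_tx = state$year_tx + t)
    X <- design_from_values(fit$terms, values)
    mu_path[, t] <- as.vector(exp(X %*% fit$beta))
    adult_year[, t] <- age_t >= ADULT_AGE
  }
  m_t <- effective_mortality(mortality_rate, seq_len(horizon), reduction, ramp)
  totals <- matrix(0, n_rep, horizon)
  for (i in seq_len(nrow(state))) {
    # survival indicator paths for patient i across replicates
    alive <- matrix(TRUE, n_rep, horizon)
    for (t in seq_len(horizon)) {
      die <- adult_year[i, t] & stats::runif(n_rep) < m_t[t]
      if (t == 1) alive[, t] <- !die else alive[, t] <- alive[, t - 1] & !die
    }
    totals <- totals + alive * matrix(mu_path[i, ], n_rep, horizon, byrow = TRUE)
  }
  list(mean = colMeans(totals),
       se = apply(totals, 2, stats::sd) / sqrt(n_rep))
}

#' @export
print.cohort_forecast <- function(x, ...) {
  cat("Cohort demand forecast:", length(unique(x$scenario)), "scenario(s),",
      min(x$year), "-", max(x$year), "\n")
  print(as.data.frame(utils::head(x, 8)), digits = 1)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Write a forecast CSV
#'
#' @param forecast a `cohort_forecast`.
#' @param path output path.
#' @param header optional comment line(s).
#' @export
write_forecast <- function(forecast, path, header = NULL) {
  write_csv_header(as.data.frame(forecast), path, header)
  invisible(path)
}

#' Plot forecast trajectories with prediction intervals
#'
#' @param forecast a `cohort_forecast`.
#' @param path optional file path; if given, a PNG is written.
#' @return the ggplot object, invisibly.
#' @export
plot_forecast <- function(forecast, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  gg <- ggplot2::ggplot(forecast,
          ggplot2::aes(x = .data$year, y = .data$total_units,
                       colour = .data$scenario, fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_lo, ymax = .data$pi_hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Predicted blood demand (units)",
                  title = "Projected annual red-cell demand") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, gg, width = 7, height = 4.5, dpi = 150)
  invisible(gg)
}
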