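#' Configuration for the synthetic cohort generator
#'
#' Collects the generating parameters of a synthetic transfusion-dependent
#' thalassemia cohort: log-linear demand coefficients, overdispersion, within-
#' patient correlation, adult mortality, and incidence of new cases.
#'
#' The defaults emulate the observed features of a chronically transfused
#' thalassemia-major registry: roughly 340 regular patients, mean annual demand
#' of about 38.7 red-cell units, inverted-U age and weight effects on the
#' log-mean demand, about 6% lower demand in females and 15% lower after
#' splenectomy, Pearson overdispersion of 1.71, around 1% annual adult
#' mortality, and an incidence of new transfusion-dependent cases near
#' 0.13 per 100,000 person-years in a population of seven million.
#'
#' @param n_patients number of prevalent patients at the start of the window.
#' @param years inclusive calendar-year range `c(first, last)`; span >= 2.
#' @param beta named coefficient vector on the log scale with elements
#'   `(Intercept)`, `age`, `age2`, `weight`, `weight2`, `female`,
#'   `splenectomy`. An `NA` intercept is calibrated at generation time so that
#'   the cohort-average expected demand equals `mean_units`.
#' @param mean_units target mean annual demand (units/patient-year), used only
#'   when the intercept is `NA`.
#' @param scale Pearson overdispersion target `phi >= 1`.
#' @param within_corr within-patient demand correlation `rho` in `[0, 1)`;
#'   must satisfy `rho <= (phi - 1)/phi` (a shared patient frailty cannot
#'   induce more correlation than the total overdispersion allows).
#' @param mortality_rate_adult annual death probability at ages >= 20.
#' @param incidence_per_100k annual rate of incident transfusion-dependent
#'   cases per 100,000 population.
#' @param population_size population base to which the incidence applies.
#' @param female_prob,splenectomy_prev cohort composition probabilities.
#' @param prop_irregular fraction of patients given an interior zero-demand
#'   year (irregular transfusion pattern, excluded downstream).
#' @param prop_missing_weight fraction of patients with all weights missing.
#' @param seed RNG seed.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 340,
                             years = c(2005, 2009),
                             beta = c("(Intercept)" = NA_real_,
                                      age = log(1.04), age2 = log(0.9992),
                                      weight = log(1.04), weight2 = log(0.9997),
                                      female = log(0.94), splenectomy = log(0.85)),
                             mean_units = 38.7,
                             scale = 1.71,
                             within_corr = 0.2,
                             mortality_rate_adult = 0.0096,
                             incidence_per_100k = 0.13,
                             population_size = 7e6,
                             female_prob = 0.504,
                             splenectomy_prev = 0.362,
                             prop_irregular = 0.081,
                             prop_missing_weight = 0.031,
                             seed = 1L) {
  stopifnot(length(years) == 2, diff(years) >= 1)
  need <- c("(Intercept)", "age", "age2", "weight", "weight2", "female", "splenectomy")
  if (!all(need %in% names(beta)))
    stop("beta must be named with: ", paste(need, collapse = ", "))
  if (scale < 1) stop("scale (overdispersion phi) must be >= 1")
  if (within_corr < 0 || within_corr >= 1) stop("within_corr must be in [0, 1)")
  if (within_corr > (scale - 1) / scale + 1e-12)
    stop("within_corr must be <= (scale - 1)/scale = ",
         signif((scale - 1) / scale, 3),
         " for a patient-frailty mechanism at this overdispersion")
  rates <- c(mortality_rate_adult, prop_irregular, prop_missing_weight,
             female_prob, splenectomy_prev)
  if (any(rates < 0 | rates > 1)) stop("all probabilities must be in [0, 1]")
  if (incidence_per_100k < 0 || population_size < 0) stop("rates must be non-negative")
  structure(list(
    n_patients = as.integer(n_patients), years = as.integer(years),
    beta = beta[need], mean_units = mean_units, scale = scale,
    within_corr = within_corr, mortality_rate_adult = mortality_rate_adult,
    incidence_per_100k = incidence_per_100k, population_size = population_size,
    female_prob = female_prob, splenectomy_prev = splenectomy_prev,
    prop_irregular = prop_irregular, prop_missing_weight = prop_missing_weight,
    seed = as.integer(seed)), class = "generator_config")
}

#' Generate a synthetic LMS weight-for-age reference
#'
#' Builds a smooth, strictly increasing median-weight curve from birth to 240
#' months as the sum of an infancy/childhood and a pubertal logistic component,
#' with a Box-Cox power `L` and a coefficient of variation `S` that grows
#' linearly with age. This is a synthetic stand-in with the shape and
#' magnitudes of a national weight-for-age reference, not a copy of one.
#'
#' @param agemos tabulated ages in months.
#' @param w_birth intercept (kg) of the median curve.
#' @param a1,t1,s1 amplitude (kg), midpoint and width (months) of the
#'   childhood logistic, per sex (named vectors `male`/`female`).
#' @param a2,t2,s2 same for the pubertal logistic.
#' @param L Box-Cox power (constant across age).
#' @param s0,s_slope S at birth and its linear increase over 240 months.
#' @return an [lms_reference()].
#' @export
generate_lms_reference <- function(agemos = seq(0, 240, by = 3),
                                   w_birth = 3.4,
                                   a1 = c(male = 30, female = 29),
                                   t1 = c(male = 60, female = 60),
                                   s1 = c(male = 40, female = 40),
                                   a2 = c(male = 35, female = 22),
                                   t2 = c(male = 168, female = 150),
                                   s2 = c(male = 18, female = 18),
                                   L = -1.2, s0 = 0.10, s_slope = 0.10) {
  rows <- lapply(c("male", "female"), function(sx) {
    M <- w_birth +
      a1[[sx]] / (1 + exp(-(agemos - t1[[sx]]) / s1[[sx]])) +
      a2[[sx]] / (1 + exp(-(agemos - t2[[sx]]) / s2[[sx]]))
    if (any(diff(M) <= 0))
      stop("median curve must be strictly increasing in age; check amplitudes")
    S <- s0 + s_slope * agemos / 240
    if (any(S <= 0)) stop("S must be positive")
    data.frame(sex = sx, agemos = agemos, L = L, M = M, S = S)
  })
  d <- do.call(rbind, rows)
  lms_reference(d$sex, d$agemos, d$L, d$M, d$S)
}

# expected demand on the log-linear scale for generator covariates
generator_mu <- function(beta, age, weight, female, splen) {
  lp <- beta[["age"]] * age + beta[["age2"]] * age^2 +
    beta[["weight"]] * weight + beta[["weight2"]] * weight^2 +
    beta[["female"]] * female + beta[["splenectomy"]] * splen
  if (!is.na(beta[["(Intercept)"]])) lp <- lp + beta[["(Intercept)"]]
  lp
}

#' Generate a synthetic patient cohort
#'
#' Simulates a roster of prevalent patients plus incident cases, with annual
#' transfusion demand following an overdispersed, within-patient-correlated
#' Poisson model: demand for patient i in year t is Poisson with mean
#' `u_i * e_it * exp(x_it' beta)` where `u_i` and `e_it` are independent
#' mean-one gamma frailties. The patient-level frailty variance is set from
#' `within_corr` and the year-level variance tops total dispersion up to
#' `scale`, so the two dials are controlled jointly but independently within
#' the feasible region. Weights follow the LMS reference at a fixed per-patient
#' z-score; adults (>= 20y) face the configured annual mortality; incident
#' cases enter at age 1 at the configured incidence.
#'
#' @param config a [generator_config()].
#' @param lms an [lms_reference()] covering ages 0-20 for both sexes.
#' @return a list of class `synthetic_cohort` with elements `roster` (one row
#'   per patient: `patient_id`, `sex`, `birth_year`, `splenectomy`, `z`,
#'   `entry_year`, `death_year`), `panel` (patient-year rows: `patient_id`,
#'   `year`, `sex`, `age_years`, `weight_kg`, `splenectomy`, `units`,
#'   `death_year`), and `truth` (the config, with the calibrated intercept
#'   filled in).
#' @export
generate_cohort <- function(config, lms) {
  stopifnot(inherits(config, "generator_config"))
  for (sx in c("male", "female")) {
    sub <- lms[lms$sex == sx, , drop = FALSE]
    if (nrow(sub) == 0 || min(sub$agemos) > 12 || max(sub$agemos) < 240)
      stop("LMS reference must cover ages 0-20 years for sex '", sx, "'")
  }
  set.seed(config$seed)
  y0 <- config$years[1]; y1 <- config$years[2]
  n <- config$n_patients

  roster <- list()
  span <- y1 - y0
  if (n > 0) {
    # prevalent patients are already under transfusion at the window start
    # (age >= 1 in the first year); entries during the window come from the
    # incidence mechanism below
    age_last <- 1 + span + round((55 - span) * stats::rbeta(n, 1.5, 2.6))
    roster[[1]] <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      sex = ifelse(stats::runif(n) < config$female_prob, "female", "male"),
      birth_year = y1 - age_last,
      splenectomy = as.integer(stats::runif(n) < config$splenectomy_prev),
      z = stats::rnorm(n), entry_year = y0, stringsAsFactors = FALSE)
  }
  # incident cases enter at age 1 in years after the first window year
  rate <- config$incidence_per_100k / 1e5 * config$population_size
  k <- n
  for (y in seq(y0 + 1, y1)) {
    m <- if (rate > 0) stats::rpois(1, rate) else 0L
    if (m == 0) next
    roster[[length(roster) + 1]] <- data.frame(
      patient_id = sprintf("P%04d", k + seq_len(m)),
      sex = ifelse(stats::runif(m) < config$female_prob, "female", "male"),
      birth_year = y - 1,
      splenectomy = as.integer(stats::runif(m) < config$splenectomy_prev),
      z = stats::rnorm(m), entry_year = y, stringsAsFactors = FALSE)
    k <- k + m
  }
  roster <- if (length(roster)) do.call(rbind, roster) else
    data.frame(patient_id = character(), sex = character(),
               birth_year = integer(), splenectomy = integer(),
               z = numeric(), entry_year = integer())
  roster$death_year <- rep(NA_integer_, nrow(roster))

  if (nrow(roster) == 0) {
    empty <- data.frame(patient_id = character(), year = integer(),
                        sex = character(), age_years = numeric(),
                        weight_kg = numeric(), splenectomy = integer(),
                        units = integer(), death_year = integer())
    return(structure(list(roster = roster, panel = empty, truth = config),
                     class = "synthetic_cohort"))
  }

  # adult mortality: first Bernoulli success over the window's adult years
  m <- config$mortality_rate_adult
  if (m > 0) {
    for (i in seq_len(nrow(roster))) {
      for (y in seq(max(y0, roster$entry_year[i]), y1)) {
        if (y - roster$birth_year[i] >= ADULT_AGE && stats::runif(1) < m) {
          roster$death_year[i] <- y
          break
        }
      }
    }
  }

  # panel rows: entry year (or window start) through the death year (deaths
  # occur at the end of the year, after that year's transfusions), ages >= 1
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    from <- max(y0, roster$entry_year[i])
    to <- if (is.na(roster$death_year[i])) y1 else roster$death_year[i]
    if (to < from) return(NULL)
    yrs <- from:to
    age <- yrs - roster$birth_year[i]
    keep <- age >= 1
    if (!any(keep)) return(NULL)
    data.frame(patient_id = roster$patient_id[i], year = yrs[keep],
               sex = roster$sex[i], age_years = age[keep],
               splenectomy = roster$splenectomy[i],
               z = roster$z[i], death_year = roster$death_year[i],
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)

  p <- lms_params(lms, panel$sex, pmin(panel$age_years, ADULT_AGE) * 12)
  panel$weight_kg <- lms_inverse(panel$z, p$L, p$M, p$S)

  beta <- config$beta
  lp <- generator_mu(beta, panel$age_years, panel$weight_kg,
                     as.numeric(panel$sex == "female"), panel$splenectomy)
  if (is.na(beta[["(Intercept)"]])) {
    beta[["(Intercept)"]] <- log(config$mean_units) - log(mean(exp(lp)))
    lp <- lp + beta[["(Intercept)"]]
  }
  mu <- exp(lp)

  # frailty decomposition: patient-level variance from rho, year-level tops up
  # Pearson dispersion to phi (both relative to the realized mean demand)
  mu_bar <- mean(mu)
  v_b <- config$within_corr * config$scale / mu_bar
  c_tot <- (config$scale - 1) / mu_bar
  v_w <- max(0, (c_tot - v_b) / (1 + v_b))
  ids <- match(panel$patient_id, roster$patient_id)
  u <- if (v_b > 0) stats::rgamma(nrow(roster), shape = 1 / v_b, rate = 1 / v_b) else
    rep(1, nrow(roster))
  e <- if (v_w > 0) stats::rgamma(nrow(panel), shape = 1 / v_w, rate = 1 / v_w) else
    rep(1, nrow(panel))
  panel$units <- stats::rpois(nrow(panel), u[ids] * e * mu)

  # data-quality features: irregular transfusion gaps and missing weights
  tab <- table(panel$patient_id)
  eligible <- names(tab)[tab >= 3]
  n_irr <- round(config$prop_irregular * nrow(roster))
  if (n_irr > 0 && length(eligible) > 0) {
    irr <- sample(eligible, min(n_irr, length(eligible)))
    for (pid in irr) {
      i <- which(panel$patient_id == pid)
      mid <- i[-c(1, length(i))]
      panel$units[mid[sample.int(length(mid), 1)]] <- 0L
    }
  }
  n_mis <- round(config$prop_missing_weight * nrow(roster))
  if (n_mis > 0) {
    mis <- sample(roster$patient_id, min(n_mis, nrow(roster)))
    panel$weight_kg[panel$patient_id %in% mis] <- NA_real_
  }

  panel$z <- NULL
  truth <- config
  truth$beta <- beta
  structure(list(roster = roster, panel = panel, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic thalassemia cohort:", nrow(x$roster), "patients,",
      nrow(x$panel), "patient-years",
      sprintf("(%d-%d)\n", x$truth$years[1], x$truth$years[2]))
  if (nrow(x$panel))
    cat("  mean annual demand:", round(mean(x$panel$units), 1), "units;",
        sum(!is.na(x$roster$death_year)), "deaths\n")
  invisible(x)
}

# standard demographic strata for incidence and population projections
AGE_GROUPS <- c("0-4", "5-9", "10-19", "20-59")

#' Assign ages to the standard projection age groups
#'
#' @param age ages in years.
#' @return factor with levels `0-4`, `5-9`, `10-19`, `20-59` (ages above 59
#'   are folded into `20-59`; the cohort's oldest patients stay in scope).
#' @export
age_group <- function(age) {
  g <- cut(pmin(age, 59), breaks = c(-Inf, 4, 9, 19, Inf), labels = AGE_GROUPS)
  factor(as.character(g), levels = AGE_GROUPS)
}

#' Generate a synthetic population projection
#'
#' Produces stratified population counts (sex by age group) growing
#' geometrically, each annotated with a forecast coefficient of variation.
#'
#' @param years vector of calendar years to cover.
#' @param base_counts data.frame with columns `sex`, `age_group`, `count`
#'   giving the first-year counts for all 8 strata; the default is a
#'   seven-million-person population with the age structure of a low-fertility
#'   East Asian city.
#' @param growth_rate annual geometric growth rate (default 0.9%/yr).
#' @param cv forecast coefficient of variation attached to every count.
#' @return data.frame of class `population_projection`: `year`, `sex`,
#'   `age_group`, `count`, `cv`.
#' @export
generate_population_projection <- function(years,
                                           base_counts = default_base_counts(),
                                           growth_rate = 0.009,
                                           cv = 0.02) {
  need <- c("sex", "age_group", "count")
  if (!all(need %in% names(base_counts)))
    stop("base_counts needs columns sex, age_group, count")
  if (any(base_counts$count < 0)) stop("population counts must be non-negative")
  base_counts$sex <- normalize_sex(base_counts$sex)
  full <- expand.grid(sex = c("male", "female"), age_group = AGE_GROUPS,
                      stringsAsFactors = FALSE)
  if (nrow(merge(full, base_counts)) < nrow(full))
    stop("base_counts must cover all 8 sex x age-group strata")
  out <- do.call(rbind, lapply(seq_along(years), function(i) {
    d <- base_counts
    d$year <- years[i]
    d$count <- d$count * (1 + growth_rate)^(i - 1)
    d$cv <- cv
    d[, c("year", "sex", "age_group", "count", "cv")]
  }))
  rownames(out) <- NULL
  class(out) <- c("population_projection", "data.frame")
  out
}

#' @rdname generate_population_projection
#' @export
default_base_counts <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 4),
    age_group = rep(AGE_GROUPS, 2),
    count = c(180000, 190000, 430000, 2630000,
              170000, 180000, 410000, 2810000))
}

#' Read / write the patient panel CSV
#'
#' Columns: `patient_id, year, sex, age_years, weight_kg, splenectomy, units,
#' death_year`. Lines starting with `#` are treated as comments.
#'
#' @param path file path.
#' @return panel data.frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("patient_id", "year", "sex", "age_years", "weight_kg",
            "splenectomy", "units")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("panel CSV missing columns: ", paste(miss, collapse = ", "))
  if (!"death_year" %in% names(d)) d$death_year <- NA_integer_
  d$sex <- normalize_sex(d$sex)
  d
}

#' @rdname read_panel
#' @param panel panel data.frame to write.
#' @param header optional comment line(s) prepended to the file.
#' @export
write_panel <- function(panel, path, header = NULL) {
  write_csv_header(panel, path, header)
  invisible(path)
}

#' Read / write the population projection CSV
#'
#' Columns: `year, sex, age_group, count, cv`.
#'
#' @param path file path.
#' @return a `population_projection` data.frame.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("population file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("year", "sex", "age_group", "count")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("population CSV missing columns: ", paste(miss, collapse = ", "))
  if (!"cv" %in% names(d)) d$cv <- 0
  if (any(d$count < 0)) stop("population counts must be non-negative")
  d$sex <- normalize_sex(d$sex)
  class(d) <- c("population_projection", "data.frame")
  d
}

#' @rdname read_population
#' @param pop population projection to write.
#' @param header optional comment line(s).
#' @export
write_population <- function(pop, path, header = NULL) {
  write_csv_header(as.data.frame(pop), path, header)
  invisible(path)
}
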