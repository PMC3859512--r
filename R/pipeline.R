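#' Read a pipeline configuration
#'
#' A single YAML file drives every stage. Recognised keys (all optional, with
#' defaults): `n_patients`, `years` (two-element), `horizon`,
#' `parsimony_delta`, `grid` (`"default"`, `"small"`, or `"interactions"`),
#' `reductions` (mortality-scenario fractions), `seed`, `pop_growth_rate`,
#' `pop_cv`, and any [generator_config()] field under `generator:`.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else as.list(path)
  defaults <- list(n_patients = 340, years = c(2005, 2009), horizon = 15,
                   parsimony_delta = 0.01, grid = "default",
                   reductions = c(0, 0.4, 0.8), seed = 1,
                   pop_growth_rate = 0.009, pop_cv = 0.02,
                   generator = list())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$years <- as.integer(unlist(cfg$years))
  cfg$reductions <- as.numeric(unlist(cfg$reductions))
  cfg
}

pipeline_grid <- function(grid) {
  if (is.list(grid)) return(grid)
  switch(grid,
         default = default_variant_grid(),
         interactions = c(default_variant_grid(), interaction_variant_grid()),
         small = list(model_variant(character()),
                      model_variant(c("age2", "weight2")),
                      model_variant(c("age2", "weight2", "year_tx")),
                      model_variant(c("age2", "weight2"), corr = "exchangeable")),
         stop("unknown grid: ", grid))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full demand-forecasting pipeline
#'
#' Simulates a synthetic cohort (or loads a panel), applies the exclusion
#' filters, completes missing weights, scores the variant grid by LOOCV,
#' selects and fits the final model, estimates incidence and adult mortality,
#' and forecasts aggregate demand under the mortality scenarios. All stage
#' outputs are written to `out_dir`; each CSV carries a header comment with
#' the config hash and seed, so a rerun with the same config is
#' byte-identical.
#'
#' @param config YAML path or list (see [read_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed if given.
#' @param panel optional pre-existing panel data.frame (skips simulation).
#' @param lms optional [lms_reference()] (default: the synthetic reference).
#' @param verbose log progress to stderr.
#' @return invisibly, a list with `fit`, `scores`, `final_variant`,
#'   `forecast`, `incidence`, `mortality`, `exclusions`, `paths`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempdir(), seed = NULL,
                         panel = NULL, lms = NULL, verbose = TRUE) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  hdr <- sprintf("config_md5=%s seed=%d", hash, as.integer(cfg$seed))
  logf <- file.path(out_dir, "run.log")
  log_lines <- c(sprintf("pipeline start: %s", hdr))
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }

  if (is.null(lms)) lms <- generate_lms_reference()

  if (is.null(panel)) {
    gen_args <- cfg$generator
    gen_args$n_patients <- cfg$n_patients
    gen_args$years <- cfg$years
    gen_args$seed <- cfg$seed
    gcfg <- do.call(generator_config, gen_args)
    cohort <- generate_cohort(gcfg, lms)
    panel <- cohort$panel
    say("simulated cohort: %d patients, %d patient-years",
        nrow(cohort$roster), nrow(panel))
  }
  base_year <- max(panel$year)
  pop <- generate_population_projection(
    years = seq(min(panel$year), base_year + cfg$horizon),
    growth_rate = cfg$pop_growth_rate, cv = cfg$pop_cv)

  write_panel(panel, file.path(out_dir, "panel.csv"), hdr)
  write_lms(lms, file.path(out_dir, "lms.csv"), hdr)
  write_population(pop, file.path(out_dir, "population.csv"), hdr)

  excl <- apply_exclusions(panel)
  fitted_panel <- backfill_weights(excl$panel, lms)
  for (i in seq_len(nrow(excl$log)))
    say("excluded (%s): %d patients, %d rows", excl$log$reason[i],
        excl$log$n_patients[i], excl$log$n_rows[i])
  say("modelling panel: %d patients, %d patient-years",
      length(unique(fitted_panel$patient_id)), nrow(fitted_panel))

  grid <- pipeline_grid(cfg$grid)
  scores <- run_variant_grid(fitted_panel, grid, verbose = verbose)
  final <- select_final(scores, cfg$parsimony_delta)
  say("selected variant: %s (%s), parsimony_delta = %g",
      final$label, final$corr, cfg$parsimony_delta)
  fit <- fit_demand_model(fitted_panel, final)
  say("fit: scale = %.3f, max VIF = %.2f", fit$scale, max(fit$vif))

  incidence <- estimate_incidence(panel, pop)
  mortality <- estimate_mortality(panel)
  say("incidence: %.3f per 100k (%d cases); adult mortality: %.2f%%",
      incidence$overall_per_100k, incidence$n_cases, 100 * mortality)

  state <- patient_state(fitted_panel, lms, base_year)
  forecast <- run_scenarios(fit, state, lms, incidence, pop, mortality,
                            cfg$horizon, base_year, cfg$reductions)
  base_total <- sum(panel$units[panel$year == base_year])
  end <- forecast$total_units[forecast$scenario == "baseline" &
                                forecast$year == base_year + cfg$horizon]
  g <- growth_summary(base_total, end, cfg$horizon)
  say("baseline: %d units in %d -> %.0f in %d (%.2f%% total, %.2f%%/yr)",
      base_total, base_year, end, base_year + cfg$horizon,
      g$percent_change, g$annual_rate)

  write_scores(scores, file.path(out_dir, "scores.csv"), hdr)
  write_demand_table(fit, file.path(out_dir, "table2.csv"), hdr)
  write_forecast(forecast, file.path(out_dir, "forecast.csv"), hdr)
  jsonlite::write_json(
    list(header = hdr, beta = as.list(fit$beta),
         robust_cov = fit$robust_cov, scale = fit$scale,
         alpha = fit$alpha, corr = fit$corr, terms = fit$terms,
         variant_extras = fit$variant$extras,
         n_patients = fit$n_patients, n_obs = fit$n_obs),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, logf)

  invisible(list(fit = fit, scores = scores, final_variant = final,
                 forecast = forecast, incidence = incidence,
                 mortality = mortality, exclusions = excl$log,
                 base_year = base_year, base_total = base_total,
                 panel = fitted_panel, state = state, lms = lms,
                 paths = file.path(out_dir, c("panel.csv", "lms.csv",
                                              "population.csv", "scores.csv",
                                              "table2.csv", "forecast.csv",
                                              "fit.json", "run.log"))))
}
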