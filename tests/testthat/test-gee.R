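test_that("intercept-only GEE recovers log of a constant outcome", {
  y <- rep(7, 20)
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  id <- rep(1:4, each = 5)
  for (corr in c("independent", "exchangeable")) {
    fit <- fit_gee(X, y, id, corr = corr)
    expect_equal(unname(fit$beta), log(7), tolerance = 1e-10)
  }
})

test_that("independent GEE equals the Poisson ML root from a Newton oracle", {
  lms <- test_lms()
  panel <- clean_panel(n = 40, seed = 4, lms = lms)
  panel <- panel[seq_len(min(200, nrow(panel))), ]
  d <- build_design(panel, model_variant(c("age2", "weight2")))
  fit <- fit_gee(d$X, d$y, d$id, corr = "independent")
  oracle <- poisson_newton(d$X, d$y)
  expect_lt(max(abs(fit$beta - oracle)), 1e-8)
  # with one observation per patient the equality holds trivially too
  one <- panel[!duplicated(panel$patient_id), ]
  d1 <- build_design(one, model_variant())
  f1 <- fit_gee(d1$X, d1$y, d1$id, corr = "independent")
  expect_lt(max(abs(f1$beta - poisson_newton(d1$X, d1$y))), 1e-8)
})

test_that("robust covariance matches the clustered sandwich on a glm fit", {
  skip_if_not_installed("sandwich")
  lms <- test_lms()
  panel <- clean_panel(n = 50, seed = 6, lms = lms)
  d <- build_design(panel, model_variant(c("age2", "weight2")))
  fit <- fit_gee(d$X, d$y, d$id, corr = "independent")
  df <- data.frame(d$X[, -1], y = d$y, id = d$id, check.names = FALSE)
  g <- glm(y ~ age + weight + female + splenectomy + age2 + weight2,
           data = df, family = poisson())
  vc <- sandwich::vcovCL(g, cluster = df$id, type = "HC0", cadjust = FALSE)
  expect_equal(unname(fit$robust_cov), unname(vc[fit$terms, fit$terms]),
               tolerance = 1e-6)
})

test_that("sandwich covariance does not depend on the scale parameter", {
  # phi appears in B as 1/phi and in M as 1/phi^2, so it cancels in B^-1 M B^-1;
  # the implementation computes the sandwich on the phi-free scale, and the
  # reported robust covariance must equal a direct phi-free evaluation
  lms <- test_lms()
  panel <- clean_panel(n = 30, seed = 9, lms = lms)
  d <- build_design(panel, model_variant())
  fit <- fit_gee(d$X, d$y, d$id, corr = "independent")
  mu <- exp(as.vector(d$X %*% fit$beta))
  B <- crossprod(d$X * sqrt(mu))
  G <- rowsum(d$X * (d$y - mu), d$id)
  direct <- solve(B) %*% crossprod(G) %*% solve(B)
  expect_equal(unname(fit$robust_cov), unname(direct), tolerance = 1e-10)
  expect_gt(fit$scale, 0)
})

test_that("estimates recover the generating coefficients on synthetic data", {
  lms <- test_lms()
  co <- generate_cohort(clean_config(n = 150, seed = 14, scale = 1.71,
                                     within_corr = 0.2), lms)
  truth <- co$truth$beta
  d <- build_design(co$panel, model_variant(c("age2", "weight2")))
  fit <- fit_gee(d$X, d$y, d$id, corr = "independent")
  se <- sqrt(diag(fit$robust_cov))
  map <- c("(Intercept)", "age", "weight", "female", "splenectomy", "age2", "weight2")
  tr <- truth[c("(Intercept)", "age", "weight", "female", "splenectomy",
                "age2", "weight2")]
  expect_true(all(abs(fit$beta[map] - tr) <= 3 * se[map]))
})

test_that("exchangeable alpha goes to zero when demand is uncorrelated", {
  lms <- test_lms()
  co <- generate_cohort(clean_config(n = 2100, seed = 17, scale = 1,
                                     within_corr = 0), lms)
  expect_gte(nrow(co$panel), 1e4)
  d <- build_design(co$panel, model_variant(c("age2", "weight2"),
                                            corr = "exchangeable"))
  fit <- fit_gee(d$X, d$y, d$id, corr = "exchangeable")
  expect_lte(abs(fit$alpha), 0.05)
})

test_that("exchangeable alpha recovers induced within-patient correlation", {
  lms <- test_lms()
  co <- generate_cohort(clean_config(n = 600, seed = 18, scale = 1.71,
                                     within_corr = 0.3), lms)
  d <- build_design(co$panel, model_variant(c("age2", "weight2"),
                                            corr = "exchangeable"))
  fit <- fit_gee(d$X, d$y, d$id, corr = "exchangeable")
  expect_gt(fit$alpha, 0.15)
  expect_lt(fit$alpha, 0.45)
})

test_that("build_design produces the documented columns and flags collinearity", {
  lms <- test_lms()
  panel <- clean_panel(n = 25, seed = 2, lms = lms)
  base <- build_design(panel, model_variant())
  expect_equal(colnames(base$X),
               c("(Intercept)", "age", "weight", "female", "splenectomy"))
  full <- build_design(panel, model_variant(c("age2", "weight2", "year_tx")))
  expect_equal(ncol(full$X), 8)
  expect_true(all(c("age2", "weight2", "year_tx") %in% colnames(full$X)))
  # VIFs are reported for inspection
  expect_named(base$vif, c("age", "weight", "female", "splenectomy"))
  expect_true(all(base$vif >= 1))
  # a duplicated column is rank-deficient
  panel2 <- panel
  panel2$weight_kg <- panel2$age_years  # weight == age => age2 == weight2 etc.
  expect_error(build_design(panel2, model_variant(c("age2", "weight2"))),
               "rank-deficient")
})

test_that("exclusion filters drop infants, irregular patterns, lost weights", {
  lms <- test_lms()
  panel <- clean_panel(n = 20, seed = 5, lms = lms)
  clean <- apply_exclusions(panel)
  expect_equal(nrow(clean$log), 0)
  expect_equal(nrow(clean$panel), nrow(panel))

  # interior zero-demand year => irregular
  pid <- unique(panel$patient_id)[1]
  rows <- which(panel$patient_id == pid)
  panel$units[rows[3]] <- 0
  out <- apply_exclusions(panel)
  expect_true("irregular_transfusion" %in% out$log$reason)
  expect_false(pid %in% out$panel$patient_id)

  # age-0 rows are dropped but the patient retained
  panel2 <- clean_panel(n = 20, seed = 5, lms = lms)
  pid2 <- unique(panel2$patient_id)[2]
  extra <- panel2[panel2$patient_id == pid2, ][1, ]
  extra$age_years <- 0
  extra$year <- extra$year - 1  # precedes the active span: not a gap
  panel2 <- rbind(extra, panel2)
  out2 <- apply_exclusions(panel2)
  expect_true(pid2 %in% out2$panel$patient_id)
  expect_true(all(out2$panel$age_years >= 1))

  # all-missing weights are excluded with a log entry
  panel3 <- clean_panel(n = 20, seed = 5, lms = lms)
  pid3 <- unique(panel3$patient_id)[3]
  panel3$weight_kg[panel3$patient_id == pid3] <- NA
  out3 <- apply_exclusions(panel3)
  expect_true("missing_weights" %in% out3$log$reason)
  expect_false(pid3 %in% out3$panel$patient_id)
})

test_that("relative_demand_table applies the Wald transform correctly", {
  fit <- structure(list(
    beta = c("(Intercept)" = log(40), splenectomy = log(0.85)),
    robust_cov = diag(c(0.001, 0.024^2)),
    terms = c("(Intercept)", "splenectomy")), class = "gee_fit")
  dimnames(fit$robust_cov) <- list(fit$terms, fit$terms)
  tab <- relative_demand_table(fit)
  expect_equal(tab$rr, 0.85)
  expect_equal(round(tab$ci_lo, 2), 0.81)
  expect_equal(round(tab$ci_hi, 2), 0.89)
  expect_lt(tab$p, 0.001)
  # a zero coefficient gives RR 1 with a CI containing 1
  fit$beta["splenectomy"] <- 0
  tab0 <- relative_demand_table(fit)
  expect_equal(tab0$rr, 1)
  expect_true(tab0$ci_lo < 1 && tab0$ci_hi > 1)
})

test_that("robust CI width shrinks as the cohort grows", {
  lms <- test_lms()
  widths <- vapply(c(40, 160, 640), function(n) {
    panel <- clean_panel(n = n, seed = 31, lms = lms)
    d <- build_design(panel, model_variant())
    fit <- fit_gee(d$X, d$y, d$id)
    tab <- relative_demand_table(fit)
    tab$ci_hi[tab$term == "female"] - tab$ci_lo[tab$term == "female"]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("peak_covariate is the quadratic argmax with guard rails", {
  fit <- structure(list(
    beta = c("(Intercept)" = 1, age = 0.04, age2 = -0.0008),
    terms = c("(Intercept)", "age", "age2")), class = "gee_fit")
  expect_equal(peak_covariate(fit, "age"), 25)
  fit$beta["age"] <- 0
  expect_equal(peak_covariate(fit, "age"), 0)
  fit$beta["age2"] <- 0.001
  expect_error(peak_covariate(fit, "age"), "no interior maximum")
  expect_error(peak_covariate(fit, "weight"), "does not include")
})

test_that("predict_mean matches closed forms and the training-mean identity", {
  # intercept-only: mu = exp(beta0)
  fit0 <- structure(list(beta = c("(Intercept)" = log(40)),
                         terms = "(Intercept)"), class = "gee_fit")
  X0 <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  expect_equal(predict_mean(fit0, X0), 40)

  # adding one unit of a term with coefficient log(2) doubles the mean
  fit2 <- structure(list(beta = c("(Intercept)" = log(10), age = log(2),
                                  weight = 0, female = 0, splenectomy = 0),
                         terms = c("(Intercept)", "age", "weight", "female",
                                   "splenectomy")), class = "gee_fit")
  nd1 <- data.frame(age = 3, weight = 30, female = 0, splenectomy = 0)
  nd2 <- data.frame(age = 4, weight = 30, female = 0, splenectomy = 0)
  expect_equal(predict_mean(fit2, nd2) / predict_mean(fit2, nd1), 2)
  expect_error(predict_mean(fit2, data.frame(age = 1)), "lacks fitted terms")

  # with an intercept and independent working correlation, fitted means
  # average to the observed mean (score-equation identity)
  lms <- test_lms()
  panel <- clean_panel(n = 40, seed = 12, lms = lms)
  d <- build_design(panel, model_variant(c("age2", "weight2")))
  fit <- fit_gee(d$X, d$y, d$id)
  mu <- predict_mean(fit, d$X)
  expect_lt(abs(mean(mu) - mean(d$y)) / mean(d$y), 1e-6)
})

test_that("fit_gee rejects degenerate inputs", {
  X <- cbind("(Intercept)" = rep(1, 10))
  expect_error(fit_gee(X, rep(0, 10), rep(1:2, 5)), "all counts are zero")
  expect_error(fit_gee(X, rep(1.5, 10), rep(1:2, 5)), "integer")
  expect_error(fit_gee(X, rep(2, 10), rep(1, 10)), "2 patients")
  expect_error(fit_gee(X, rep(-1, 10), rep(1:2, 5)), "non-negative")
})
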