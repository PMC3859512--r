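#' Model variants for the demand model
#'
#' A variant is the base predictor set (age, weight, female, splenectomy) plus
#' optional quadratic terms, years-of-transfusion, and pairwise interactions,
#' paired with a working correlation structure.
#'
#' @param extras character vector from `age2`, `weight2`, `year_tx`, and
#'   interaction terms written as `a:b` between base predictors (e.g.
#'   `"age:female"`).
#' @param corr working correlation, `"independent"` or `"exchangeable"`.
#' @param label optional display label; default is built from the terms.
#' @return list of class `model_variant` with elements `terms` (design column
#'   names), `extras`, `corr`, `label`.
#' @export
model_variant <- function(extras = character(),
                          corr = c("independent", "exchangeable"),
                          label = NULL) {
  corr <- match.arg(corr)
  base <- c("age", "weight", "female", "splenectomy")
  known <- c("age2", "weight2", "year_tx")
  inter <- grepl(":", extras, fixed = TRUE)
  bad <- extras[!inter & !extras %in% known]
  if (length(bad)) stop("unknown extra terms: ", paste(bad, collapse = ", "))
  for (tm in extras[inter]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% c(base, "year_tx")))
      stop("interaction must be between two base predictors: ", tm)
  }
  terms <- c("(Intercept)", base, extras)
  if (is.null(label)) {
    label <- if (length(extras) == 0) "base" else
      paste0("+", paste(sub("2$", "^2", extras), collapse = ","))
  }
  structure(list(terms = terms, extras = extras, corr = corr, label = label),
            class = "model_variant")
}

#' The default variant grid
#'
#' Eight predictor sets (base; each of age-squared, weight-squared and
#' years-of-transfusion added singly and in combination) crossed with
#' independent and exchangeable working correlation: 16 candidate models.
#'
#' @return list of [model_variant()]s.
#' @export
default_variant_grid <- function() {
  sets <- list(character(),
               "age2", "weight2", "year_tx",
               c("age2", "weight2"), c("age2", "year_tx"),
               c("weight2", "year_tx"), c("age2", "weight2", "year_tx"))
  out <- list()
  for (corr in c("independent", "exchangeable"))
    for (s in sets)
      out[[length(out) + 1]] <- model_variant(s, corr)
  out
}

#' Interaction-augmented variant grid
#'
#' The quadratic model plus pairwise interactions of age and weight with sex
#' and splenectomy status (independent working correlation), mirroring a
#' sensitivity grid of interaction-term variants.
#'
#' @param interactions interaction terms to sweep; each is added singly to the
#'   quadratic model, plus one variant with all of them.
#' @return list of [model_variant()]s.
#' @export
interaction_variant_grid <- function(interactions = c("age:female",
                                                      "age:splenectomy",
                                                      "weight:female",
                                                      "weight:splenectomy")) {
  out <- list(model_variant(c("age2", "weight2")))
  for (tm in interactions)
    out[[length(out) + 1]] <- model_variant(c("age2", "weight2", tm))
  out[[length(out) + 1]] <- model_variant(c("age2", "weight2", interactions))
  out
}

# evaluate one design column from base covariate values
eval_term <- function(term, v) {
  if (term == "(Intercept)") return(rep(1, length(v$age)))
  if (term %in% names(v)) return(v[[term]])
  if (term == "age2") return(v$age^2)
  if (term == "weight2") return(v$weight^2)
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    return(eval_term(parts[1], v) * eval_term(parts[2], v))
  }
  stop("cannot evaluate design term: ", term)
}

design_from_values <- function(terms, values) {
  X <- vapply(terms, eval_term, numeric(length(values$age)), v = values)
  X <- matrix(X, ncol = length(terms), dimnames = list(NULL, terms))
  X
}

#' Build the GEE design matrix from a patient panel
#'
#' Covariates enter uncentred, so exponentiated coefficients read as relative
#' demand per year of age / per kg at the natural origin. Quadratic terms are
#' squares of the uncentred covariates. `year_tx` (years of transfusion) is
#' the current year minus the patient's first year with recorded demand.
#'
#' @param panel patient panel (see [read_panel()] for columns).
#' @param variant a [model_variant()].
#' @return list with `X` (design matrix), `y` (units), `id` (patient ids),
#'   and `vif` (variance inflation factors of the non-intercept columns,
#'   reported, not enforced).
#' @export
build_design <- function(panel, variant) {
  stopifnot(inherits(variant, "model_variant"))
  if (any(is.na(panel$weight_kg)))
    stop("panel has missing weights; run backfill_weights() first")
  first_year <- stats::ave(ifelse(panel$units > 0, panel$year, NA),
                           panel$patient_id,
                           FUN = function(x) if (all(is.na(x))) NA else min(x, na.rm = TRUE))
  first_year[is.na(first_year)] <-
    stats::ave(panel$year, panel$patient_id, FUN = min)[is.na(first_year)]
  values <- list(age = panel$age_years, weight = panel$weight_kg,
                 female = as.numeric(panel$sex == "female"),
                 splenectomy = as.numeric(panel$splenectomy),
                 year_tx = panel$year - first_year)
  X <- design_from_values(variant$terms, values)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear terms: ", paste(drop, collapse = ", "))
  }
  list(X = X, y = as.numeric(panel$units), id = as.character(panel$patient_id),
       vif = design_vif(X))
}

#' Variance inflation factors of a design matrix
#'
#' @param X design matrix including an intercept column.
#' @return named vector of VIFs for the non-intercept columns.
#' @export
design_vif <- function(X) {
  cols <- setdiff(colnames(X), "(Intercept)")
  if (length(cols) < 2) return(stats::setNames(rep(1, length(cols)), cols))
  vif <- vapply(cols, function(cl) {
    others <- X[, setdiff(colnames(X), cl), drop = FALSE]
    f <- stats::lm.fit(others, X[, cl])
    r2 <- 1 - sum(f$residuals^2) / sum((X[, cl] - mean(X[, cl]))^2)
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
  vif
}

#' Apply the cohort exclusion filters
#'
#' Removes, in order: patient-years at age below 1 (transfusion therapy
#' typically begins between 6 and 12 months, so younger rows are not modelled);
#' patients with an irregular transfusion pattern, operationalised as a
#' non-contiguous span of active (units > 0) years — a zero-demand or missing
#' year strictly inside the first-to-last active-year span; and patients with
#' no recoverable weight (all weights missing).
#'
#' @param panel raw patient panel.
#' @return list with `panel` (filtered) and `log` (data.frame of `reason`,
#'   `n_patients`, `n_rows` removed per reason).
#' @export
apply_exclusions <- function(panel) {
  log <- data.frame(reason = character(), n_patients = integer(),
                    n_rows = integer(), stringsAsFactors = FALSE)
  infant <- panel$age_years < 1
  if (any(infant)) {
    kept_pids <- unique(panel$patient_id[!infant])
    gone <- setdiff(unique(panel$patient_id), kept_pids)
    log <- rbind(log, data.frame(reason = "age_below_1_year",
                                 n_patients = length(gone),
                                 n_rows = sum(infant)))
    panel <- panel[!infant, , drop = FALSE]
  }
  # irregular: active years not contiguous within the patient's span
  irregular <- vapply(split(seq_len(nrow(panel)), panel$patient_id), function(i) {
    act <- panel$year[i][panel$units[i] > 0]
    if (length(act) == 0) return(TRUE)
    (max(act) - min(act) + 1) > length(unique(act))
  }, logical(1))
  irr_ids <- names(irregular)[irregular]
  if (length(irr_ids)) {
    drop <- panel$patient_id %in% irr_ids
    log <- rbind(log, data.frame(reason = "irregular_transfusion",
                                 n_patients = length(irr_ids),
                                 n_rows = sum(drop)))
    panel <- panel[!drop, , drop = FALSE]
  }
  noweight <- vapply(split(panel$weight_kg, panel$patient_id),
                     function(w) all(is.na(w)), logical(1))
  nw_ids <- names(noweight)[noweight]
  if (length(nw_ids)) {
    drop <- panel$patient_id %in% nw_ids
    log <- rbind(log, data.frame(reason = "missing_weights",
                                 n_patients = length(nw_ids),
                                 n_rows = sum(drop)))
    panel <- panel[!drop, , drop = FALSE]
  }
  rownames(panel) <- NULL
  list(panel = panel, log = log)
}

# exchangeable working-correlation shrink factor per cluster size:
# V_i^{-1} = (I - c_n J) / (1 - alpha), c_n = alpha / (1 + (n-1) alpha)
exch_c <- function(sizes, alpha) alpha / (1 + (sizes - 1) * alpha)

#' Fit a Poisson GEE with log link
#'
#' Solves the generalized estimating equations
#' `sum_i D_i' V_i^{-1} (y_i - mu_i) = 0` with `mu = exp(X beta)`,
#' `V_i = A_i^{1/2} R(alpha) A_i^{1/2}`, by Fisher scoring with step-halving.
#' The exchangeable correlation `alpha` is re-estimated each iteration by the
#' moment estimator on Pearson residuals; the scale `phi` is Pearson
#' chi-squared over `N - p`. The covariance of `beta` is the Liang-Zeger
#' sandwich `B^{-1} M B^{-1}`, which is invariant to `phi`. With an
#' independent working correlation the estimate coincides with the pooled
#' Poisson maximum-likelihood root.
#'
#' @param X design matrix (include an intercept column).
#' @param y non-negative integer outcome (annual units transfused).
#' @param id cluster (patient) identifiers, one per row.
#' @param corr working correlation, `"independent"` or `"exchangeable"`.
#' @param beta_init optional warm start.
#' @param tol convergence tolerance on the relative coefficient change.
#' @param max_iter maximum Fisher-scoring iterations.
#' @return object of class `gee_fit`: `beta`, `robust_cov`, `naive_cov`,
#'   `scale`, `alpha`, `corr`, `n_patients`, `n_obs`, `iterations`, `terms`.
#' @export
fit_gee <- function(X, y, id, corr = c("independent", "exchangeable"),
                    beta_init = NULL, tol = 1e-8, max_iter = 100L) {
  corr <- match.arg(corr)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n || length(id) != n) stop("X, y, id lengths differ")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("outcome must be non-negative integer counts")
  if (all(y == 0)) stop("degenerate outcome: all counts are zero")
  id <- as.character(id)
  if (length(unique(id)) < 2) stop("GEE needs at least 2 patients (clusters)")

  fid <- factor(id, levels = unique(id))
  sizes_tab <- tabulate(fid)

  beta <- beta_init
  if (is.null(beta)) {
    # log-linear least-squares start
    beta <- qr.coef(qr(X), log(y + 0.5))
    beta[is.na(beta)] <- 0
  }

  alpha <- 0
  eta <- pmin(as.vector(X %*% beta), 30)
  mu <- exp(eta)
  score_norm_old <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    r <- (y - mu) / sqrt(mu)
    if (corr == "exchangeable") {
      phi_work <- sum(r^2) / (n - p)
      rs <- rowsum(r, fid)            # cluster sums of Pearson residuals
      rs2 <- rowsum(r^2, fid)
      npairs <- sum(sizes_tab * (sizes_tab - 1)) / 2
      alpha <- if (npairs > p)
        sum(rs^2 - rs2) / 2 / (phi_work * (npairs - p)) else 0
      alpha <- min(max(alpha, 0), 0.99)
    }
    Z <- X * sqrt(mu)
    if (alpha > 0) {
      Ti <- rowsum(Z, fid)
      cvec <- exch_c(sizes_tab, alpha)
      B <- (crossprod(Z) - crossprod(Ti * sqrt(cvec))) / (1 - alpha)
      u <- (crossprod(Z, r) - crossprod(Ti, cvec * rowsum(r, fid))) / (1 - alpha)
    } else {
      B <- crossprod(Z)
      u <- crossprod(X, y - mu)
    }
    delta <- tryCatch(solve(B, u), error = function(e)
      stop("singular working information at iteration ", it))
    # step-halving on a diverging score norm
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- as.vector(X %*% beta_new)
      if (max(eta_new) < 30) break
      step <- step / 2
      if (step < 1e-8) stop("GEE diverged: linear predictor overflow")
    }
    mu_new <- exp(pmin(eta_new, 30))
    sn <- sum(crossprod(X, y - mu_new)^2)
    halved <- 0
    while (is.finite(score_norm_old) && sn > 4 * score_norm_old && halved < 20) {
      step <- step / 2
      beta_new <- beta + step * delta
      mu_new <- exp(pmin(as.vector(X %*% beta_new), 30))
      sn <- sum(crossprod(X, y - mu_new)^2)
      halved <- halved + 1
    }
    change <- max(abs(beta_new - beta)) / (max(abs(beta_new)) + 1e-10)
    trace[it] <- change
    beta <- beta_new
    mu <- mu_new
    score_norm_old <- sn
    if (change <= tol) break
    if (it == max_iter)
      stop("GEE did not converge in ", max_iter,
           " iterations; relative changes: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  }

  r <- (y - mu) / sqrt(mu)
  phi <- sum(r^2) / (n - p)
  Z <- X * sqrt(mu)
  Ti <- rowsum(Z, fid)
  if (alpha > 0) {
    cvec <- exch_c(sizes_tab, alpha)
    B <- (crossprod(Z) - crossprod(Ti * sqrt(cvec))) / (1 - alpha)
    G <- (rowsum(Z * r, fid) - Ti * as.vector(cvec * rowsum(r, fid))) / (1 - alpha)
  } else {
    B <- crossprod(Z)
    G <- rowsum(X * (y - mu), fid)
  }
  Binv <- solve(B)
  robust <- Binv %*% crossprod(G) %*% Binv
  robust <- (robust + t(robust)) / 2
  beta <- as.vector(beta)
  names(beta) <- colnames(X)
  dimnames(robust) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, robust_cov = robust,
                 naive_cov = Binv * phi, scale = phi,
                 alpha = if (corr == "exchangeable") alpha else NA_real_,
                 corr = corr, n_patients = length(sizes_tab), n_obs = n,
                 iterations = it, terms = colnames(X), variant = NULL),
            class = "gee_fit")
}

#' Fit a demand-model variant to a panel
#'
#' Convenience wrapper: builds the design with [build_design()] and calls
#' [fit_gee()], attaching the variant so predictions and projections can
#' rebuild covariate rows.
#'
#' @param panel filtered patient panel.
#' @param variant a [model_variant()].
#' @return a `gee_fit` with `$variant` set and `$vif` recorded.
#' @export
fit_demand_model <- function(panel, variant = model_variant(c("age2", "weight2"))) {
  d <- build_design(panel, variant)
  fit <- fit_gee(d$X, d$y, d$id, corr = variant$corr)
  fit$variant <- variant
  fit$vif <- d$vif
  fit
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Poisson GEE fit (", x$corr, " working correlation)\n", sep = "")
  cat("  ", x$n_obs, "patient-years,", x$n_patients, "patients;",
      "scale =", round(x$scale, 3),
      if (!is.na(x$alpha)) paste("; alpha =", round(x$alpha, 3)) else "", "\n")
  print(relative_demand_table(x), digits = 4)
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$beta

#' @export
vcov.gee_fit <- function(object, ...) object$robust_cov

#' Relative-demand table from a GEE fit
#'
#' Exponentiates coefficients into relative demand ratios with robust
#' (sandwich) 95% Wald confidence intervals and two-sided p-values.
#'
#' @param fit a `gee_fit`.
#' @return data.frame with one row per non-intercept term: `term`, `rr`,
#'   `ci_lo`, `ci_hi`, `p`.
#' @export
relative_demand_table <- function(fit) {
  keep <- fit$terms != "(Intercept)"
  b <- fit$beta[keep]
  se <- sqrt(diag(fit$robust_cov))[keep]
  z <- b / se
  data.frame(term = fit$terms[keep], rr = exp(b),
             ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
}

#' Covariate value maximising expected demand
#'
#' For a covariate entering linearly and quadratically (coefficients `b1`,
#' `b2 < 0`), expected log-demand peaks at `-b1 / (2 b2)`.
#'
#' @param fit a `gee_fit` containing both `term` and its square.
#' @param term `"age"` or `"weight"`.
#' @return the maximising covariate value.
#' @export
peak_covariate <- function(fit, term = c("age", "weight")) {
  term <- match.arg(term)
  sq <- paste0(term, "2")
  if (!all(c(term, sq) %in% fit$terms))
    stop("fit does not include both ", term, " and ", sq)
  b1 <- fit$beta[[term]]; b2 <- fit$beta[[sq]]
  if (b2 >= 0) stop("no interior maximum: coefficient on ", sq, " is non-negative")
  -b1 / (2 * b2)
}

#' Expected demand for covariate rows
#'
#' @param fit a `gee_fit`.
#' @param newdata either a design matrix with the fit's columns, or a
#'   data.frame with columns `age`, `weight`, `female`, `splenectomy` (and
#'   `year_tx` if the model uses it) from which the design is rebuilt.
#' @return expected units/year, `mu = exp(x' beta)`.
#' @export
predict_mean <- function(fit, newdata) {
  if (is.matrix(newdata)) {
    miss <- setdiff(fit$terms, colnames(newdata))
    if (length(miss)) stop("newdata lacks fitted terms: ", paste(miss, collapse = ", "))
    X <- newdata[, fit$terms, drop = FALSE]
  } else {
    values <- as.list(newdata)
    needs_ytx <- "year_tx" %in% fit$terms ||
      any(grepl("year_tx", fit$terms, fixed = TRUE))
    if (needs_ytx && is.null(values$year_tx))
      stop("newdata lacks fitted terms: year_tx")
    base <- c("age", "weight", "female", "splenectomy")
    miss <- setdiff(base, names(values))
    if (length(miss)) stop("newdata lacks fitted terms: ", paste(miss, collapse = ", "))
    X <- design_from_values(fit$terms, values)
  }
  as.vector(exp(X %*% fit$beta))
}

#' @export
predict.gee_fit <- function(object, newdata, ...) predict_mean(object, newdata)

#' Write a relative-demand table CSV
#'
#' @param fit a `gee_fit`.
#' @param path output path.
#' @param header optional comment line(s).
#' @export
write_demand_table <- function(fit, path, header = NULL) {
  write_csv_header(relative_demand_table(fit), path, header)
  invisible(path)
}
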