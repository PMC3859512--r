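# Independent oracles and small fixtures shared across tests.

# Newton-Raphson solver of the Poisson log-likelihood, written independently
# of the package's GEE path: the pooled Poisson MLE is the root the
# independence-working-correlation GEE must find.
poisson_newton <- function(X, y, tol = 1e-12, max_iter = 50) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 1e-8)
  for (i in seq_len(max_iter)) {
    mu <- as.vector(exp(X %*% beta))
    step <- solve(crossprod(X * sqrt(mu)), crossprod(X, y - mu))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# small LMS fixture (coarser grid than the default)
test_lms <- function() generate_lms_reference(agemos = seq(0, 240, by = 12))

# clean cohort without data-quality injections, for estimation tests
clean_config <- function(n = 80, seed = 1, ...) {
  generator_config(n_patients = n, prop_irregular = 0,
                   prop_missing_weight = 0, incidence_per_100k = 0,
                   mortality_rate_adult = 0, seed = seed, ...)
}

clean_panel <- function(n = 80, seed = 1, lms = test_lms(), ...) {
  generate_cohort(clean_config(n, seed, ...), lms)$panel
}
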