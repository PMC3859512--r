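#' Leave-one-out cross-validated mean absolute error of a variant
#'
#' For each patient-year row, the model is refit on all remaining rows
#' (warm-started at the full-data coefficients; the exchangeable correlation is
#' re-estimated within each fold) and the held-out demand is predicted from the
#' refit. The score is the mean absolute difference between held-out demand and
#' its prediction, in units of blood.
#'
#' @param panel filtered patient panel.
#' @param variant a [model_variant()].
#' @param warm_start warm-start each fold at the full-data coefficients
#'   (default). The scores are invariant to this switch to within the solver
#'   tolerance; it only affects speed.
#' @return list of class `variant_score`: `variant`, `label`, `correlation`,
#'   `mae`, `n_heldout`, `n_failed`.
#' @export
loocv_mae <- function(panel, variant, warm_start = TRUE) {
  d <- build_design(panel, variant)
  X <- d$X; y <- d$y; id <- d$id
  n <- nrow(X)
  full <- fit_gee(X, y, id, corr = variant$corr)
  init <- if (warm_start) full$beta else NULL
  abs_err <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    fit_r <- tryCatch(
      fit_gee(X[-r, , drop = FALSE], y[-r], id[-r], corr = variant$corr,
              beta_init = init),
      error = function(e) NULL)
    if (is.null(fit_r)) next
    abs_err[r] <- abs(y[r] - exp(sum(X[r, ] * fit_r$beta)))
  }
  ok <- !is.na(abs_err)
  n_failed <- sum(!ok)
  if (n_failed > 0.01 * n)
    warning("LOOCV: ", n_failed, " of ", n, " folds failed to refit")
  structure(list(variant = variant, label = variant$label,
                 correlation = variant$corr,
                 mae = mean(abs_err[ok]), n_heldout = sum(ok),
                 n_failed = n_failed),
            class = "variant_score")
}

#' Score a grid of model variants by LOOCV
#'
#' @param panel filtered patient panel.
#' @param grid list of [model_variant()]s (default: [default_variant_grid()],
#'   8 predictor sets x 2 correlation structures).
#' @param verbose print progress per variant.
#' @return data.frame of class `variant_scores`, sorted ascending by MAE:
#'   `label`, `correlation`, `n_predictors`, `mae`, `n_heldout`; the variants
#'   themselves are kept in attribute `"variants"` (in the sorted order).
#' @export
run_variant_grid <- function(panel, grid = default_variant_grid(),
                             verbose = FALSE) {
  if (length(grid) == 0) stop("variant grid is empty")
  scores <- lapply(grid, function(v) {
    s <- loocv_mae(panel, v)
    if (verbose)
      message(sprintf("  %-28s %-13s mae = %.3f", v$label, v$corr, s$mae))
    s
  })
  out <- data.frame(
    label = vapply(scores, `[[`, character(1), "label"),
    correlation = vapply(scores, `[[`, character(1), "correlation"),
    n_predictors = vapply(grid, function(v) length(v$terms) - 1L, integer(1)),
    mae = vapply(scores, `[[`, numeric(1), "mae"),
    n_heldout = vapply(scores, `[[`, integer(1), "n_heldout"),
    stringsAsFactors = FALSE)
  ord <- order(out$mae)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variants") <- grid[ord]
  class(out) <- c("variant_scores", "data.frame")
  out
}

#' Select the final model with a parsimony rule
#'
#' Among variants whose MAE is within `parsimony_delta` of the minimum, the
#' one with the fewest predictors wins; remaining ties are broken by dropping
#' years-of-transfusion first, then interaction terms. This encodes the
#' judgement that a predictor earning only a negligible MAE improvement does
#' not belong in a long-horizon forecasting model.
#'
#' @param scores a `variant_scores` table from [run_variant_grid()].
#' @param parsimony_delta MAE tolerance in units (default 0.01).
#' @return the selected [model_variant()].
#' @export
select_final <- function(scores, parsimony_delta = 0.01) {
  if (nrow(scores) == 0) stop("no scores to select from")
  variants <- attr(scores, "variants")
  best <- min(scores$mae)
  cand <- which(scores$mae <= best + parsimony_delta)
  has_ytx <- vapply(variants[cand], function(v)
    any(grepl("year_tx", v$extras, fixed = TRUE)), logical(1))
  n_inter <- vapply(variants[cand], function(v)
    sum(grepl(":", v$extras, fixed = TRUE)), integer(1))
  ord <- order(scores$n_predictors[cand], has_ytx, n_inter, scores$mae[cand])
  variants[[cand[ord[1]]]]
}

#' Write a variant-score table CSV
#'
#' @param scores a `variant_scores` table.
#' @param path output path.
#' @param header optional comment line(s).
#' @export
write_scores <- function(scores, path, header = NULL) {
  write_csv_header(as.data.frame(scores), path, header)
  invisible(path)
}
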