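#' LMS growth-reference transforms
#'
#' The LMS method summarises a growth reference by three age- and sex-specific
#' parameters: a Box-Cox power `L`, the median `M` (kg), and a coefficient of
#' variation `S`. A measurement `x` maps to a z-score by
#' \deqn{z = \frac{(x/M)^L - 1}{L S} \quad (L \neq 0), \qquad
#'       z = \frac{\log(x/M)}{S} \quad (L = 0).}
#'
#' @param weight body weight in kg (vectorised); must be positive.
#' @param L,M,S LMS parameters, recycled against `weight`. `M > 0`, `S > 0`.
#' @return numeric vector of z-scores.
#' @seealso [lms_inverse()] for the exact algebraic inverse.
#' @export
lms_z <- function(weight, L, M, S) {
  if (any(weight <= 0)) stop("weight must be positive")
  if (any(M <= 0) || any(S <= 0)) stop("LMS parameters require M > 0 and S > 0")
  n <- max(length(weight), length(L), length(M), length(S))
  weight <- rep_len(weight, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- numeric(n)
  zero <- L == 0
  z[zero] <- log(weight[zero] / M[zero]) / S[zero]
  nz <- !zero
  z[nz] <- ((weight[nz] / M[nz])^L[nz] - 1) / (L[nz] * S[nz])
  z
}

#' Invert an LMS z-score back to a measurement
#'
#' Exact inverse of [lms_z()]: `x = M (1 + L S z)^{1/L}` for `L != 0` and
#' `x = M exp(S z)` for `L = 0`. The inverse only exists where
#' `1 + L*S*z > 0`; values outside that support raise an error.
#'
#' @param z z-score (vectorised).
#' @inheritParams lms_z
#' @return body weight in kg.
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) stop("LMS parameters require M > 0 and S > 0")
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  x <- numeric(n)
  zero <- L == 0
  x[zero] <- M[zero] * exp(S[zero] * z[zero])
  nz <- !zero
  base <- 1 + L[nz] * S[nz] * z[nz]
  if (any(base <= 0)) stop("z outside the support of the LMS transform (1 + L*S*z <= 0)")
  x[nz] <- M[nz] * base^(1 / L[nz])
  x
}

#' Construct an LMS reference table
#'
#' @param sex character vector, "male"/"female" (CDC numeric codes 1/2 and
#'   "M"/"F" are also accepted and normalised).
#' @param agemos age in months.
#' @param L,M,S LMS parameters per row.
#' @return a data.frame of class `lms_reference`, sorted by sex then age.
#' @export
lms_reference <- function(sex, agemos, L, M, S) {
  sex <- normalize_sex(sex)
  ref <- data.frame(sex = sex, agemos = as.numeric(agemos),
                    L = as.numeric(L), M = as.numeric(M), S = as.numeric(S),
                    stringsAsFactors = FALSE)
  ref <- ref[order(ref$sex, ref$agemos), , drop = FALSE]
  rownames(ref) <- NULL
  validate_lms(ref)
  class(ref) <- c("lms_reference", "data.frame")
  ref
}

validate_lms <- function(ref) {
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop("LMS reference requires M > 0 and S > 0")
  for (s in unique(ref$sex)) {
    a <- ref$agemos[ref$sex == s]
    if (anyDuplicated(a)) stop("duplicated age_months for sex ", s)
    if (is.unsorted(a, strictly = TRUE)) stop("age_months must be strictly increasing within sex")
  }
  invisible(ref)
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("1", "m", "male"), "male",
         ifelse(s %in% c("2", "f", "female"), "female", NA_character_))
  if (anyNA(out)) stop("unrecognised sex code(s): ",
                       paste(unique(sex[is.na(out)]), collapse = ", "))
  out
}

#' Interpolate LMS parameters at given sex/age
#'
#' Linear interpolation of L, M and S in age (months) within sex. Ages beyond
#' the tabulated range are clamped to the nearest tabulated entry with a
#' warning.
#'
#' @param lms an [lms_reference()].
#' @param sex sex code(s), recycled.
#' @param agemos age(s) in months.
#' @return data.frame with columns `L`, `M`, `S` (one row per query).
#' @export
lms_params <- function(lms, sex, agemos) {
  sex <- normalize_sex(sex)
  n <- max(length(sex), length(agemos))
  sex <- rep_len(sex, n); agemos <- rep_len(as.numeric(agemos), n)
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (s in unique(sex)) {
    sub <- lms[lms$sex == s, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("LMS reference has no entries for sex '", s, "'")
    i <- sex == s
    a <- agemos[i]
    rng <- range(sub$agemos)
    if (any(a < rng[1] - 1e-9) || any(a > rng[2] + 1e-9))
      warning("age ", paste(signif(a[a < rng[1] | a > rng[2]], 4), collapse = ", "),
              " months outside LMS range for ", s, "; clamped to [",
              rng[1], ", ", rng[2], "]")
    a <- pmin(pmax(a, rng[1]), rng[2])
    out$L[i] <- stats::approx(sub$agemos, sub$L, xout = a)$y
    out$M[i] <- stats::approx(sub$agemos, sub$M, xout = a)$y
    out$S[i] <- stats::approx(sub$agemos, sub$S, xout = a)$y
  }
  out
}

# Growth is treated as negligible from this age on: weight projections and the
# LMS lookup are capped at 20 years (240 months).
ADULT_AGE <- 20

#' Project a patient's future weight under a constant z-score
#'
#' Converts the current weight to a z-score on the reference at the current
#' age, then reads the weight off the reference at the target age, holding the
#' z-score constant. Growth is assumed negligible from age 20: ages are capped
#' at 20 for the lookup, and a patient already aged 20 or older keeps their
#' current weight unchanged.
#'
#' @param current_weight observed weight (kg).
#' @param sex sex code.
#' @param current_age,target_age ages in years; `target_age >= current_age`.
#' @param lms an [lms_reference()].
#' @return projected weight in kg (vectorised over patients).
#' @export
project_weight <- function(current_weight, sex, current_age, target_age, lms) {
  n <- max(length(current_weight), length(sex), length(current_age), length(target_age))
  current_weight <- rep_len(current_weight, n); sex <- rep_len(sex, n)
  current_age <- rep_len(current_age, n); target_age <- rep_len(target_age, n)
  if (any(target_age < current_age)) stop("target_age must be >= current_age")
  out <- current_weight
  grow <- current_age < ADULT_AGE & target_age > current_age
  if (any(grow)) {
    p0 <- lms_params(lms, sex[grow], pmin(current_age[grow], ADULT_AGE) * 12)
    z0 <- lms_z(current_weight[grow], p0$L, p0$M, p0$S)
    p1 <- lms_params(lms, sex[grow], pmin(target_age[grow], ADULT_AGE) * 12)
    out[grow] <- lms_inverse(z0, p1$L, p1$M, p1$S)
  }
  out
}

#' Impute a missing weight from the mean z-score of age-group peers
#'
#' @param sex sex code of the patient.
#' @param age age in years.
#' @param peer_zscores z-scores of patients in the same age group (>= 1 value).
#' @param lms an [lms_reference()].
#' @return imputed weight (kg) at the mean peer z-score.
#' @export
impute_weight <- function(sex, age, peer_zscores, lms) {
  peer_zscores <- peer_zscores[is.finite(peer_zscores)]
  if (length(peer_zscores) == 0)
    stop("no peer z-scores in this age group; fall back to the nearest non-empty group")
  p <- lms_params(lms, sex, pmin(age, ADULT_AGE) * 12)
  lms_inverse(mean(peer_zscores), p$L, p$M, p$S)
}

# z-score of every observed weight in a panel, evaluated at min(age, 20).
panel_zscores <- function(panel, lms) {
  z <- rep(NA_real_, nrow(panel))
  obs <- !is.na(panel$weight_kg)
  if (any(obs)) {
    p <- lms_params(lms, panel$sex[obs], pmin(panel$age_years[obs], ADULT_AGE) * 12)
    z[obs] <- lms_z(panel$weight_kg[obs], p$L, p$M, p$S)
  }
  z
}

# Age-group bins used for mean-z imputation: 1-year bins below 20, one adult
# bin at 20+.
impute_bin <- function(age) ifelse(age >= ADULT_AGE, ADULT_AGE, floor(age))

#' Fill in missing weights across a patient panel
#'
#' Weights observed in some years are carried to the patient's other years at a
#' constant z-score (from the nearest observed year). Patients with no observed
#' weight at all are imputed from the mean z-score of their age-group peers
#' (1-year bins below 20, a single 20+ adult bin; an empty bin falls back to the
#' nearest non-empty bin); if peer imputation is impossible the patient is
#' dropped and logged.
#'
#' @param panel patient panel data.frame with columns `patient_id`, `year`,
#'   `sex`, `age_years`, `weight_kg`, at minimum.
#' @param lms an [lms_reference()].
#' @param drop_allmissing if `TRUE` (default), patients whose weights cannot be
#'   recovered even by peer imputation are removed.
#' @return the panel with `weight_kg` complete; attribute `"imputation_log"`
#'   records per-patient actions (a data.frame of `patient_id`, `action`).
#' @export
backfill_weights <- function(panel, lms, drop_allmissing = TRUE) {
  panel <- panel[order(panel$patient_id, panel$year), , drop = FALSE]
  z <- panel_zscores(panel, lms)
  log_rows <- list()

  # per-patient constant-z carry from the nearest observed year
  for (pid in unique(panel$patient_id)) {
    i <- which(panel$patient_id == pid)
    obs <- i[!is.na(z[i])]
    mis <- i[is.na(z[i])]
    if (length(mis) == 0) next
    if (length(obs) == 0) {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(patient_id = pid, action = "peer_imputed_or_dropped")
      next
    }
    nearest <- obs[vapply(mis, function(m)
      which.min(abs(panel$year[obs] - panel$year[m])), integer(1))]
    zfill <- z[nearest]
    p <- lms_params(lms, panel$sex[mis], pmin(panel$age_years[mis], ADULT_AGE) * 12)
    panel$weight_kg[mis] <- lms_inverse(zfill, p$L, p$M, p$S)
    z[mis] <- zfill
    log_rows[[length(log_rows) + 1]] <-
      data.frame(patient_id = pid, action = "constant_z_carry")
  }

  # patients with nothing observed: mean peer z in the age-group bin
  still <- is.na(panel$weight_kg)
  if (any(still)) {
    bins <- impute_bin(panel$age_years)
    peer_mean <- tapply(z[!still], bins[!still], mean, na.rm = TRUE)
    for (r in which(still)) {
      b <- impute_bin(panel$age_years[r])
      avail <- as.numeric(names(peer_mean))
      if (length(avail) == 0) next
      use <- avail[which.min(abs(avail - b))]
      p <- lms_params(lms, panel$sex[r], pmin(panel$age_years[r], ADULT_AGE) * 12)
      panel$weight_kg[r] <- lms_inverse(peer_mean[[as.character(use)]], p$L, p$M, p$S)
    }
  }

  if (drop_allmissing && any(is.na(panel$weight_kg))) {
    bad <- unique(panel$patient_id[is.na(panel$weight_kg)])
    log_rows[[length(log_rows) + 1]] <-
      data.frame(patient_id = bad, action = "dropped_no_weight")
    panel <- panel[!panel$patient_id %in% bad, , drop = FALSE]
  }

  attr(panel, "imputation_log") <-
    if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(patient_id = character(), action = character())
  panel
}

#' Read / write an LMS reference CSV
#'
#' The CSV dialect is `sex, agemos, L, M, S`; real CDC weight-for-age ("wtage")
#' files with capitalised headers and numeric sex codes (1 = male, 2 = female)
#' are accepted unchanged. Comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return an [lms_reference()].
#' @export
read_lms <- function(path) {
  if (!file.exists(path)) stop("LMS file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("sex", "agemos", "l", "m", "s")
  if (!all(need %in% names(d)))
    stop("LMS CSV must have columns sex, agemos, L, M, S; got: ",
         paste(names(d), collapse = ", "))
  lms_reference(d$sex, d$agemos, d$l, d$m, d$s)
}

#' @rdname read_lms
#' @param lms an [lms_reference()] to write.
#' @param header optional comment line(s) written before the CSV header.
#' @export
write_lms <- function(lms, path, header = NULL) {
  write_csv_header(as.data.frame(lms), path, header)
  invisible(path)
}

# shared comment-header CSV writer
write_csv_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.lms_reference <- function(x, ...) {
  cat("LMS growth reference:", nrow(x), "rows;",
      paste(unique(x$sex), collapse = "/"), "; age",
      min(x$agemos), "-", max(x$agemos), "months\n")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}
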