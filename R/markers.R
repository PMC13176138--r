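#' @title Imaging markers of biological brain aging
#'
#' @description Relative brain age (cross-validated OLS age prediction from
#'   regional morphometry followed by a two-stage bias correction that
#'   enforces orthogonality with chronological age), logarithmized white
#'   matter hyperintensity load, the peak width of skeletonized mean
#'   diffusivity (PSMD), and the gap-variant sensitivity markers (WMH brain
#'   age, microstructural brain age) built by running the identical
#'   two-stage pipeline on a single marker.
#' @name aging_markers
NULL

#' Out-of-fold age prediction from morphometry
#'
#' Within each sex stratum, subjects are partitioned into `n_folds` seeded
#' random folds; each subject's predicted age comes from an ordinary
#' least-squares model (with intercept) fit on the remaining folds.
#'
#' @param features numeric matrix (subjects x morphometry features).
#' @param age chronological age vector (years).
#' @param sex sex vector (female/male labels or 0/1).
#' @param n_folds folds per stratum (default 5).
#' @param seed fold-assignment seed.
#' @param ridge if `TRUE`, add a minimal ridge penalty
#'   (`1e-8 * mean diagonal`) so rank-deficient synthetic fixtures fit;
#'   default fails loudly naming the collinear columns.
#' @return list: `predicted_age` (out-of-fold, aligned with input),
#'   `fold_id`, `sex` (normalized factor), and per-stratum `metrics`
#'   (out-of-fold MAE and R^2).
#' @export
fit_predict_age <- function(features, age, sex, n_folds = 5, seed = NULL,
                            ridge = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(age) == n, length(sex) == n, n_folds >= 2)
  sex <- normalize_sex(sex)
  p <- ncol(features)

  predicted <- numeric(n)
  fold_id <- integer(n)
  metrics <- list()
  with_seed(seed, {
    for (lev in levels(droplevels(sex))) {
      idx <- which(sex == lev)
      if (length(idx) <= p + 1)
        stop("stratum `", lev, "` has too few subjects for ", p, " features")
      folds <- sample(rep(seq_len(n_folds), length.out = length(idx)))
      for (f in seq_len(n_folds)) {
        tr <- idx[folds != f]; te <- idx[folds == f]
        Xtr <- cbind(1, features[tr, , drop = FALSE])
        beta <- ols_coef(Xtr, age[tr], ridge = ridge,
                         colnames = c("(intercept)", colnames(features)))
        predicted[te] <- drop(cbind(1, features[te, , drop = FALSE]) %*% beta)
      }
      fold_id[idx] <- folds
      err <- predicted[idx] - age[idx]
      metrics[[lev]] <- c(
        mae = mean(abs(err)),
        r2 = 1 - sum(err^2) / sum((age[idx] - mean(age[idx]))^2)
      )
    }
  })
  list(predicted_age = predicted, fold_id = fold_id, sex = sex,
       metrics = metrics)
}

# least squares via QR; error names collinear columns unless ridge requested
ols_coef <- function(X, y, ridge = FALSE, colnames = NULL) {
  if (ridge) {
    XtX <- crossprod(X)
    lambda <- 1e-8 * mean(diag(XtX))
    return(drop(solve(XtX + lambda * diag(ncol(X)), crossprod(X, y))))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
    lbl <- if (is.null(colnames)) as.character(bad) else colnames[bad]
    stop("rank-deficient feature matrix; collinear column(s): ",
         paste(lbl, collapse = ", "), " (set ridge = TRUE to override)")
  }
  qr.coef(qr_x, y)
}

#' Relative brain age from predicted and chronological age
#'
#' Second stage of the bias correction: per sex stratum, expected age is the
#' OLS fit of predicted age on chronological age, and relative brain age is
#' `predicted - expected`.  By construction the result is orthogonal to
#' chronological age within each stratum (zero mean, zero correlation) when
#' the fit sample equals the evaluation sample.
#'
#' @param predicted_age out-of-fold predicted age (years).
#' @param age chronological age (years).
#' @param sex sex vector; a single present level computes one stratum with a
#'   warning.
#' @return list: `relative_brain_age`, `expected_age`, and per-stratum
#'   `coefficients` (intercept, slope of the expected-age line).
#' @export
relative_brain_age <- function(predicted_age, age, sex) {
  n <- length(age)
  stopifnot(length(predicted_age) == n, length(sex) == n)
  sex <- normalize_sex(sex)
  levs <- levels(droplevels(sex))
  if (length(levs) == 1L)
    warning("single sex level present; computing one stratum")
  expected <- numeric(n)
  coefs <- list()
  for (lev in levs) {
    idx <- which(sex == lev)
    if (length(idx) < 3) stop("need >= 3 subjects per stratum")
    fit <- stats::lm.fit(cbind(1, age[idx]), predicted_age[idx])
    expected[idx] <- fit$fitted.values
    coefs[[lev]] <- c(intercept = fit$coefficients[1],
                      slope = fit$coefficients[2])
  }
  list(relative_brain_age = predicted_age - expected,
       expected_age = expected, coefficients = coefs)
}

#' Logarithmized white matter hyperintensity load
#'
#' `load% = 100 * wmh_volume / icv`, then the natural log with a small
#' declared floor so zero-WMH subjects stay finite:
#' `log(load% + floor)`.
#'
#' @param wmh_volume WMH volume (ml), non-negative.
#' @param icv intracranial volume (ml), positive.
#' @param floor additive floor in percent before the log (default 1e-3).
#' @return list: `load_pct` and `log_wmh_load` (both per subject).
#' @export
#' @examples
#' compute_wmh_load(4.63, 1600)
compute_wmh_load <- function(wmh_volume, icv, floor = 1e-3) {
  if (any(wmh_volume < 0)) stop("wmh_volume must be non-negative")
  if (any(icv <= 0)) stop("icv must be positive")
  load_pct <- 100 * wmh_volume / icv
  if (any(load_pct == 0))
    message(sum(load_pct == 0), " zero-WMH subject(s) floored at ", floor, "%")
  list(load_pct = load_pct, log_wmh_load = log(load_pct + floor))
}

#' Peak width of skeletonized mean diffusivity
#'
#' The difference between the 95th and 5th percentiles of the MD voxel
#' values on the white matter skeleton, using linear-interpolation
#' percentiles (R type 7, the numpy default).  Invariant to input order and
#' equivariant under positive affine scaling.
#'
#' @param md_values vector of diffusivities (mm^2/s), at least 20 values.
#' @return scalar PSMD (mm^2/s).
#' @export
#' @examples
#' compute_psmd(0:100)  # 90 under the linear-interpolation convention
compute_psmd <- function(md_values) {
  if (length(md_values) < 20)
    stop("need at least 20 MD values for stable percentiles")
  if (!all(is.finite(md_values))) stop("MD values must be finite")
  q <- stats::quantile(md_values, c(0.05, 0.95), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Gap variant of a scalar marker (WMH brain age, microstructural brain age)
#'
#' Runs the identical two-stage relative-brain-age pipeline but with a
#' single marker as the sole feature: cross-validated age prediction from
#' the marker, then the expected-age regression.  The result quantifies the
#' marker's deviation from its age norm, orthogonal to age within stratum.
#'
#' @param marker numeric vector (e.g. log WMH load or PSMD).
#' @param age,sex,n_folds,seed as in [fit_predict_age()].
#' @return gap vector (years), aligned with input.
#' @export
marker_gap <- function(marker, age, sex, n_folds = 5, seed = NULL) {
  pred <- fit_predict_age(matrix(marker, ncol = 1,
                                 dimnames = list(NULL, "marker")),
                          age, sex, n_folds = n_folds, seed = seed)
  relative_brain_age(pred$predicted_age, age, sex)$relative_brain_age
}

#' Compute the full imaging marker panel for a cohort
#'
#' @param cohort a [cohort_table()] with morphometry columns.
#' @param n_folds CV folds for age prediction.
#' @param seed seed for fold assignment (gap variants use an offset stream).
#' @param gap_variants if `TRUE`, also compute WMH brain age and
#'   microstructural brain age.
#' @param wmh_floor floor (%) for the WMH log transform.
#' @return data.frame keyed by `subject_id` with `relative_brain_age`,
#'   `log_wmh_load`, `psmd`, optional gap variants, plus attribute
#'   `brain_age` holding the fit diagnostics.
#' @export
compute_marker_panel <- function(cohort, n_folds = 5, seed = NULL,
                                 gap_variants = FALSE, wmh_floor = 1e-3) {
  stopifnot(inherits(cohort, "cohort_table"))
  morph <- as.matrix(as.data.frame(cohort)[, attr(cohort, "morph_cols"),
                                           drop = FALSE])
  fit <- fit_predict_age(morph, cohort$age, cohort$sex,
                         n_folds = n_folds, seed = seed)
  rba <- relative_brain_age(fit$predicted_age, cohort$age, cohort$sex)
  wmh <- compute_wmh_load(cohort$wmh_volume, cohort$icv, floor = wmh_floor)
  panel <- data.frame(
    subject_id = cohort$subject_id,
    relative_brain_age = rba$relative_brain_age,
    log_wmh_load = wmh$log_wmh_load,
    psmd = cohort$psmd,
    stringsAsFactors = FALSE
  )
  if (gap_variants) {
    gseed <- if (is.null(seed)) NULL else stage_seed(seed, "gap")
    panel$wmh_brain_age <- marker_gap(wmh$log_wmh_load, cohort$age,
                                      cohort$sex, n_folds, gseed)
    panel$microstructural_brain_age <- marker_gap(cohort$psmd, cohort$age,
                                                  cohort$sex, n_folds, gseed)
  }
  attr(panel, "brain_age") <- list(
    predicted_age = fit$predicted_age, fold_id = fit$fold_id,
    expected_age = rba$expected_age, metrics = fit$metrics,
    coefficients = rba$coefficients
  )
  panel
}
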