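#' @title Bootstrap mediation analysis
#'
#' @description Single-mediator mediation of each vascular risk factor's
#'   effect on the subject-level clinical score through the subject-level
#'   imaging score, with covariate adjustment.  The total effect c
#'   decomposes into the direct effect c' and the indirect effect
#'   ab = a * b, where a is the risk -> mediator path and b the
#'   mediator -> outcome path adjusting for the risk factor.  Significance
#'   of ab uses a percentile bootstrap; the suite applies FDR correction
#'   across risk factors within each effect family.
#' @name mediation
NULL

# mediation taxonomy: a, b and ab must all be significant; then "full" if
# the direct path lost significance, "partial" if it remains but attenuated
classify_mediation <- function(a_sig, b_sig, ab_sig, cp_sig, attenuated) {
  ifelse(a_sig & b_sig & ab_sig,
         ifelse(!cp_sig, "full", ifelse(attenuated, "partial", "none")),
         "none")
}

# OLS coefficient + t-test p-value for one design column
ols_path <- function(X, y, col) {
  fit <- stats::lm.fit(X, y)
  dfree <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / dfree
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[col, col])
  est <- unname(fit$coefficients[col])
  list(est = est, se = se,
       p = 2 * stats::pt(abs(est / se), dfree, lower.tail = FALSE))
}

#' Single-mediator bootstrap mediation
#'
#' Three OLS fits on z-scored inputs: `m ~ x + cov` (path a),
#' `y ~ x + m + cov` (paths b and c'), `y ~ x + cov` (path c).  The
#' indirect effect is the product `ab = a * b`; its confidence interval and
#' p-value come from a percentile bootstrap over subjects.  The linear
#' decomposition `c = c' + ab` holds exactly on the same sample.
#'
#' @param x exposure (risk factor) vector.
#' @param m mediator (imaging score) vector.
#' @param y outcome (clinical score) vector.
#' @param covariates numeric matrix of adjustment covariates (no intercept
#'   column), full rank; may be NULL.
#' @param n_boot bootstrap replicates (default 5000; < 100 warns).
#' @param seed RNG seed.
#' @param standardize z-score x, m, y internally (default TRUE, so all
#'   paths are standardized effects).
#' @return a `mediation_result` list: paths `a`, `b`, `c`, `c_prime` (each
#'   with `est`, `se`, `p`), `ab`, `ab_ci` (percentile 95%), `ab_p`,
#'   `proportion_mediated` (NA and flagged unstable unless
#'   `|c| > 10 * SE(c)`), `n`, `n_boot`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000, seed = NULL,
                    standardize = TRUE) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (n_boot < 1) stop("n_boot must be positive")
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1)
      stop("rank-deficient covariate matrix")
  }
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) input variable")
  if (standardize) {
    x <- as.numeric(scale(x)); m <- as.numeric(scale(m))
    y <- as.numeric(scale(y))
  }
  cv <- if (is.null(covariates)) NULL else covariates
  Xa <- cbind(1, x, cv)                # m ~ x + cov          -> a at col 2
  Xb <- cbind(1, x, m, cv)             # y ~ x + m + cov      -> c' col 2, b col 3
  a_fit <- ols_path(Xa, m, 2L)
  b_fit <- ols_path(Xb, y, 3L)
  cp_fit <- ols_path(Xb, y, 2L)
  c_fit <- ols_path(Xa, y, 2L)         # same design as path a

  ab <- a_fit$est * b_fit$est
  ab_boot <- numeric(n_boot)
  with_seed(seed, {
    for (bb in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fa <- stats::lm.fit(Xa[idx, , drop = FALSE], m[idx])$coefficients[2]
      fb <- stats::lm.fit(Xb[idx, , drop = FALSE], y[idx])$coefficients[3]
      ab_boot[bb] <- fa * fb
    }
  })
  ab_ci <- stats::quantile(ab_boot, c(0.025, 0.975), names = FALSE)
  ab_p <- min(1, max(2 / n_boot,
                     2 * min(mean(ab_boot <= 0), mean(ab_boot >= 0))))
  stable_c <- abs(c_fit$est) > 10 * c_fit$se
  # single-model classification from raw p-values; the suite re-derives it
  # with FDR-adjusted p-values across risk factors
  classification <- classify_mediation(
    a_fit$p < 0.05, b_fit$p < 0.05, ab_p < 0.05, cp_fit$p < 0.05,
    abs(cp_fit$est) < abs(c_fit$est))
  structure(list(
    a = a_fit, b = b_fit, c = c_fit, c_prime = cp_fit,
    ab = ab, ab_ci = ab_ci, ab_p = ab_p,
    proportion_mediated = if (stable_c) ab / c_fit$est else NA_real_,
    proportion_stable = stable_c,
    classification = classification,
    n = n, n_boot = n_boot
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation> a = %.4f, b = %.4f, c = %.4f, c' = %.4f, ab = %.4f [%.4f, %.4f]\n",
    x$a$est, x$b$est, x$c$est, x$c_prime$est, x$ab, x$ab_ci[1], x$ab_ci[2]))
  invisible(x)
}

#' Mediation suite over the vascular risk factors
#'
#' Runs one [mediate()] per risk factor (imaging score as mediator,
#' clinical score as outcome, age/sex/education as covariates), then
#' applies FDR correction across risk factors separately within each effect
#' family (all a paths together, all b, all c, all c', all ab) and
#' classifies each factor: `full` mediation when a, b and ab are
#' significant and c' is not; `partial` when additionally c' remains
#' significant but attenuated (`|c'| < |c|`); `none` otherwise.
#'
#' @param cohort a [cohort_table()] providing risk factors and covariates.
#' @param imaging_score,clinical_score subject-level PLS scores aligned
#'   with the cohort rows.
#' @param risk_factors character vector (default all nine); missing columns
#'   are skipped with a warning.
#' @param n_boot,seed bootstrap settings (per-factor seeds derived from
#'   `seed`).
#' @return data.frame with one row per factor: paths, SEs, raw and
#'   FDR-adjusted p-values, `ab` with CI, `proportion_mediated`,
#'   `classification`.
#' @export
run_mediation_suite <- function(cohort, imaging_score, clinical_score,
                                risk_factors = risk_factor_names(),
                                n_boot = 5000, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- nrow(cohort)
  stopifnot(length(imaging_score) == n, length(clinical_score) == n)
  covs <- cbind(age = cohort$age, sex = sex_numeric(cohort$sex),
                education = cohort$education)
  present <- risk_factors %in% names(cohort)
  if (any(!present))
    warning("skipping missing risk factor(s): ",
            paste(risk_factors[!present], collapse = ", "))
  risk_factors <- risk_factors[present]
  res <- vector("list", length(risk_factors))
  for (i in seq_along(risk_factors)) {
    si <- if (is.null(seed)) NULL else (as.integer(seed) + i) %% .Machine$integer.max
    r <- mediate(cohort[[risk_factors[i]]], imaging_score, clinical_score,
                 covariates = covs, n_boot = n_boot, seed = si)
    res[[i]] <- data.frame(
      risk_factor = risk_factors[i],
      a = r$a$est, a_p = r$a$p,
      b = r$b$est, b_p = r$b$p,
      c = r$c$est, c_p = r$c$p,
      c_prime = r$c_prime$est, c_prime_p = r$c_prime$p,
      ab = r$ab, ab_lo = r$ab_ci[1], ab_hi = r$ab_ci[2], ab_p = r$ab_p,
      proportion_mediated = r$proportion_mediated,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  for (fam in c("a", "b", "c", "c_prime", "ab"))
    out[[paste0(fam, "_p_fdr")]] <- fdr_bh(out[[paste0(fam, "_p")]])
  sig <- function(p) !is.na(p) & p < 0.05
  out$classification <- classify_mediation(
    sig(out$a_p_fdr), sig(out$b_p_fdr), sig(out$ab_p_fdr),
    sig(out$c_prime_p_fdr), abs(out$c_prime) < abs(out$c))
  rownames(out) <- NULL
  out
}
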