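#' @title End-to-end analysis pipeline
#'
#' @description Orchestrates the full analysis: cohort simulation or
#'   ingestion, subject exclusions, imaging marker computation, clinical
#'   harmonization, confound residualization, PLS correlation with
#'   permutation and bootstrap inference, and the vascular-risk mediation
#'   suite.  All stage seeds derive deterministically from one master seed,
#'   so a re-run from a saved config reproduces every output.
#' @name pipeline_cli
NULL

#' Pipeline run configuration
#'
#' @param cohort_path CSV path to ingest, or NULL to simulate.
#' @param synthetic a [synthetic_config()] used when `cohort_path` is NULL
#'   (its seed is overridden by the derived stage seed).
#' @param domain_map a [domain_map()] for clinical harmonization.
#' @param exclusion_rules list of [exclusion_rule()]s; default PSMD 3-SD.
#' @param confounds confound set; currently `age`, `sex`, `education`, with
#'   optional `icv` as a sensitivity setting.
#' @param n_folds CV folds for age prediction.
#' @param n_perm,n_boot permutation / bootstrap replicates.
#' @param cv_folds folds for the out-of-fold score correlation.
#' @param gap_variants compute WMH brain age / microstructural brain age
#'   and use them in place of the absolute markers alongside relative brain
#'   age (sensitivity analysis).
#' @param seed master seed; every stage seed is derived from it.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort_path = NULL,
                       synthetic = synthetic_config(),
                       domain_map = default_domain_map("ukb"),
                       exclusion_rules = default_exclusion_rules(),
                       confounds = c("age", "sex", "education"),
                       n_folds = 5, n_perm = 500, n_boot = 500,
                       cv_folds = 10, gap_variants = FALSE,
                       seed = 1L, out_dir = NULL) {
  stopifnot(all(confounds %in% c("age", "sex", "education", "icv")),
            all(c("age", "sex", "education") %in% confounds))
  structure(as.list(environment()), class = "run_config")
}

#' Descriptive cohort summary
#'
#' Mean and standard deviation per numeric analysis variable plus the
#' percentage of female subjects — the tabular layout of a cohort
#' descriptives table.
#'
#' @param cohort a [cohort_table()].
#' @return data.frame: `variable`, `mean`, `sd`; the sex row reports
#'   `% female` in the `mean` column.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"), nrow(cohort) > 0)
  vars <- c("age", "education", risk_factor_names(), "wmh_volume", "icv",
            "psmd", attr(cohort, "test_cols"), attr(cohort, "motor_cols"))
  vars <- intersect(vars, names(cohort))
  rows <- data.frame(
    variable = c("sex_pct_female", vars),
    mean = c(100 * mean(cohort$sex == "female"),
             vapply(vars, function(v) mean(cohort[[v]]), numeric(1))),
    sd = c(NA_real_,
           vapply(vars, function(v) stats::sd(cohort[[v]]), numeric(1))),
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  rows
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate/ingest -> exclusions -> imaging markers ->
#' clinical harmonization -> residualization against confounds -> PLS
#' (fit, permutation, bootstrap, cross-validated score correlation) ->
#' per-marker regressions -> mediation suite on the LV1 subject scores.
#' Covariate check columns (age, sex, education) are appended to the
#' clinical block so their bootstrap CIs can confirm deconfounding.
#'
#' @param config a [run_config()].
#' @return a `run_bundle` list: `cohort`, `truth` (synthetic runs only),
#'   `exclusion_report`, `markers`, `clinical`, `pls` (model, permutation,
#'   bootstrap, score correlations), `regressions`, `mediation`, and a
#'   `manifest` with counts and stage seeds.  Written to `out_dir` as
#'   CSV/JSON when configured.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(
    simulate = stage_seed(config$seed, "simulate"),
    folds = stage_seed(config$seed, "folds"),
    permutation = stage_seed(config$seed, "permutation"),
    bootstrap = stage_seed(config$seed, "bootstrap"),
    crossval = stage_seed(config$seed, "crossval"),
    mediation = stage_seed(config$seed, "mediation")
  )

  truth <- NULL
  if (is.null(config$cohort_path)) {
    sim_cf <- config$synthetic
    sim_cf$seed <- seeds$simulate
    sim <- generate_cohort(sim_cf)
    cohort <- sim$cohort; truth <- sim$truth
  } else {
    cohort <- read_cohort(config$cohort_path)
  }

  excl <- apply_exclusions(cohort, config$exclusion_rules)
  cohort <- excl$cohort
  if (!is.null(truth)) {
    planted <- attributes(truth)[c("a_k", "b", "c_prime_k", "s_age")]
    truth <- truth[truth$subject_id %in% cohort$subject_id, , drop = FALSE]
    attributes(truth)[names(planted)] <- planted
  }

  markers <- compute_marker_panel(cohort, n_folds = config$n_folds,
                                  seed = seeds$folds,
                                  gap_variants = config$gap_variants)
  marker_cols <- if (config$gap_variants)
    c("relative_brain_age", "wmh_brain_age", "microstructural_brain_age")
  else c("relative_brain_age", "log_wmh_load", "psmd")
  X_raw <- as.matrix(markers[, marker_cols, drop = FALSE])

  clinical <- build_clinical_matrix(cohort, config$domain_map)

  conf <- cbind(age = cohort$age, sex = sex_numeric(cohort$sex),
                education = cohort$education)
  if ("icv" %in% config$confounds) conf <- cbind(conf, icv = cohort$icv)
  X <- zscore(residualize(X_raw, conf))
  Y <- zscore(residualize(clinical, conf))
  # covariate check columns: X is residualized against them, so their
  # loadings should be null (CIs covering 0) if deconfounding worked
  checks <- zscore(conf[, c("age", "sex", "education"), drop = FALSE])
  colnames(checks) <- paste0("check_", colnames(checks))
  Yc <- cbind(Y, checks)

  model <- fit_pls(X, Yc, sign_anchor = "relative_brain_age")
  perm <- permutation_test(X, Yc, n_perm = config$n_perm,
                           seed = seeds$permutation)
  boot <- bootstrap_stability(X, Yc, n_boot = config$n_boot,
                              seed = seeds$bootstrap,
                              sign_anchor = "relative_brain_age")
  r_sp <- score_correlation(model, 1L)
  cv <- crossval_score_correlation(X, Yc, k = config$cv_folds,
                                   seed = seeds$crossval)
  regressions <- per_marker_regressions(X, Y, conf)
  mediation <- run_mediation_suite(
    cohort, model$imaging_scores[, 1], model$clinical_scores[, 1],
    n_boot = config$n_boot, seed = seeds$mediation)

  manifest <- list(
    n_input = excl$report$n_input,
    n_retained = excl$report$n_retained,
    n_excluded_by_rule = excl$report$n_excluded_by_rule,
    seeds = seeds,
    n_perm = config$n_perm, n_boot = config$n_boot,
    n_folds = config$n_folds, cv_folds = config$cv_folds,
    confounds = config$confounds,
    marker_columns = marker_cols,
    covariance_explained = as.numeric(model$covariance_explained),
    lv_p_fdr = perm$p_fdr,
    score_correlation = r_sp,
    cv_score_correlation = cv$mean_correlation
  )

  bundle <- structure(list(
    cohort = cohort, truth = truth, exclusion_report = excl$report,
    markers = markers, clinical = clinical,
    pls = list(model = model, permutation = perm, bootstrap = boot,
               score_correlation = r_sp, crossval = cv),
    regressions = regressions, mediation = mediation,
    manifest = manifest, config = config
  ), class = "run_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<run_bundle> %d/%d subjects retained\n",
              m$n_retained, m$n_input))
  cat(sprintf("  LV1 covariance explained: %.1f%% (p_fdr = %.4g)\n",
              100 * m$covariance_explained[1], m$lv_p_fdr[1]))
  cat(sprintf("  score correlation r_sp = %.3f (10-fold CV mean %.3f)\n",
              m$score_correlation, m$cv_score_correlation))
  cat(sprintf("  mediation: %s\n",
              paste(sprintf("%s=%s", x$mediation$risk_factor,
                            x$mediation$classification), collapse = " ")))
  invisible(x)
}

#' Write a run bundle to disk
#'
#' Emits the marker panel, clinical matrix, PLS loadings and per-LV
#' summary, subject scores, regression table, mediation table (CSV) and the
#' JSON manifest.
#'
#' @param bundle a `run_bundle`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$markers, "markers.csv")
  wr(as.data.frame(bundle$clinical), "clinical.csv")
  m <- bundle$pls$model
  wr(data.frame(variable = rownames(m$u), m$u), "imaging_loadings.csv")
  wr(data.frame(variable = rownames(m$v), m$v), "clinical_loadings.csv")
  wr(cbind(as.data.frame(bundle$pls$permutation),
           covariance_explained = m$covariance_explained), "lv_summary.csv")
  wr(data.frame(subject_id = bundle$cohort$subject_id,
                imaging_score = m$imaging_scores[, 1],
                clinical_score = m$clinical_scores[, 1]),
     "subject_scores.csv")
  wr(bundle$regressions, "regressions.csv")
  wr(bundle$mediation, "mediation.csv")
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_exclusion_report(bundle$exclusion_report,
                         file.path(out_dir, "exclusion_report.json"))
  invisible(out_dir)
}
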