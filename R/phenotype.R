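#' @title Clinical score harmonization and shared statistics
#'
#' @description Harmonizes raw cognitive and motor test scores into
#'   analysis variables: timed scores (Trail Making Test, reaction time)
#'   are inverted and log transformed so higher always means better, tests
#'   are z-scored within the analysis sample and averaged into domain
#'   scores, grip strength is height-normalized.  Also provides confound
#'   residualization and Benjamini-Hochberg FDR adjustment used across the
#'   pipeline.
#' @name phenotype_prep
NULL

#' Invert-log transform for timed scores
#'
#' `-log(raw)`: strictly decreasing in the raw time, so larger transformed
#' values mean better (faster) performance.
#'
#' @param raw positive raw score (e.g. seconds).
#' @return transformed score.
#' @export
invert_log_transform <- function(raw) {
  if (any(raw <= 0)) stop("invert_log requires positive input")
  -log(raw)
}

#' Build a domain map
#'
#' @param domains named list: domain name -> character vector of test
#'   columns.
#' @param transforms named character vector: test -> `"identity"` or
#'   `"invert_log"`; unlisted tests default to identity.
#' @return a `domain_map` list.  Each test may appear in exactly one domain.
#' @export
domain_map <- function(domains, transforms = character()) {
  tests <- unlist(domains, use.names = FALSE)
  if (anyDuplicated(tests))
    stop("test(s) mapped to more than one domain: ",
         paste(unique(tests[duplicated(tests)]), collapse = ", "))
  bad <- setdiff(names(transforms), tests)
  if (length(bad)) stop("transform for unmapped test(s): ",
                        paste(bad, collapse = ", "))
  if (!all(transforms %in% c("identity", "invert_log")))
    stop("transforms must be 'identity' or 'invert_log'")
  structure(list(domains = domains, transforms = transforms),
            class = "domain_map")
}

#' Shipped domain-map presets
#'
#' Editable defaults mirroring the test batteries of the two emulated
#' cohorts (UKB-style and HCHS-style); the exact test-to-domain assignment
#' of any given study is a configuration choice, not package ground truth.
#'
#' @param preset `"ukb"` or `"hchs"`.
#' @return a [domain_map()].
#' @export
default_domain_map <- function(preset = c("ukb", "hchs")) {
  preset <- match.arg(preset)
  if (preset == "ukb") {
    domain_map(
      domains = list(
        memory = c("cog_numeric_memory", "cog_paired_associate"),
        executive_function = c("cog_tmt_b", "cog_tower_rearranging"),
        processing_speed = c("cog_tmt_a", "cog_reaction_time",
                             "cog_symbol_digit"),
        reasoning = c("cog_matrix_pattern", "cog_fluid_intelligence"),
        motor_activity = "mot_accelerometry"
      ),
      transforms = c(cog_tmt_a = "invert_log", cog_tmt_b = "invert_log",
                     cog_reaction_time = "invert_log")
    )
  } else {
    domain_map(
      domains = list(
        memory = "cog_word_list_recall",
        executive_function = c("cog_tmt_b", "cog_animal_naming"),
        processing_speed = "cog_tmt_a",
        crystallized = "cog_vocabulary",
        motor_mobility = "mot_timed_up_and_go"
      ),
      transforms = c(cog_tmt_a = "invert_log", cog_tmt_b = "invert_log",
                     mot_timed_up_and_go = "invert_log")
    )
  }
}

#' Domain scores from raw tests
#'
#' Per test: apply its transform, z-score within the analysis sample, then
#' average available (non-missing) tests within each domain.  Domain scores
#' are not re-z-scored unless `rescale = TRUE`.
#'
#' @param tests data.frame or matrix of raw test scores (subjects x tests).
#' @param map a [domain_map()].
#' @param rescale z-score the domain averages afterwards.
#' @return numeric matrix (subjects x domains); domains with zero available
#'   tests are dropped with a warning.
#' @export
build_domain_scores <- function(tests, map, rescale = FALSE) {
  stopifnot(inherits(map, "domain_map"))
  tests <- as.data.frame(tests)
  out <- list()
  for (dn in names(map$domains)) {
    cols <- intersect(map$domains[[dn]], names(tests))
    if (!length(cols)) {
      warning("domain `", dn, "` has no available tests; dropped")
      next
    }
    zs <- sapply(cols, function(cc) {
      v <- tests[[cc]]
      tr <- map$transforms[cc]
      if (!is.na(tr) && tr == "invert_log") v <- invert_log_transform(v)
      as.numeric(scale(v))
    })
    zs <- matrix(zs, nrow = nrow(tests))
    out[[dn]] <- rowMeans(zs, na.rm = TRUE)
  }
  if (!length(out)) stop("no domain could be scored")
  m <- do.call(cbind, out)
  colnames(m) <- names(out)
  if (rescale) m <- zscore(m)
  m
}

#' Height-normalized mean grip strength
#'
#' `((left + right) / 2) / height^2`, in kg/m^2.
#'
#' @param left,right grip strength (kg), non-negative.
#' @param height body height (m), positive.
#' @return normalized grip vector.
#' @export
#' @examples
#' normalize_grip(30, 32, 1.7)  # 10.727
normalize_grip <- function(left, right, height) {
  if (any(height <= 0)) stop("height must be positive")
  if (any(left < 0) || any(right < 0)) stop("grip must be non-negative")
  ((left + right) / 2) / height^2
}

#' Residualize variables against confounds
#'
#' Column-wise OLS residuals against the confound matrix (an intercept is
#' added internally).  Each residual column has mean zero and correlation
#' zero with every confound column, to numerical tolerance; residualizing
#' twice changes nothing.
#'
#' @param values numeric matrix (or data.frame) of variables to deconfound.
#' @param confounds numeric matrix of confounds (no intercept column
#'   needed), full rank.
#' @return residual matrix with the input's dimnames.
#' @export
residualize <- function(values, confounds) {
  values <- as.matrix(values)
  confounds <- as.matrix(confounds)
  stopifnot(nrow(values) == nrow(confounds))
  X <- cbind(1, confounds)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient confound matrix")
  res <- values - qr.fitted(qr_x, values)
  dimnames(res) <- dimnames(values)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, clipped at 1;
#' adjusted values never fall below the raw values and never reverse their
#' ranking.
#'
#' @param pvalues vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
fdr_bh <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- sum(!is.na(pvalues))
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  p <- pvalues[ok]
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  out[ok] <- adj
  out
}

#' Build the clinical analysis matrix from a cohort
#'
#' Domain scores from the cognitive battery plus the harmonized motor
#' variables (height-normalized grip where grip columns are present, any
#' `mot_*` columns via the domain map).
#'
#' @param cohort a [cohort_table()].
#' @param map a [domain_map()]; default UKB-style preset.
#' @return numeric matrix (subjects x clinical variables).
#' @export
build_clinical_matrix <- function(cohort, map = default_domain_map("ukb")) {
  stopifnot(inherits(cohort, "cohort_table"))
  raw_cols <- c(attr(cohort, "test_cols"), attr(cohort, "motor_cols"))
  tests <- as.data.frame(cohort)[, intersect(raw_cols, names(cohort)),
                                 drop = FALSE]
  m <- build_domain_scores(tests, map)
  if (all(c("grip_left", "grip_right", "height") %in% names(cohort))) {
    g <- normalize_grip(cohort$grip_left, cohort$grip_right, cohort$height)
    m <- cbind(m, grip_normalized = as.numeric(scale(g)))
  }
  m
}
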