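#' @title Cohort data model, file IO and subject exclusion
#'
#' @description A cohort is a wide per-subject table: demographics (age, sex,
#'   education), vascular risk factors, region-level morphometry, white
#'   matter hyperintensity (WMH) volume and intracranial volume (ICV), PSMD,
#'   and raw cognitive/motor test scores.  This file defines the validated
#'   `cohort_table` container, CSV read/write, and the exclusion-rule engine
#'   (e.g. removal of subjects whose PSMD deviates more than three standard
#'   deviations from the sample mean).
#' @name cohort_io
NULL

# canonical mandatory scalar columns
.mandatory_cols <- c(
  "subject_id", "age", "sex", "education",
  "bp_systolic", "bp_diastolic", "cholesterol_total", "cholesterol_ldl",
  "cholesterol_hdl", "triglycerides", "glucose", "waist_hip_ratio",
  "pack_years", "wmh_volume", "icv", "psmd"
)

#' Risk-factor column names
#'
#' The nine vascular risk factors carried by a cohort table, in the order
#' used throughout the mediation suite: systolic and diastolic blood
#' pressure, total/HDL/LDL cholesterol, triglycerides, glucose, waist-hip
#' ratio and pack years (packs per day times years smoked).
#'
#' @return character vector of length 9.
#' @export
risk_factor_names <- function() {
  c("bp_systolic", "bp_diastolic", "cholesterol_total", "cholesterol_hdl",
    "cholesterol_ldl", "triglycerides", "glucose", "waist_hip_ratio",
    "pack_years")
}

#' Construct a validated cohort table
#'
#' @param df data.frame holding one row per subject.
#' @param morph_cols character vector naming the morphometry feature columns
#'   (cortical thickness in mm, subcortical volumes in mm^3); order is part
#'   of the contract and preserved.
#' @param test_cols character vector naming raw cognitive test columns.
#' @param motor_cols character vector naming raw motor columns.
#' @param education_range inclusive ordinal bounds for the education code.
#' @return `df` with class `cohort_table` and the column-role attributes
#'   attached.
#' @details Validation enforces: all mandatory columns present and numeric
#'   (besides `subject_id` and `sex`); `age > 0`, `icv > 0`,
#'   `wmh_volume >= 0`; sex with exactly the levels female/male (or a
#'   0/1 coding, re-labelled as female = 0, male = 1); education inside the
#'   declared ordinal range.  Rows with missing mandatory imaging fields are
#'   dropped with a message (complete-case policy; no imputation).
#' @export
cohort_table <- function(df, morph_cols,
                         test_cols = character(),
                         motor_cols = character(),
                         education_range = c(1L, 6L)) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c(.mandatory_cols, morph_cols, test_cols, motor_cols),
                          names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  df$sex <- normalize_sex(df$sex)

  num_cols <- setdiff(c(.mandatory_cols, morph_cols), c("subject_id", "sex"))
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]]))
      stop(sprintf("column `%s` must be numeric", cc))
  }

  imaging <- c("age", "icv", "wmh_volume", "psmd", morph_cols)
  complete <- stats::complete.cases(df[imaging])
  if (any(!complete)) {
    message(sum(!complete), " row(s) dropped: missing mandatory imaging fields")
    df <- df[complete, , drop = FALSE]
  }
  if (!nrow(df)) stop("no complete rows remain")

  if (any(df$age <= 0)) stop("age must be positive")
  if (any(df$icv <= 0)) stop("icv must be positive")
  if (any(df$wmh_volume < 0)) stop("wmh_volume must be non-negative")
  ed <- df$education
  if (any(ed < education_range[1] | ed > education_range[2], na.rm = TRUE))
    stop("education outside declared ordinal range [",
         education_range[1], ", ", education_range[2], "]")

  rownames(df) <- NULL
  structure(df,
            morph_cols = morph_cols,
            test_cols = test_cols,
            motor_cols = motor_cols,
            education_range = as.integer(education_range),
            class = c("cohort_table", "data.frame"))
}

# accept "female"/"male" labels or 0/1 numeric; modeling code uses 0 = female,
# 1 = male (explicit coding, documented)
normalize_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) stop("numeric sex coding must be 0/1")
    sex <- ifelse(sex == 1, "male", "female")
  }
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male")))
    stop("sex must take exactly the levels female/male")
  factor(sex, levels = c("female", "male"))
}

# 0 = female, 1 = male
sex_numeric <- function(sex) as.integer(normalize_sex(sex)) - 1L

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d morphometry features, %d tests\n",
              nrow(x), length(attr(x, "morph_cols")),
              length(attr(x, "test_cols"))))
  cat(sprintf("  age %.1f +/- %.1f | %.1f%% female\n",
              mean(x$age), stats::sd(x$age),
              100 * mean(x$sex == "female")))
  invisible(x)
}

#' Read a cohort table from CSV/TSV
#'
#' @param path file path; comma-separated UTF-8 with a header row (`sep`
#'   switches to tab for `.tsv`).
#' @param schema optional column mapping: a named character vector
#'   `canonical = file_column` renaming file columns to the canonical names
#'   used by the package.  Unmapped extra columns are preserved untouched.
#' @param morph_cols morphometry column names (after mapping).  Default:
#'   every column starting with `thk_` or `vol_`.
#' @param test_cols,motor_cols raw test score columns (after mapping).
#'   Default: every column starting with `cog_` resp. `mot_`, plus
#'   grip/height columns.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, schema = NULL, morph_cols = NULL,
                        test_cols = NULL, motor_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    stopifnot(!is.null(names(schema)))
    miss <- setdiff(unname(schema), names(df))
    if (length(miss))
      stop("schema maps absent column(s): ", paste(miss, collapse = ", "))
    names(df)[match(unname(schema), names(df))] <- names(schema)
  }
  miss <- setdiff(.mandatory_cols, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))

  num_cols <- setdiff(.mandatory_cols, c("subject_id", "sex"))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("non-numeric value in column `%s` at row %d", cc, bad[1]))
      df[[cc]] <- parsed
    }
  }
  if (is.null(morph_cols))
    morph_cols <- grep("^(thk|vol)_", names(df), value = TRUE)
  if (is.null(test_cols))
    test_cols <- grep("^cog_", names(df), value = TRUE)
  if (is.null(motor_cols))
    motor_cols <- intersect(
      c(grep("^mot_", names(df), value = TRUE),
        "grip_left", "grip_right", "height"), names(df))
  cohort_table(df, morph_cols = morph_cols, test_cols = test_cols,
               motor_cols = motor_cols)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()] up to floating-point formatting (values are
#' written with full `double` precision, so a read/write round trip is an
#' identity at 1e-12 relative tolerance).
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Standard-deviation outlier mask
#'
#' Keep-mask that is `FALSE` exactly where `|x - mean(x)| > k * sd(x)`, with
#' mean and SD computed once on the full input vector (single-pass removal;
#' no iterative re-computation after exclusions).
#'
#' @param values numeric vector, length >= 2, finite.
#' @param k SD multiplier (default 3).
#' @return logical keep-mask aligned with `values`.
#' @export
#' @examples
#' exclude_outliers(c(rnorm(50), 100))
exclude_outliers <- function(values, k = 3) {
  if (!length(values)) stop("empty input")
  if (length(values) < 2) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("values must be finite")
  check_scalar(k, "k", lower = 0)
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation; keeping all values")
    return(rep(TRUE, length(values)))
  }
  abs(values - mean(values)) <= k * s
}

#' Build an exclusion rule
#'
#' @param name rule label used in the report.
#' @param field cohort column the rule inspects.
#' @param type `"sd_outlier"` (exclude beyond `k` SDs from the full-sample
#'   mean), `"range"` (exclude outside `[min, max]`), or `"flag"` (exclude
#'   where a boolean column is `TRUE` — the generic hook for cohort-specific
#'   illness-code exclusions).
#' @param k,min,max rule parameters.
#' @return an `exclusion_rule` list.
#' @export
exclusion_rule <- function(name, field,
                           type = c("sd_outlier", "range", "flag"),
                           k = 3, min = -Inf, max = Inf) {
  type <- match.arg(type)
  structure(list(name = name, field = field, type = type,
                 k = k, min = min, max = max),
            class = "exclusion_rule")
}

#' Apply exclusion rules to a cohort
#'
#' Rules are evaluated in declared order, each on the *original* sample
#' statistics (the full input cohort), then the union of excluded subjects
#' is removed in one step.
#'
#' @param cohort a [cohort_table()].
#' @param rules list of [exclusion_rule()] objects (may be empty).
#' @return list with elements `cohort` (retained subjects) and `report`
#'   (class `exclusion_report`: `n_input`, `n_excluded_by_rule`,
#'   `n_retained`, `excluded_ids`).
#' @export
apply_exclusions <- function(cohort, rules = list()) {
  stopifnot(inherits(cohort, "cohort_table"))
  n_input <- nrow(cohort)
  excl_by_rule <- integer(0)
  excluded <- rep(FALSE, n_input)
  for (r in rules) {
    stopifnot(inherits(r, "exclusion_rule"))
    if (!r$field %in% names(cohort))
      stop("exclusion rule `", r$name, "` references missing field `",
           r$field, "`")
    v <- cohort[[r$field]]
    drop <- switch(r$type,
      sd_outlier = !exclude_outliers(v, k = r$k),
      range = v < r$min | v > r$max,
      flag = as.logical(v) %in% TRUE
    )
    drop[is.na(drop)] <- FALSE
    excl_by_rule[r$name] <- sum(drop)
    excluded <- excluded | drop
  }
  report <- structure(list(
    n_input = n_input,
    n_excluded_by_rule = as.list(excl_by_rule),
    n_retained = n_input - sum(excluded),
    excluded_ids = as.character(cohort$subject_id[excluded])
  ), class = "exclusion_report")
  kept <- cohort[!excluded, , drop = FALSE]
  rownames(kept) <- NULL
  list(cohort = kept, report = report)
}

#' Default exclusion rule set
#'
#' The single quantitative rule applied before analysis: PSMD more than
#' three standard deviations from the sample mean.
#'
#' @param k SD multiplier.
#' @return list of rules suitable for [apply_exclusions()].
#' @export
default_exclusion_rules <- function(k = 3) {
  list(exclusion_rule("psmd_3sd", "psmd", "sd_outlier", k = k))
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d in, %d excluded, %d retained\n",
              x$n_input, x$n_input - x$n_retained, x$n_retained))
  for (nm in names(x$n_excluded_by_rule))
    cat(sprintf("  %-20s %d\n", nm, x$n_excluded_by_rule[[nm]]))
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report an `exclusion_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
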