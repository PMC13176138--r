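test_that("cohort round-trips through CSV up to float formatting", {
  cohort <- tiny_cohort(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_s3_class(back, "cohort_table")
  expect_equal(nrow(back), 3)
  num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  for (cc in num)
    expect_equal(back[[cc]], cohort[[cc]], tolerance = 1e-12)
  expect_identical(as.character(back$sex), as.character(cohort$sex))
  expect_identical(attr(back, "morph_cols"), attr(cohort, "morph_cols"))
})

test_that("missing mandatory column raises a schema error naming it", {
  df <- tiny_cohort_df(3)
  df$icv <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "icv")
})

test_that("non-numeric value in a numeric column reports the row", {
  df <- tiny_cohort_df(3)
  df$glucose <- as.character(df$glucose)
  df$glucose[2] <- "oops"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "glucose.*row 2")
})

test_that("schema mapping renames file columns to canonical names", {
  df <- tiny_cohort_df(3)
  names(df)[names(df) == "icv"] <- "IntracranialVol"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "icv")
  back <- read_cohort(path, schema = c(icv = "IntracranialVol"))
  expect_equal(back$icv, df$IntracranialVol, tolerance = 1e-12)
})

test_that("cohort validation enforces the declared invariants", {
  df <- tiny_cohort_df(5)
  bad <- df; bad$age[1] <- -1
  expect_error(cohort_table(bad, "thk_01"), "age")
  bad <- df; bad$education[2] <- 9
  expect_error(cohort_table(bad, "thk_01"), "education")
  bad <- df; bad$sex <- "other"
  expect_error(cohort_table(bad, "thk_01"), "sex")
  # missing imaging rows are dropped, not imputed
  df$psmd[3] <- NA
  expect_message(ct <- cohort_table(df, "thk_01"), "dropped")
  expect_equal(nrow(ct), 4)
})

test_that("exclude_outliers matches a brute-force z-score oracle", {
  set.seed(11)
  v <- c(rnorm(48), 8, -9)  # two gross outliers in a 50-point fixture
  oracle <- abs((v - mean(v)) / sd(v)) <= 3
  expect_identical(exclude_outliers(v, k = 3), oracle)
  expect_false(all(oracle))  # fixture actually exercises the rule
})

test_that("exclude_outliers is invariant under affine transforms", {
  set.seed(12)
  for (rep in 1:20) {
    v <- rnorm(60, sd = runif(1, 0.5, 4))
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    expect_identical(exclude_outliers(v), exclude_outliers(a * v + b))
  }
})

test_that("exclude_outliers edge cases", {
  expect_warning(keep <- exclude_outliers(rep(3, 5)), "zero standard")
  expect_true(all(keep))
  expect_error(exclude_outliers(numeric(0)), "empty")
  expect_error(exclude_outliers(1), "at least 2")
  expect_error(exclude_outliers(c(1, NA, 2)), "finite")
})

test_that("3-SD exclusion fraction on a big normal sample matches tail mass", {
  set.seed(13)
  v <- rnorm(1e5)
  frac <- mean(!exclude_outliers(v, k = 3))
  expect_equal(frac, 2 * pnorm(-3), tolerance = 0.001 / (2 * pnorm(-3)))
})

test_that("apply_exclusions reconciles counts and lists excluded ids", {
  # at n = 10 the largest attainable |z| is (n-1)/sqrt(n) ~ 2.85, so a
  # 3-SD rule can never fire; the toy uses k = 1.5 to exercise the flow
  cohort <- tiny_cohort(10)
  cohort$psmd[c(3, 7)] <- c(10e-4, 12e-4)
  res <- apply_exclusions(
    cohort, list(exclusion_rule("psmd_sd", "psmd", "sd_outlier", k = 1.5)))
  expect_equal(res$report$n_input, 10)
  expect_equal(res$report$n_retained, 8)
  expect_setequal(res$report$excluded_ids,
                  cohort$subject_id[c(3, 7)])
  expect_equal(res$report$n_excluded_by_rule$psmd_sd, 2)
  expect_equal(nrow(res$cohort), 8)
  # retained + excluded always sum to input
  expect_equal(res$report$n_retained + length(res$report$excluded_ids),
               res$report$n_input)
})

test_that("empty rule list leaves the cohort unchanged", {
  cohort <- tiny_cohort(6)
  res <- apply_exclusions(cohort, list())
  expect_equal(nrow(res$cohort), 6)
  expect_equal(res$report$n_retained, 6)
  expect_length(res$report$excluded_ids, 0)
})

test_that("rules referencing missing fields fail; flag rules work", {
  cohort <- tiny_cohort(8)
  expect_error(
    apply_exclusions(cohort, list(exclusion_rule("x", "nope", "flag"))),
    "missing field")
  cohort$bad_scan <- rep(c(TRUE, FALSE), 4)
  res <- apply_exclusions(cohort,
                          list(exclusion_rule("qc", "bad_scan", "flag")))
  expect_equal(res$report$n_retained, 4)
})

test_that("exclusion report serializes to JSON", {
  res <- apply_exclusions(tiny_cohort(5), list())
  path <- withr::local_tempfile(fileext = ".json")
  write_exclusion_report(res$report, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$n_input, 5)
  expect_equal(j$n_retained, 5)
})
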