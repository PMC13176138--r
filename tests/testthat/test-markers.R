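test_that("a perfect age feature yields near-zero out-of-fold error", {
  set.seed(31)
  n <- 120
  age <- runif(n, 45, 80)
  sex <- rep(c("female", "male"), length.out = n)
  features <- cbind(age_copy = age, junk = rnorm(n))
  fit <- fit_predict_age(features, age, sex, n_folds = 5, seed = 1)
  expect_lt(mean(abs(fit$predicted_age - age)), 1e-6)
  expect_lt(fit$metrics$female["mae"], 1e-6)
})

test_that("age-independent features give non-positive out-of-fold R^2", {
  set.seed(32)
  r2 <- replicate(50, {
    n <- 200
    age <- runif(n, 45, 80)
    sex <- rep(c("female", "male"), length.out = n)
    features <- matrix(rnorm(n * 3), n, 3)
    fit <- fit_predict_age(features, age, sex, n_folds = 5, seed = 1)
    c(fit$metrics$female["r2"], fit$metrics$male["r2"])
  })
  # out-of-fold R^2 of pure noise models is negative in expectation
  expect_lt(mean(r2), 0)
  expect_lt(quantile(r2, 0.9), 0.1)
})

test_that("planted aging slopes are recovered from the synthetic cohort", {
  sim <- generate_cohort(synthetic_config(n_subjects = 5000, seed = 41,
                                          md_voxels_per_subject = 200L))
  co <- sim$cohort
  morph <- as.matrix(as.data.frame(co)[, attr(co, "morph_cols")])
  fit <- fit_predict_age(morph, co$age, co$sex, n_folds = 5, seed = 2)
  expect_gt(cor(fit$predicted_age, co$age), 0.8)
  # two-stage corrected gap tracks the planted brain-aging deviation
  rba <- relative_brain_age(fit$predicted_age, co$age, co$sex)
  expect_gt(cor(rba$relative_brain_age, sim$truth$delta), 0.5)
})

test_that("rank-deficient features fail loudly, ridge overrides", {
  set.seed(33)
  n <- 60
  age <- runif(n, 45, 80)
  sex <- rep("female", n)
  x <- rnorm(n)
  features <- cbind(f1 = x, f2 = 2 * x)
  expect_error(
    suppressWarnings(fit_predict_age(features, age, sex, seed = 1)),
    "collinear")
  expect_silent(
    suppressWarnings(fit_predict_age(features, age, sex, seed = 1,
                                     ridge = TRUE)))
})

test_that("relative brain age absorbs constant offsets and keeps noise", {
  set.seed(34)
  n <- 400
  age <- runif(n, 45, 80)
  sex <- rep(c("female", "male"), length.out = n)
  # constant shift: gap is identically zero
  r <- relative_brain_age(age + 5, age, sex)
  expect_lt(max(abs(r$relative_brain_age)), 1e-10)
  # shrunk slope + noise: the gap is exactly the stratum OLS residual, so
  # it is orthogonal to age and recovers the noise component
  noise <- rnorm(n)
  pred <- 0.5 * age + noise
  r <- relative_brain_age(pred, age, sex)
  for (s in c("female", "male")) {
    idx <- sex == s
    expect_lt(abs(cor(r$relative_brain_age[idx], age[idx])), 1e-8)
    resid_oracle <- residuals(lm(pred[idx] ~ age[idx]))
    expect_equal(r$relative_brain_age[idx], unname(resid_oracle),
                 tolerance = 1e-10)
  }
  expect_gt(cor(r$relative_brain_age, noise), 0.99)
  expect_lt(abs(mean(r$relative_brain_age)), 1e-10)
})

test_that("single sex level computes one stratum with a warning", {
  set.seed(35)
  age <- runif(50, 45, 80)
  expect_warning(r <- relative_brain_age(age + rnorm(50), age,
                                         rep("female", 50)),
                 "single sex")
  expect_lt(abs(cor(r$relative_brain_age, age)), 1e-8)
})

test_that("WMH load arithmetic and edge handling", {
  # load of exactly 1% logs to ~0 (up to the declared floor)
  r <- compute_wmh_load(16, 1600)
  expect_equal(r$load_pct, 1)
  expect_equal(r$log_wmh_load, log(1 + 1e-3))
  # monotone in volume for fixed ICV
  v <- seq(0.5, 20, length.out = 50)
  expect_true(all(diff(compute_wmh_load(v, 1500)$log_wmh_load) > 0))
  # zero volume is floored, finite and flagged
  expect_message(r0 <- compute_wmh_load(0, 1500), "floored")
  expect_equal(r0$log_wmh_load, log(1e-3))
  expect_error(compute_wmh_load(-1, 1500), "non-negative")
  expect_error(compute_wmh_load(1, 0), "positive")
})

test_that("PSMD follows the linear-interpolation percentile convention", {
  expect_equal(compute_psmd(rep(2e-4, 30)), 0)
  # brute-force oracle on 0..100: sorted grid where type-7 interpolation
  # lands exactly on the 5 and 95 values
  v <- 0:100
  oracle <- unname(quantile(v, 0.95, type = 7) - quantile(v, 0.05, type = 7))
  expect_equal(oracle, 90)
  expect_equal(compute_psmd(v), 90)
  expect_error(compute_psmd(1:10), "at least 20")
})

test_that("PSMD is order-invariant and affine-equivariant", {
  set.seed(36)
  for (rep in 1:10) {
    v <- rlnorm(500)
    expect_equal(compute_psmd(sample(v)), compute_psmd(v))
    a <- runif(1, 0.1, 5); c <- runif(1, -2, 2)
    expect_equal(compute_psmd(a * v + c), a * compute_psmd(v),
                 tolerance = 1e-12)
  }
})

test_that("marker gap reduces to the two-stage pipeline on one marker", {
  set.seed(37)
  n <- 300
  age <- runif(n, 45, 80)
  sex <- rep(c("female", "male"), length.out = n)
  # exact linear function of age: gap is identically zero
  gap <- marker_gap(3 * age + 2, age, sex, seed = 1)
  expect_lt(max(abs(gap)), 1e-6)
  # age signal + independent noise: gap tracks the noise, orthogonal to age
  noise <- rnorm(n)
  gap <- marker_gap(0.02 * age + 0.05 * noise, age, sex, seed = 1)
  expect_lt(abs(cor(gap, age)), 0.05)  # out-of-fold, so near- not exact-zero
  expect_gt(abs(cor(gap, noise)), 0.8)
})

test_that("marker panel carries diagnostics and optional gap variants", {
  sim <- generate_cohort(synthetic_config(n_subjects = 600, seed = 42,
                                          md_voxels_per_subject = 200L))
  panel <- compute_marker_panel(sim$cohort, seed = 3, gap_variants = TRUE)
  expect_named(panel, c("subject_id", "relative_brain_age", "log_wmh_load",
                        "psmd", "wmh_brain_age", "microstructural_brain_age"))
  expect_true(all(is.finite(panel$relative_brain_age)))
  diag <- attr(panel, "brain_age")
  expect_named(diag$metrics, c("female", "male"))
  # gap variants are orthogonal to age within stratum by construction
  for (s in c("female", "male")) {
    idx <- sim$cohort$sex == s
    expect_lt(abs(cor(panel$wmh_brain_age[idx], sim$cohort$age[idx])), 1e-8)
  }
})
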