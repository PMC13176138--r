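# Fixtures are built in code; nothing is read from disk.

# minimal valid cohort data.frame with all mandatory columns, two
# morphometry features and one raw test column
tiny_cohort_df <- function(n = 10, seed = 42) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    data.frame(
      subject_id = sprintf("T%03d", seq_len(n)),
      age = runif(n, 50, 75),
      sex = rep(c("female", "male"), length.out = n),
      education = sample(1:6, n, replace = TRUE),
      bp_systolic = rnorm(n, 138, 18),
      bp_diastolic = rnorm(n, 79, 10),
      cholesterol_total = rnorm(n, 5.7, 1.1),
      cholesterol_hdl = rnorm(n, 1.5, 0.4),
      cholesterol_ldl = rnorm(n, 3.6, 0.8),
      triglycerides = rlnorm(n, 0.3, 0.5),
      glucose = rnorm(n, 5, 1),
      waist_hip_ratio = rnorm(n, 0.9, 0.1),
      pack_years = rlnorm(n, 2.5, 0.8),
      wmh_volume = rlnorm(n, 1.2, 0.8),
      icv = rnorm(n, 1500, 120),
      psmd = rnorm(n, 2.29e-4, 3e-5),
      thk_01 = rnorm(n, 2.5, 0.1),
      vol_01 = rnorm(n, 5000, 300),
      cog_test = rnorm(n, 10, 2),
      stringsAsFactors = FALSE
    )
  })
}

tiny_cohort <- function(n = 10, seed = 42) {
  cohort_table(tiny_cohort_df(n, seed),
               morph_cols = c("thk_01", "vol_01"),
               test_cols = "cog_test")
}

# rank-1 planted cross-block coupling: X = z u' + noise, Y = z v' + noise
planted_rank1 <- function(n = 500, p = 3, q = 8, noise = 0.3, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  u <- rep(1 / sqrt(p), p)
  v <- rep(1 / sqrt(q), q)
  list(
    X = tcrossprod(z, u) + matrix(rnorm(n * p, 0, noise), n, p),
    Y = tcrossprod(z, v) + matrix(rnorm(n * q, 0, noise), n, q),
    u = u, v = v, z = z
  )
}

# cosine similarity up to sign
abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
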