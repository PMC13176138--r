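#' @title Synthetic cohort generation
#'
#' @description Generates cohorts with the statistical structure the
#'   analysis assumes: population marginals matching a large UK
#'   population-imaging cohort (age 63.7 +/- 7.6 y, systolic BP
#'   138.6 +/- 18.6 mmHg, ...), a single latent brain-aging deviation
#'   \eqn{\delta} (years) that couples vascular risk, imaging markers and
#'   behavior, and planted risk -> \eqn{\delta} -> performance mediation
#'   paths.  Ground truth is returned alongside the cohort so parameter
#'   recovery is testable end to end.
#' @name synthetic_cohort
NULL

# UKB-style marginal moments (mean, sd); pack_years and triglycerides are
# drawn log-normal to respect non-negativity and skew
.default_moments <- list(
  age               = c(63.7, 7.6),
  bp_systolic       = c(138.6, 18.6),
  bp_diastolic      = c(78.7, 10),
  cholesterol_total = c(5.7, 1.1),
  cholesterol_ldl   = c(3.6, 0.8),
  cholesterol_hdl   = c(1.5, 0.4),
  triglycerides     = c(1.6, 1),
  glucose           = c(5.0, 1),
  waist_hip_ratio   = c(0.9, 0.1),
  pack_years        = c(18.8, 15.7),
  icv               = c(1500, 130)
)

# risk -> delta paths (years of brain aging per SD of risk factor); the three
# cholesterol fractions are deliberately null so the mediation suite has a
# planted negative control, mirroring the observed null for lipids
.default_a <- c(
  bp_systolic = 0.8, bp_diastolic = 0.8, cholesterol_total = 0,
  cholesterol_hdl = 0, cholesterol_ldl = 0, triglycerides = 0.5,
  glucose = 0.8, waist_hip_ratio = 1.0, pack_years = 1.0
)

# direct risk -> behavior paths (standardized); HDL protective
.default_c_prime <- c(
  bp_systolic = -0.03, bp_diastolic = -0.04, cholesterol_total = 0,
  cholesterol_hdl = 0.10, cholesterol_ldl = -0.03, triglycerides = -0.07,
  glucose = -0.02, waist_hip_ratio = -0.13, pack_years = -0.07
)

# cognitive/motor battery: native-scale moments, latent loading, transform
.default_tests <- list(
  cog_numeric_memory     = list(mean = 6.79,  sd = 1.3,  loading = 0.7, transform = "identity",   domain = "memory"),
  cog_tmt_a              = list(mean = 22.45, sd = 8.1,  loading = 0.7, transform = "invert_log", domain = "processing_speed"),
  cog_tmt_b              = list(mean = 57.13, sd = 25.7, loading = 0.7, transform = "invert_log", domain = "executive_function"),
  cog_matrix_pattern     = list(mean = 8.03,  sd = 2.1,  loading = 0.7, transform = "identity",   domain = "reasoning"),
  cog_fluid_intelligence = list(mean = 6.66,  sd = 2.1,  loading = 0.7, transform = "identity",   domain = "reasoning"),
  cog_reaction_time      = list(mean = 0.59,  sd = 0.1,  loading = 0.7, transform = "invert_log", domain = "processing_speed"),
  cog_paired_associate   = list(mean = 6.98,  sd = 2.6,  loading = 0.7, transform = "identity",   domain = "memory"),
  cog_tower_rearranging  = list(mean = 9.97,  sd = 3.2,  loading = 0.7, transform = "identity",   domain = "executive_function"),
  cog_symbol_digit       = list(mean = 19.06, sd = 5.2,  loading = 0.7, transform = "identity",   domain = "processing_speed"),
  mot_accelerometry      = list(mean = 28.5,  sd = 7.8,  loading = 0.6, transform = "identity",   domain = "motor_activity")
)

#' Synthetic cohort configuration
#'
#' Collects every tunable of the generative model with defaults stating the
#' emulated population.  Identical config + seed yields an identical cohort.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer RNG seed.
#' @param moments named list of `c(mean, sd)` population moments; defaults
#'   to the UKB-style values above.
#' @param n_cortical,n_subcortical morphometry feature counts (defaults 68
#'   cortical thickness regions, 16 subcortical volumes).
#' @param delta_sd SD (years) of the idiosyncratic part of the brain-aging
#'   deviation \eqn{\delta}.
#' @param a_k named vector: years of \eqn{\delta} per SD of each risk factor.
#' @param b standardized effect of \eqn{z(\delta)} on the behavioral latent
#'   (entering with a negative sign: older-appearing brains perform worse).
#' @param c_prime_k named vector of direct standardized risk effects on the
#'   behavioral latent.
#' @param s_age standardized chronological-age effect on behavior, so
#'   deconfounding is exercised non-trivially.
#' @param behavior_noise SD of the behavioral latent's idiosyncratic part.
#' @param thickness_noise,volume_noise_frac idiosyncratic marker noise:
#'   absolute (mm) for thickness, fraction of the region mean for volumes.
#' @param wmh_slope,wmh_noise,log_wmh_base log-WMH-load model:
#'   `log load% = base + slope * (age + delta - mean age) + noise`.
#' @param psmd_slope,psmd_noise PSMD target model (mm^2/s per year, mm^2/s).
#' @param md_voxels_per_subject voxels drawn per subject when simulating
#'   skeleton MD values.
#' @param education_probs probabilities over ordinal education levels 1..6
#'   (defaults give mean 4.5, SD 1.26).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 2000,
                             seed = 1L,
                             moments = .default_moments,
                             n_cortical = 68L,
                             n_subcortical = 16L,
                             delta_sd = 3,
                             a_k = .default_a,
                             b = 0.35,
                             c_prime_k = .default_c_prime,
                             s_age = 0.3,
                             behavior_noise = 0.85,
                             thickness_noise = 0.1,
                             volume_noise_frac = 0.05,
                             wmh_slope = 0.04,
                             wmh_noise = 0.5,
                             log_wmh_base = log(0.25),
                             psmd_slope = 3e-6,
                             psmd_noise = 2.5e-5,
                             md_voxels_per_subject = 2000L,
                             education_probs = c(0.02, 0.06, 0.12, 0.25, 0.30, 0.25),
                             tests = .default_tests) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  sds <- c(vapply(moments, `[`, numeric(1), 2), delta_sd, behavior_noise,
           thickness_noise, volume_noise_frac, psmd_noise)
  if (any(sds <= 0)) stop("all SDs must be positive")
  stopifnot(setequal(names(a_k), risk_factor_names()),
            setequal(names(c_prime_k), risk_factor_names()),
            all(is.finite(c(a_k, b, c_prime_k, s_age))))
  structure(as.list(environment()), class = "synthetic_config")
}

# mean/sd -> log-normal parameters
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

rtruncnorm_simple <- function(n, mean, sd, lower, upper) {
  # inverse-CDF truncation: exact and vectorized
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort with ground truth
#'
#' Generative model, in order: (1) age ~ truncated Normal(63.7, 7.6) on
#' \[45, 80\], sex ~ Bernoulli(0.5), ordinal education; (2) risk factors from
#' the configured moments (log-normal for pack years and triglycerides);
#' (3) brain-aging deviation
#' \eqn{\delta_i = \sum_k a_k z(risk_{ik}) + \epsilon}; (4) each
#' morphometric feature declines linearly in biological age
#' \eqn{age_i + \delta_i} plus noise; (5) log WMH load and the PSMD target
#' are linear in biological age plus marker noise; (6) the behavioral latent
#' \eqn{\eta_i = -b\,z(\delta_i) + \sum_k c'_k z(risk_{ik}) - s_{age} z(age_i)
#' + \epsilon} drives every test score, mapped to its native scale (timed
#' tests via the log-normal inverse of the invert-log harmonization, grip in
#' kg with height ~ Normal by sex).
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` (a [cohort_table()]) and `truth` (data.frame
#'   with per-subject `delta` and `eta`, plus the realized path coefficients
#'   as attributes `a_k`, `b`, `c_prime_k`, `s_age`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  n <- cf$n_subjects
  with_seed(cf$seed, {
    mom <- cf$moments
    age <- rtruncnorm_simple(n, mom$age[1], mom$age[2], 45, 80)
    sex <- factor(ifelse(stats::runif(n) < 0.5, "male", "female"),
                  levels = c("female", "male"))
    education <- sample(seq_along(cf$education_probs), n, replace = TRUE,
                        prob = cf$education_probs)

    rf <- risk_factor_names()
    risk <- matrix(NA_real_, n, length(rf), dimnames = list(NULL, rf))
    for (v in rf) {
      m <- mom[[v]]
      if (v %in% c("pack_years", "triglycerides")) {
        p <- lnorm_params(m[1], m[2])
        risk[, v] <- stats::rlnorm(n, p["meanlog"], p["sdlog"])
      } else {
        risk[, v] <- stats::rnorm(n, m[1], m[2])
      }
    }
    risk_z <- zscore(risk)

    delta <- drop(risk_z %*% cf$a_k[rf]) + stats::rnorm(n, 0, cf$delta_sd)
    bioage <- age + delta

    # morphometry: deterministic per-region means/slopes, linear decline
    thk_mu <- seq(2.2, 3.0, length.out = cf$n_cortical)
    thk_slope <- seq(0.0025, 0.0060, length.out = cf$n_cortical)
    vol_mu <- seq(1500, 20000, length.out = cf$n_subcortical)
    vol_slope_frac <- seq(0.0010, 0.0022, length.out = cf$n_subcortical)
    morph <- matrix(NA_real_, n, cf$n_cortical + cf$n_subcortical)
    colnames(morph) <- c(sprintf("thk_%02d", seq_len(cf$n_cortical)),
                         sprintf("vol_%02d", seq_len(cf$n_subcortical)))
    centered <- bioage - mom$age[1]
    for (j in seq_len(cf$n_cortical))
      morph[, j] <- thk_mu[j] - thk_slope[j] * centered +
        stats::rnorm(n, 0, cf$thickness_noise)
    for (j in seq_len(cf$n_subcortical))
      morph[, cf$n_cortical + j] <- vol_mu[j] * (1 - vol_slope_frac[j] * centered) +
        stats::rnorm(n, 0, cf$volume_noise_frac * vol_mu[j])

    icv <- stats::rnorm(n, mom$icv[1], mom$icv[2])
    log_load <- cf$log_wmh_base + cf$wmh_slope * centered +
      stats::rnorm(n, 0, cf$wmh_noise)
    wmh_volume <- exp(log_load) / 100 * icv

    psmd_target <- 2.29e-4 + cf$psmd_slope * centered +
      stats::rnorm(n, 0, cf$psmd_noise)
    psmd_target <- pmax(psmd_target, 1e-5)
    psmd <- simulate_psmd_from_voxels(psmd_target, cf$md_voxels_per_subject)

    # behavioral latent and test battery
    eta <- -cf$b * as.numeric(scale(delta)) +
      drop(risk_z %*% cf$c_prime_k[rf]) -
      cf$s_age * as.numeric(scale(age)) +
      stats::rnorm(n, 0, cf$behavior_noise)
    eta_z <- as.numeric(scale(eta))

    tests <- cf$tests
    test_mat <- matrix(NA_real_, n, length(tests),
                       dimnames = list(NULL, names(tests)))
    for (tn in names(tests)) {
      tt <- tests[[tn]]
      z <- tt$loading * eta_z + stats::rnorm(n, 0, sqrt(1 - tt$loading^2))
      if (tt$transform == "invert_log") {
        p <- lnorm_params(tt$mean, tt$sd)
        test_mat[, tn] <- exp(p["meanlog"] - p["sdlog"] * z)
      } else {
        test_mat[, tn] <- tt$mean + tt$sd * z
      }
    }

    # grip strength: strong sex effect, shared latent; height by sex
    grip_z <- 0.6 * eta_z + stats::rnorm(n, 0, 0.8)
    grip_base <- ifelse(sex == "male", 37, 24)
    grip_left <- grip_base + 5 * grip_z + stats::rnorm(n, 0, 1.5)
    grip_right <- grip_base + 5 * grip_z + stats::rnorm(n, 0, 1.5)
    height <- ifelse(sex == "male", stats::rnorm(n, 1.77, 0.06),
                     stats::rnorm(n, 1.63, 0.06))

    df <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n)),
      age = age, sex = sex, education = education,
      risk, wmh_volume = wmh_volume, icv = icv, psmd = psmd,
      test_mat,
      grip_left = pmax(grip_left, 0), grip_right = pmax(grip_right, 0),
      height = height,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    cohort <- cohort_table(df,
      morph_cols = character(0),
      test_cols = names(tests),
      motor_cols = c("grip_left", "grip_right", "height"))
    # bind morphometry after validation to keep attribute bookkeeping simple
    cohort <- cbind_morph(cohort, morph)

    truth <- data.frame(subject_id = df$subject_id, delta = delta, eta = eta)
    attr(truth, "a_k") <- cf$a_k
    attr(truth, "b") <- cf$b
    attr(truth, "c_prime_k") <- cf$c_prime_k
    attr(truth, "s_age") <- cf$s_age
    list(cohort = cohort, truth = truth)
  })
}

cbind_morph <- function(cohort, morph) {
  at <- attributes(cohort)
  df <- cbind(as.data.frame(cohort), as.data.frame(morph))
  structure(df,
            morph_cols = colnames(morph),
            test_cols = at$test_cols,
            motor_cols = at$motor_cols,
            education_range = at$education_range,
            class = c("cohort_table", "data.frame"))
}

# draw per-subject MD voxel samples whose p95 - p5 equals the target in
# expectation (Normal sample: p95 - p5 = 2 * qnorm(0.95) * sd), return the
# realized peak widths; chunked so memory stays bounded
simulate_psmd_from_voxels <- function(target, n_voxels, md_center = 7.3e-4) {
  sd_v <- target / (2 * stats::qnorm(0.95))
  n <- length(target)
  out <- numeric(n)
  chunk <- max(1L, floor(2e6 / n_voxels))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    m <- matrix(stats::rnorm(length(idx) * n_voxels), length(idx), n_voxels)
    m <- m * sd_v[idx] + md_center
    out[idx] <- apply(m, 1, function(v) compute_psmd(v))
  }
  out
}

#' Simulate skeleton MD voxel values for given PSMD targets
#'
#' Returns the per-subject voxel matrix (unordered values, no geometry) so
#' that `compute_psmd()` on each row matches the target in expectation.
#'
#' @param target vector of PSMD targets (mm^2/s).
#' @param n_voxels voxels per subject.
#' @param seed RNG seed.
#' @return numeric matrix, `length(target)` x `n_voxels`.
#' @export
simulate_md_values <- function(target, n_voxels = 10000L, seed = NULL) {
  if (length(target) * n_voxels > 5e7) stop("requested MD matrix too large")
  with_seed(seed, {
    sd_v <- target / (2 * stats::qnorm(0.95))
    matrix(stats::rnorm(length(target) * n_voxels), length(target), n_voxels) *
      sd_v + 7.3e-4
  })
}

#' Independent imaging/clinical matrix pair (null model)
#'
#' Two independent standard-normal matrices with zero population
#' cross-covariance — the calibration harness for permutation testing.
#'
#' @param n rows (subjects); must exceed `max(p, q)`.
#' @param p,q imaging / clinical dimensions.
#' @param seed RNG seed.
#' @return list with matrices `X` (n x p) and `Y` (n x q).
#' @export
make_null_pair <- function(n, p, q, seed = NULL) {
  if (n <= max(p, q)) stop("need n > max(p, q)")
  with_seed(seed, list(
    X = matrix(stats::rnorm(n * p), n, p,
               dimnames = list(NULL, paste0("x", seq_len(p)))),
    Y = matrix(stats::rnorm(n * q), n, q,
               dimnames = list(NULL, paste0("y", seq_len(q))))
  ))
}
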