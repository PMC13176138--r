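test_that("p = q = 1 with identical blocks gives the degenerate solution", {
  set.seed(61)
  x <- matrix(rnorm(100), dimnames = list(NULL, "m"))
  fit <- fit_pls(x, x)
  expect_equal(abs(drop(fit$u)), 1)
  expect_equal(abs(drop(fit$v)), 1)
  expect_equal(fit$covariance_explained, 1)
  expect_equal(score_correlation(fit, 1), 1)
})

test_that("singular values match a dense SVD of the explicit cross-correlation", {
  # oracle route: stats::cor builds the cross-block matrix, base svd
  # decomposes it; the fitted route must agree to 1e-10
  set.seed(62)
  for (rep in 1:10) {
    n <- 40
    X <- matrix(rnorm(n * 5), n, 5)
    Y <- matrix(rnorm(n * 8), n, 8)
    fit <- fit_pls(X, Y)
    oracle <- svd(cor(X, Y))$d
    expect_equal(fit$singular_values, oracle[1:5], tolerance = 1e-10)
    expect_equal(sum(fit$covariance_explained), 1, tolerance = 1e-10)
  }
})

test_that("a planted rank-1 coupling is recovered", {
  pl <- planted_rank1(n = 800, p = 3, q = 8, noise = 0.3, seed = 63)
  fit <- fit_pls(pl$X, pl$Y)
  expect_gt(fit$covariance_explained[1], 0.9)
  expect_gt(abs_cosine(fit$u[, 1], pl$u), 0.95)
  expect_gt(abs_cosine(fit$v[, 1], pl$v), 0.95)
  # sign convention: anchor loading oriented positive on every component
  expect_true(all(fit$u[1, ] >= 0))
})

test_that("columns of U and V are unit norm, singular values descending", {
  np <- make_null_pair(120, 4, 6, seed = 64)
  fit <- fit_pls(np$X, np$Y)
  expect_equal(colSums(fit$u^2), rep(1, 4), ignore_attr = TRUE)
  expect_equal(colSums(fit$v^2), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  expect_error(fit_pls(cbind(np$X, const = 1), np$Y), "const")
})

test_that("global sign flips leave invariants unchanged", {
  pl <- planted_rank1(n = 400, seed = 65)
  fit <- fit_pls(pl$X, pl$Y)
  flipped <- fit_pls(-pl$X, pl$Y)  # flips loadings, not the geometry
  expect_equal(flipped$singular_values, fit$singular_values,
               tolerance = 1e-10)
  expect_equal(flipped$covariance_explained, fit$covariance_explained,
               tolerance = 1e-10)
  expect_equal(abs(flipped$u), abs(fit$u), tolerance = 1e-8)
})

test_that("permutation p-values are seeded, reproducible and bounded", {
  pl <- planted_rank1(n = 300, noise = 0.2, seed = 66)
  p1 <- permutation_test(pl$X, pl$Y, n_perm = 200, seed = 7)
  p2 <- permutation_test(pl$X, pl$Y, n_perm = 200, seed = 7)
  expect_identical(p1$p, p2$p)
  # strong planted signal attains the add-one minimum
  expect_equal(p1$p[1], 1 / 201)
  expect_true(all(p1$p > 0 & p1$p <= 1))
  expect_true(all(p1$p_fdr >= p1$p))
  expect_warning(permutation_test(pl$X, pl$Y, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("rotation-aligned permutation scheme also rejects planted signal", {
  pl <- planted_rank1(n = 300, noise = 0.2, seed = 67)
  pr <- permutation_test(pl$X, pl$Y, n_perm = 200, seed = 8, rotate = TRUE)
  expect_equal(pr$p[1], 1 / 201)
})

test_that("bootstrap separates planted from null variables", {
  pl <- planted_rank1(n = 2000, p = 3, q = 6, noise = 0.3, seed = 68)
  set.seed(6800)
  X <- cbind(pl$X, noise_var = rnorm(2000))  # appended pure-noise column
  bs <- bootstrap_stability(X, pl$Y, n_boot = 300, seed = 9)
  expect_true(all(abs(bs$bsr[1:3, 1]) > 1.96))
  expect_lt(abs(bs$bsr[4, 1]), 1.96)
  # planted clinical CIs exclude zero on LV1
  expect_true(all(bs$v_ci_lo[, 1] > 0 | bs$v_ci_hi[, 1] < 0))
  expect_error(bootstrap_stability(X, pl$Y, n_boot = 0), "positive")
})

test_that("null clinical variable's bootstrap CI covers zero", {
  covered <- sapply(1:10, function(i) {
    pl <- planted_rank1(n = 500, p = 3, q = 5, noise = 0.3, seed = 100 + i)
    set.seed(200 + i)
    Y <- cbind(pl$Y, null_var = rnorm(500))
    bs <- bootstrap_stability(pl$X, Y, n_boot = 200, seed = 300 + i)
    bs$v_ci_lo[6, 1] <= 0 && bs$v_ci_hi[6, 1] >= 0
  })
  expect_gte(mean(covered), 0.9)
})

test_that("score correlation is a rank statistic", {
  pl <- planted_rank1(n = 400, seed = 69)
  fit <- fit_pls(pl$X, pl$Y)
  r <- score_correlation(fit, 1)
  # invariant under strictly monotone transforms of either score vector
  m2 <- fit
  m2$imaging_scores[, 1] <- exp(m2$imaging_scores[, 1] / 2)
  expect_equal(score_correlation(m2, 1), r)
  expect_error(score_correlation(fit, 99), "out of range")
})

test_that("cross-validated score correlation is seeded and calibrated", {
  pl <- planted_rank1(n = 600, noise = 0.1, seed = 70)
  cv1 <- crossval_score_correlation(pl$X, pl$Y, k = 10, seed = 11)
  cv2 <- crossval_score_correlation(pl$X, pl$Y, k = 10, seed = 11)
  expect_identical(cv1, cv2)
  expect_gt(cv1$mean_correlation, 0.9)  # near-deterministic coupling
  # null data: mean out-of-fold correlation over the rep suite near zero
  rs <- sapply(1:5, function(i) {
    np <- make_null_pair(2000, 3, 8, seed = 500 + i)
    crossval_score_correlation(np$X, np$Y, k = 10,
                               seed = i)$mean_correlation
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(crossval_score_correlation(pl$X, pl$Y, k = 1), ">= 2")
  expect_error(crossval_score_correlation(pl$X[1:50, ], pl$Y[1:50, ],
                                          k = 10), "n >= 10")
})

test_that("per-marker regressions recover standardized effects", {
  set.seed(72)
  n <- 10000
  conf <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  marker <- rnorm(n)
  out <- 0.3 * marker + rnorm(n, 0, sqrt(1 - 0.09))
  tab <- per_marker_regressions(cbind(m1 = marker),
                                cbind(y1 = out, y_null = rnorm(n)), conf)
  b <- tab$beta[tab$outcome == "y1"]
  expect_lt(abs(b - 0.30), 0.02)
  expect_lt(tab$p_fdr[tab$outcome == "y1"], 0.001)
  expect_gt(tab$p_fdr[tab$outcome == "y_null"], 0.05)
  # a variable regressed on itself has beta 1
  self <- per_marker_regressions(cbind(m = marker), cbind(y = marker), conf)
  expect_equal(self$beta, 1, tolerance = 1e-10)
})
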