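#' @title Partial least squares correlation (PLS-C)
#'
#' @description Singular value decomposition of the cross-covariance between
#'   an imaging block and a clinical block of column-standardized variables,
#'   yielding paired latent variables that maximize covariance between block
#'   projections.  Inference: permutation testing of singular values
#'   (shuffling subject labels of the imaging block only), bootstrap
#'   stability of loadings (bootstrap ratios for imaging variables,
#'   percentile confidence intervals for clinical variables), subject-level
#'   scores, and a cross-validated out-of-fold score correlation.
#' @name pls_correlation
NULL

#' Fit a PLS correlation model
#'
#' Columns of both blocks are centered and scaled to unit variance (so
#' cross-covariance and cross-correlation coincide and loadings are
#' comparable across native scales), then the `p x q` cross-covariance
#' `R = X'Y / (n - 1)` is decomposed by SVD into `L = min(p, q)` latent
#' variables.  Subject scores are the projections `X U` and `Y V`.
#'
#' @param X imaging block, `n x p` (typically confound residuals).
#' @param Y clinical block, `n x q` (clinical residuals, optionally with
#'   appended covariate check columns).
#' @param sign_anchor column (index or name) of `X` whose loading is
#'   oriented positive on every component — with relative brain age as the
#'   anchor, positive imaging loadings read as "more brain aging" and
#'   negative clinical loadings as "worse performance".
#' @return a `pls_model`: `u` (p x L), `v` (q x L), `singular_values`,
#'   `covariance_explained`, `imaging_scores`, `clinical_scores`, centering
#'   and scaling vectors for out-of-sample projection.
#' @export
fit_pls <- function(X, Y, sign_anchor = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  if (n <= max(ncol(X), ncol(Y))) stop("need n > max(p, q)")
  Xz <- zscore(X); Yz <- zscore(Y)
  R <- crossprod(Xz, Yz) / (n - 1)
  L <- min(ncol(X), ncol(Y))
  sv <- svd(R, nu = L, nv = L)
  u <- sv$u; v <- sv$v; d <- sv$d[seq_len(L)]
  if (is.character(sign_anchor)) sign_anchor <- match(sign_anchor, colnames(X))
  flip <- ifelse(u[sign_anchor, ] < 0, -1, 1)
  u <- sweep(u, 2, flip, `*`); v <- sweep(v, 2, flip, `*`)
  dimnames(u) <- list(colnames(X), paste0("LV", seq_len(L)))
  dimnames(v) <- list(colnames(Y), paste0("LV", seq_len(L)))
  structure(list(
    u = u, v = v,
    singular_values = d,
    covariance_explained = d^2 / sum(sv$d^2),
    imaging_scores = Xz %*% u,
    clinical_scores = Yz %*% v,
    x_center = attr(Xz, "scaled:center"), x_scale = attr(Xz, "scaled:scale"),
    y_center = attr(Yz, "scaled:center"), y_scale = attr(Yz, "scaled:scale"),
    n = n, sign_anchor = sign_anchor
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> n = %d, p = %d, q = %d\n",
              x$n, nrow(x$u), nrow(x$v)))
  ce <- round(100 * x$covariance_explained, 1)
  cat("  covariance explained (%):", paste(ce, collapse = ", "), "\n")
  invisible(x)
}

# cross-block correlation SVD for resampling loops (no bookkeeping)
svd_crosscor <- function(X, Y, L) {
  R <- crossprod(zscore(X), zscore(Y)) / (nrow(X) - 1)
  svd(R, nu = L, nv = L)
}

#' Permutation test of latent-variable significance
#'
#' Each permutation row-shuffles the imaging block only (breaking the
#' subject correspondence), refits the SVD and records singular values.
#' Raw per-LV p-values use the add-one estimator
#' `p = (1 + #\{s_perm >= s_emp\}) / (1 + n_perm)` and are FDR-adjusted
#' across latent variables.
#'
#' @param X,Y as in [fit_pls()].
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @param rotate if `TRUE`, align each permuted solution to the empirical
#'   one by an orthogonal Procrustes rotation before reading off singular
#'   values; default compares same-index singular values directly.
#' @return a `pls_permutation` data.frame: one row per LV with
#'   `singular_value`, `perm_mean`, `perm_q95`, `p`, `p_fdr`; attribute
#'   `n_perm`.
#' @export
permutation_test <- function(X, Y, n_perm = 5000, seed = NULL,
                             rotate = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_perm < 1) stop("n_perm must be positive")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-value resolution")
  L <- min(ncol(X), ncol(Y))
  # row shuffles leave column means/SDs untouched, so standardize once
  Xz <- zscore(X); Yz <- zscore(Y)
  n1 <- nrow(X) - 1
  emp <- svd(crossprod(Xz, Yz) / n1, nu = L, nv = L)
  d_emp <- emp$d[seq_len(L)]
  perm_d <- matrix(NA_real_, n_perm, L)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Xp <- Xz[sample.int(nrow(X)), , drop = FALSE]
      sv <- svd(crossprod(Xp, Yz) / n1, nu = L, nv = L)
      perm_d[b, ] <- if (rotate)
        rotated_singvals(emp$u[, seq_len(L), drop = FALSE], sv, L)
      else sv$d[seq_len(L)]
    }
  })
  exceed <- colSums(sweep(perm_d, 2, d_emp, `>=`))
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    lv = seq_len(L),
    singular_value = d_emp,
    perm_mean = colMeans(perm_d),
    perm_q95 = apply(perm_d, 2, stats::quantile, 0.95),
    p = p,
    p_fdr = fdr_bh(p)
  )
  attr(out, "n_perm") <- n_perm
  class(out) <- c("pls_permutation", "data.frame")
  out
}

# Procrustes-aligned singular values: rotate the permuted singular structure
# onto the empirical imaging loadings, read component norms
rotated_singvals <- function(U_emp, sv, L) {
  Up <- sv$u[, seq_len(L), drop = FALSE]
  dp <- sv$d[seq_len(L)]
  m <- svd(crossprod(U_emp, Up))
  Q <- m$u %*% t(m$v)
  S <- Up %*% diag(dp, L) %*% t(Q)
  sqrt(colSums(S^2))
}

#' Bootstrap stability of PLS loadings
#'
#' Resamples subjects with replacement (paired rows of both blocks), refits
#' the SVD, aligns each bootstrap solution to the original by a
#' per-component sign flip (or full Procrustes), and summarizes: bootstrap
#' ratio (original loading / bootstrap SE) for imaging variables, percentile
#' 95% confidence intervals for clinical loadings.  `|BSR| > 1.96` and
#' `0 notin CI` are the conventional stability flags.
#'
#' @param X,Y as in [fit_pls()].
#' @param n_boot bootstrap replicates (default 5000); 0 is an error.
#' @param seed RNG seed.
#' @param align `"sign"` (per-component dot-product sign flip, default) or
#'   `"procrustes"` (orthogonal rotation of the whole loading basis).
#' @param sign_anchor passed to the internal [fit_pls()].
#' @return a `pls_bootstrap` list: `bsr` (p x L), `v_ci_lo`/`v_ci_hi`
#'   (q x L), `u_se`, `n_boot`, `n_redrawn` (replicates redrawn because a
#'   resampled column was constant).
#' @export
bootstrap_stability <- function(X, Y, n_boot = 5000, seed = NULL,
                                align = c("sign", "procrustes"),
                                sign_anchor = 1L) {
  align <- match.arg(align)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_boot < 1) stop("n_boot must be positive")
  model <- fit_pls(X, Y, sign_anchor = sign_anchor)
  L <- length(model$singular_values)
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  u_b <- array(NA_real_, c(p, L, n_boot))
  v_b <- array(NA_real_, c(q, L, n_boot))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        ok <- all(apply(Xb, 2, stats::sd) > 0) &&
              all(apply(Yb, 2, stats::sd) > 0)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
      }
      sv <- svd_crosscor(Xb, Yb, L)
      Ub <- sv$u[, seq_len(L), drop = FALSE]
      Vb <- sv$v[, seq_len(L), drop = FALSE]
      if (align == "procrustes") {
        m <- svd(crossprod(model$u, Ub) + crossprod(model$v, Vb))
        Q <- m$u %*% t(m$v)
        Ub <- Ub %*% t(Q); Vb <- Vb %*% t(Q)
      } else {
        s <- sign(colSums(model$u * Ub) + colSums(model$v * Vb))
        s[s == 0] <- 1
        Ub <- sweep(Ub, 2, s, `*`); Vb <- sweep(Vb, 2, s, `*`)
      }
      u_b[, , b] <- Ub; v_b[, , b] <- Vb
    }
  })
  u_se <- apply(u_b, c(1, 2), stats::sd)
  bsr <- model$u / u_se
  v_ci <- apply(v_b, c(1, 2), stats::quantile, probs = c(0.025, 0.975))
  v_ci_lo <- v_ci[1, , , drop = TRUE]
  v_ci_hi <- v_ci[2, , , drop = TRUE]
  dim(v_ci_lo) <- dim(v_ci_hi) <- c(q, L)
  dimnames(bsr) <- dimnames(model$u)
  dimnames(v_ci_lo) <- dimnames(v_ci_hi) <- dimnames(model$v)
  structure(list(bsr = bsr, u_se = u_se,
                 v_ci_lo = v_ci_lo, v_ci_hi = v_ci_hi,
                 model = model, n_boot = n_boot, n_redrawn = n_redrawn),
            class = "pls_bootstrap")
}

#' Subject-score correlation for one latent variable
#'
#' Rank (Spearman) correlation — by default — between the imaging and
#' clinical subject scores of one latent variable.
#'
#' @param model a fitted `pls_model`.
#' @param lv latent-variable index.
#' @param method correlation method (default `"spearman"`).
#' @return scalar correlation.
#' @export
score_correlation <- function(model, lv = 1L, method = "spearman") {
  stopifnot(inherits(model, "pls_model"))
  if (lv < 1 || lv > length(model$singular_values))
    stop("lv out of range")
  stats::cor(model$imaging_scores[, lv], model$clinical_scores[, lv],
             method = method)
}

#' Cross-validated out-of-fold score correlation
#'
#' Seeded k-fold partition; for each fold the PLS is fit on the training
#' rows (training centering/scaling), held-out rows are projected with the
#' training loadings (sign-aligned to the full-sample fit), and the LV
#' Spearman correlation of the held-out scores is computed.  Reports the
#' fold mean.
#'
#' @param X,Y as in [fit_pls()].
#' @param k folds (default 10); requires `n >= 10 * k`.
#' @param seed RNG seed for the partition.
#' @param lv latent-variable index (default 1).
#' @return list: `mean_correlation`, `fold_correlations`.
#' @export
crossval_score_correlation <- function(X, Y, k = 10, seed = NULL, lv = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (k < 2) stop("k must be >= 2")
  n <- nrow(X)
  if (n < 10 * k) stop("need n >= 10 * k")
  full <- fit_pls(X, Y)
  rs <- numeric(k)
  with_seed(seed, {
    folds <- sample(rep(seq_len(k), length.out = n))
    for (f in seq_len(k)) {
      tr <- folds != f; te <- !tr
      m <- fit_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
      s <- sign(colSums(full$u * m$u) + colSums(full$v * m$v))
      s[s == 0] <- 1
      xs <- scale(X[te, , drop = FALSE], m$x_center, m$x_scale) %*%
        (m$u * rep(s, each = nrow(m$u)))
      ys <- scale(Y[te, , drop = FALSE], m$y_center, m$y_scale) %*%
        (m$v * rep(s, each = nrow(m$v)))
      rs[f] <- stats::cor(xs[, lv], ys[, lv], method = "spearman")
    }
  })
  list(mean_correlation = mean(rs), fold_correlations = rs)
}

#' Per-marker linear regressions (comparability analysis)
#'
#' One OLS per (marker, outcome) pair with covariate adjustment; marker and
#' outcome are z-scored so the marker coefficient is a standardized beta.
#' P-values are FDR-adjusted across the full grid.
#'
#' @param markers numeric matrix/data.frame of imaging markers.
#' @param clinical numeric matrix/data.frame of outcomes.
#' @param covariates numeric matrix of adjustment covariates (age, sex,
#'   education), no intercept column.
#' @return data.frame: `marker`, `outcome`, `beta`, `se`, `p`, `p_fdr`.
#' @export
per_marker_regressions <- function(markers, clinical, covariates) {
  markers <- as.matrix(markers); clinical <- as.matrix(clinical)
  covariates <- as.matrix(covariates)
  mk <- zscore(markers); cl <- zscore(clinical)
  rows <- list(); i <- 0L
  for (mj in seq_len(ncol(mk))) for (cj in seq_len(ncol(cl))) {
    X <- cbind(1, mk[, mj], covariates)
    fit <- stats::lm.fit(X, cl[, cj])
    rss <- sum(fit$residuals^2)
    dfree <- nrow(X) - ncol(X)
    XtX_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / dfree * XtX_inv[2, 2])
    beta <- fit$coefficients[2]
    i <- i + 1L
    rows[[i]] <- data.frame(
      marker = colnames(mk)[mj] %||% paste0("m", mj),
      outcome = colnames(cl)[cj] %||% paste0("y", cj),
      beta = beta, se = se,
      p = 2 * stats::pt(abs(beta / se), dfree, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
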