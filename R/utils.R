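# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so seeded package functions never disturb the
#' user's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic counter scheme: each named pipeline stage gets its own
#' 31-bit seed so stages are independently reproducible and changing one
#' stage's settings never perturbs another stage's randomness.
#'
#' @param master integer master seed.
#' @param stage stage name (character).
#' @return integer seed in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(master, stage) {
  stages <- c(simulate = 1L, folds = 2L, permutation = 3L, bootstrap = 4L,
              crossval = 5L, mediation = 6L, gap = 7L)
  idx <- stages[[match.arg(stage, names(stages))]]
  # multiplicative hash folded into 31 bits; offsets keep streams apart
  h <- (as.double(master) * 48271 + idx * 1664525) %% (2^31 - 2)
  as.integer(h) + 1L
}

# column-wise z-score; constant columns raise unless allow_constant
zscore <- function(x, allow_constant = FALSE) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- sdv == 0 | !is.finite(sdv)
  if (any(bad) && !allow_constant)
    stop("constant column(s): ", paste(colnames(x)[bad], collapse = ", "))
  sdv[bad] <- 1
  scale(x, center = mu, scale = sdv)
}

# defensive scalar checks used by several entry points
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper))
  invisible(x)
}
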