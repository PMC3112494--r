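# Internal numerical helpers.

# Symmetry tolerance is relative to the largest matrix entry.
.check_symmetric <- function(M, tol = 1e-6, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > tol * scale)
    stop(sprintf("%s is not symmetric (relative tolerance %g)", what, tol),
         call. = FALSE)
  (M + t(M)) / 2
}

# Log-determinant of a symmetric positive-definite matrix via Cholesky.
.logdet_pd <- function(M) {
  if (length(M) == 0L) return(0)
  2 * sum(log(diag(chol(M))))
}

# Smallest/largest eigenvalue check: eigenvalues below -tol * lambda_max
# violate positive semi-definiteness.
.check_psd <- function(M, tol = 1e-8, what = "matrix") {
  if (length(M) == 0L) return(invisible(M))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(abs(ev), 1e-300)
  if (min(ev) < -tol * lmax)
    stop(sprintf("%s has a negative eigenvalue (%g) beyond tolerance", what,
                 min(ev)), call. = FALSE)
  invisible(M)
}

# Multivariate normal log-density with covariance S (must be PD).
.ldmvnorm <- function(x, mean, S) {
  d <- length(mean)
  if (d == 0L) return(0)
  R <- tryCatch(chol(S), error = function(e)
    stop("degenerate marginal covariance", call. = FALSE))
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Deterministic small-integer seed derived from a base seed and a tag,
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(seed) %% 2147480 + 1) * 1000 + h %% 1000)
}

# Evaluate fn with a locally seeded RNG, restoring global RNG state.
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
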