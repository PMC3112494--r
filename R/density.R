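#' Multivariate Gaussian density with explicit point-mass directions
#'
#' Container for the Gaussian priors and posteriors used throughout the
#' package. A density is specified by a mean vector and either a precision or
#' a covariance matrix. Coordinates whose variance is exactly (numerically)
#' zero are flagged as *fixed*: they carry a point mass at their mean, which
#' is how parameters are removed from a model by infinitely precise shrinkage
#' priors. The precision is stored for the free (non-fixed) block only.
#'
#' @param mean numeric vector of length d.
#' @param precision optional d x d symmetric positive-definite precision
#'   matrix (inverse covariance). Supply exactly one of `precision` and
#'   `covariance`.
#' @param covariance optional d x d symmetric positive-semidefinite covariance
#'   matrix. Zero-variance coordinates (diagonal below `tol` times the largest
#'   diagonal entry) are flagged as fixed; their off-diagonal entries must be
#'   (numerically) zero.
#' @param labels optional character vector of parameter names; used as join
#'   keys when matching a reduced prior to a full model.
#' @param tol relative tolerance for symmetry / positive-semidefiniteness
#'   checks and for detecting zero-variance coordinates.
#'
#' @return An object of class `bmr_density` with elements `mean`, `cov`,
#'   `prec` (free-block precision embedded in a d x d matrix, zero rows and
#'   columns on fixed coordinates), `fixed` (logical), `labels`.
#'
#' @examples
#' gaussian_density(c(0, 0), covariance = diag(c(4, 1)))
#' # point mass on the second coordinate:
#' gaussian_density(c(0, 3), covariance = diag(c(4, 0)))
#' @export
gaussian_density <- function(mean, precision = NULL, covariance = NULL,
                             labels = NULL, tol = 1e-8) {
  mean <- as.numeric(mean)
  d <- length(mean)
  if (is.null(precision) == is.null(covariance))
    stop("supply exactly one of `precision` and `covariance`", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != d)
      stop("labels length must equal the dimension", call. = FALSE)
  }
  if (!is.null(precision)) {
    P <- .check_symmetric(as.matrix(precision), what = "precision")
    if (nrow(P) != d) stop("mean and precision dimensions differ", call. = FALSE)
    .check_psd(P, tol = tol, what = "precision")
    R <- tryCatch(chol(P), error = function(e)
      stop("precision is singular; supply a covariance with explicit ",
           "zero-variance coordinates instead", call. = FALSE))
    S <- chol2inv(R)
    fixed <- rep(FALSE, d)
  } else {
    S <- .check_symmetric(as.matrix(covariance), what = "covariance")
    if (nrow(S) != d) stop("mean and covariance dimensions differ", call. = FALSE)
    .check_psd(S, tol = tol, what = "covariance")
    dS <- diag(S)
    if (d > 0L) diag(S) <- pmax(dS, 0)
    fixed <- if (d > 0L) diag(S) <= tol * max(diag(S), 1e-300) else logical(0)
    if (any(fixed)) {
      off <- S[fixed, !fixed, drop = FALSE]
      if (length(off) && max(abs(off)) > sqrt(tol) * max(abs(S), 1e-300))
        stop("zero-variance coordinates must be uncorrelated with the rest",
             call. = FALSE)
      S[fixed, ] <- 0
      S[, fixed] <- 0
    }
    P <- matrix(0, d, d)
    if (any(!fixed)) {
      Rf <- tryCatch(chol(S[!fixed, !fixed, drop = FALSE]), error = function(e)
        stop("covariance is singular in a non-coordinate direction; ",
             "only coordinate-aligned point masses are supported", call. = FALSE))
      P[!fixed, !fixed] <- chol2inv(Rf)
    }
  }
  structure(list(mean = mean, cov = S, prec = (P + t(P)) / 2, fixed = fixed,
                 labels = labels),
            class = "bmr_density")
}

#' @export
dim.bmr_density <- function(x) length(x$mean)

#' @export
print.bmr_density <- function(x, ...) {
  d <- length(x$mean)
  cat(sprintf("Gaussian density, dimension %d (%d fixed)\n", d, sum(x$fixed)))
  v <- diag(x$cov)
  tab <- data.frame(mean = x$mean, variance = v, fixed = x$fixed)
  rownames(tab) <- if (!is.null(x$labels)) x$labels else seq_len(d)
  print(utils::head(tab, 12L))
  if (d > 12L) cat(sprintf("... (%d more)\n", d - 12L))
  invisible(x)
}

#' Marginal of a Gaussian density on selected coordinates
#'
#' @param x a `bmr_density`.
#' @param idx integer indices of coordinates to keep.
#' @return a `bmr_density` over `idx`.
#' @export
density_marginal <- function(x, idx) {
  stopifnot(inherits(x, "bmr_density"))
  idx <- as.integer(idx)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > length(x$mean)))
    stop("invalid marginal indices", call. = FALSE)
  gaussian_density(x$mean[idx], covariance = x$cov[idx, idx, drop = FALSE],
                   labels = if (!is.null(x$labels)) x$labels[idx])
}

#' Conditional of a Gaussian density given fixed coordinate values
#'
#' Conditions `x` on `x[idx] = values` and returns the Gaussian over the
#' remaining coordinates. All conditioned coordinates must be free (non-fixed).
#'
#' @param x a `bmr_density`.
#' @param idx integer indices of coordinates to condition on.
#' @param values numeric values for those coordinates.
#' @return a `bmr_density` over the remaining coordinates.
#' @export
density_conditional <- function(x, idx, values) {
  stopifnot(inherits(x, "bmr_density"))
  idx <- as.integer(idx)
  d <- length(x$mean)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > d))
    stop("invalid conditioning indices", call. = FALSE)
  if (length(values) != length(idx))
    stop("values length must match indices", call. = FALSE)
  if (any(x$fixed[idx]))
    stop("cannot condition on a fixed coordinate", call. = FALSE)
  r <- setdiff(seq_len(d), idx)
  if (!length(r))
    return(gaussian_density(numeric(0), covariance = matrix(0, 0, 0)))
  if (any(x$fixed[r])) {
    # fixed remainder coordinates are untouched by conditioning
    free_r <- r[!x$fixed[r]]
    Prr <- x$prec[free_r, free_r, drop = FALSE]
    Prc <- x$prec[free_r, idx, drop = FALSE]
    mu_r <- x$mean[r]
    if (length(free_r)) {
      shift <- solve(Prr, Prc %*% (values - x$mean[idx]))
      mu_r[match(free_r, r)] <- x$mean[free_r] - as.numeric(shift)
    }
    S <- matrix(0, length(r), length(r))
    if (length(free_r)) {
      pos <- match(free_r, r)
      S[pos, pos] <- chol2inv(chol(Prr))
    }
    return(gaussian_density(mu_r, covariance = S,
                            labels = if (!is.null(x$labels)) x$labels[r]))
  }
  # conditioning in precision form: the free-block precision is the sub-block
  Prr <- x$prec[r, r, drop = FALSE]
  Prc <- x$prec[r, idx, drop = FALSE]
  mu <- x$mean[r] - as.numeric(solve(Prr, Prc %*% (values - x$mean[idx])))
  gaussian_density(mu, precision = Prr,
                   labels = if (!is.null(x$labels)) x$labels[r])
}

#' Log-density of a Gaussian at a point
#'
#' Evaluated on the free block; returns `-Inf` if a fixed coordinate of `x`
#' disagrees with the corresponding entry of `at`.
#'
#' @param x a `bmr_density`.
#' @param at numeric vector, same dimension as `x`.
#' @return scalar log-density (nats).
#' @export
density_logpdf <- function(x, at) {
  stopifnot(inherits(x, "bmr_density"))
  at <- as.numeric(at)
  if (length(at) != length(x$mean))
    stop("point dimension mismatch", call. = FALSE)
  if (any(x$fixed) && any(abs(at[x$fixed] - x$mean[x$fixed]) > 1e-12))
    return(-Inf)
  f <- !x$fixed
  if (!any(f)) return(0)
  .ldmvnorm(at[f], x$mean[f], x$cov[f, f, drop = FALSE])
}
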