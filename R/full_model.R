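#' Full-model inversion: prior, posterior and free energy
#'
#' Bundles the sufficient statistics of an inverted ("full") model: the
#' Gaussian prior, the Gaussian (Laplace-approximate) posterior and the scalar
#' free-energy bound on its log-evidence. These three quantities are all that
#' is needed to score any reduced model analytically.
#'
#' @param prior a [gaussian_density()] for the prior.
#' @param posterior a [gaussian_density()] for the posterior; must have the
#'   same dimension and label order as the prior, and a positive-definite
#'   precision on its free block.
#' @param free_energy scalar free energy of the full model (nats). Defaults to
#'   0 when unknown; model comparisons then rest on free-energy differences
#'   only, which are unaffected.
#' @param meta free-form provenance list.
#'
#' @return An object of class `bmr_full_model`.
#' @examples
#' pr <- gaussian_density(0, covariance = matrix(4))
#' po <- gaussian_density(1, covariance = matrix(0.25))
#' full_model(pr, po)
#' @export
full_model <- function(prior, posterior, free_energy = 0, meta = list()) {
  stopifnot(inherits(prior, "bmr_density"), inherits(posterior, "bmr_density"))
  if (length(prior$mean) != length(posterior$mean))
    stop("prior and posterior dimensions differ", call. = FALSE)
  if (!identical(prior$labels, posterior$labels))
    stop("prior and posterior labels differ", call. = FALSE)
  if (!is.numeric(free_energy) || length(free_energy) != 1 ||
      !is.finite(free_energy))
    stop("free_energy must be a finite scalar", call. = FALSE)
  f <- !posterior$fixed
  if (any(f)) {
    ok <- tryCatch({chol(posterior$prec[f, f, drop = FALSE]); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("posterior precision is not positive definite", call. = FALSE)
  }
  structure(list(prior = prior, posterior = posterior,
                 free_energy = as.numeric(free_energy), meta = meta),
            class = "bmr_full_model")
}

#' @export
dim.bmr_full_model <- function(x) length(x$prior$mean)

#' @export
print.bmr_full_model <- function(x, ...) {
  cat(sprintf("Full model: %d parameters, free energy %.4f nats\n",
              length(x$prior$mean), x$free_energy))
  tab <- data.frame(prior_mean = x$prior$mean,
                    prior_var = diag(x$prior$cov),
                    post_mean = x$posterior$mean,
                    post_var = diag(x$posterior$cov))
  rownames(tab) <- if (!is.null(x$prior$labels)) x$prior$labels
                   else seq_along(x$prior$mean)
  print(utils::head(tab, 12L))
  if (nrow(tab) > 12L) cat(sprintf("... (%d more)\n", nrow(tab) - 12L))
  invisible(x)
}

# internal constructor for reduction results
.reduced_result <- function(free_energy, delta_f, posterior, reduced_prior,
                            clamped_indices = integer(0),
                            clamped_values = numeric(0)) {
  structure(list(free_energy = free_energy, delta_f = delta_f,
                 posterior = posterior, reduced_prior = reduced_prior,
                 clamped_indices = clamped_indices,
                 clamped_values = clamped_values),
            class = "bmr_reduced")
}

#' @export
print.bmr_reduced <- function(x, ...) {
  cat(sprintf("Reduced model: F = %.4f nats (delta F = %.4f)\n",
              x$free_energy, x$delta_f))
  if (length(x$clamped_indices))
    cat("clamped:", paste(sprintf("[%d]=%g", x$clamped_indices,
                                  x$clamped_values), collapse = ", "), "\n")
  invisible(x)
}
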