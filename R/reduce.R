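#' Evidence and posterior of a reduced model from a full inversion
#'
#' Computes, in closed form, the free energy (log-evidence bound) and Gaussian
#' posterior of any *reduced* model -- one that shares the full model's
#' likelihood but carries a different Gaussian prior -- from the prior,
#' posterior and free energy of a single full-model inversion. Writing
#' \eqn{(\eta_F,\Pi_F)} and \eqn{(\mu_F,P_F)} for the full prior and posterior
#' means and precisions and \eqn{(\eta_i,\Pi_i)} for the reduced prior, the
#' reduced posterior precision is \eqn{P_i = P_F + \Pi_i - \Pi_F}, its mean is
#' \eqn{\mu_i = P_i^{-1}(P_F\mu_F + \Pi_i\eta_i - \Pi_F\eta_F)}, and
#' \deqn{F_i = F_F + \tfrac12\ln\frac{|\Pi_i||P_F|}{|P_i||\Pi_F|}
#'   - \tfrac12(\mu_F^T P_F\mu_F + \eta_i^T\Pi_i\eta_i
#'              - \eta_F^T\Pi_F\eta_F - \mu_i^T P_i\mu_i).}
#'
#' Reduced-prior coordinates with zero variance (point masses) are handled
#' exactly by block partitioning: the point-mass block contributes a
#' Savage-Dickey density-ratio term (posterior over prior marginal log-density
#' at the clamped values) and the remaining block is reduced after
#' conditioning both full densities on the clamped values. A removed
#' parameter therefore contributes no determinant terms, avoiding the
#' cancellation that a large-but-finite precision would cause.
#'
#' @param full a [full_model()].
#' @param reduced_prior a [gaussian_density()] with the same dimension and
#'   label order as `full$prior`. Coordinates fixed in the full prior must be
#'   fixed at the same value in the reduced prior (prior support containment).
#' @param tol positive-definiteness tolerance for the reduced posterior
#'   precision.
#'
#' @return An object of class `bmr_reduced` with elements `free_energy`
#'   (\eqn{F_i}), `delta_f` (\eqn{F_i - F_F}), `posterior`, `reduced_prior`,
#'   `clamped_indices` and `clamped_values`. Clamped coordinates of the
#'   returned posterior have mean equal to the clamp value and zero variance.
#'
#' @seealso [clamp_parameters()] for pure point-mass (Savage-Dickey)
#'   reductions, [model_posterior()] to turn free energies into model
#'   probabilities.
#' @examples
#' pr <- gaussian_density(0, covariance = matrix(4))
#' po <- gaussian_density(1, covariance = matrix(0.25))
#' fm <- full_model(pr, po)
#' reduce_model(fm, gaussian_density(0, covariance = matrix(1)))
#' @export
reduce_model <- function(full, reduced_prior, tol = 1e-8) {
  stopifnot(inherits(full, "bmr_full_model"),
            inherits(reduced_prior, "bmr_density"))
  d <- length(full$prior$mean)
  if (length(reduced_prior$mean) != d)
    stop("dimension mismatch between full model and reduced prior",
         call. = FALSE)
  if (!is.null(full$prior$labels) && !is.null(reduced_prior$labels) &&
      !identical(full$prior$labels, reduced_prior$labels))
    stop("label mismatch between full model and reduced prior; ",
         "labels are join keys and are never reordered silently",
         call. = FALSE)

  fixF <- full$prior$fixed
  fixR <- reduced_prior$fixed
  # support containment: zero full-prior variance forces zero reduced-prior
  # variance at the same mean
  bad <- fixF & (!fixR | abs(reduced_prior$mean - full$prior$mean) > 1e-10)
  if (any(bad))
    stop(sprintf(paste0("support violation: coordinate(s) %s have zero ",
                        "variance under the full prior but differ under ",
                        "the reduced prior"),
                 paste(which(bad), collapse = ",")), call. = FALSE)

  excl <- fixF & fixR              # fixed in both: shared known parameters
  clamp <- fixR & !fixF            # newly clamped by the reduced prior
  free <- !fixR                    # free under the reduced prior

  cidx <- which(clamp)
  v <- reduced_prior$mean[cidx]

  out <- .reduce_partitioned(
    mu = full$posterior$mean, P = full$posterior$prec,
    Cpost = full$posterior$cov,
    etaF = full$prior$mean, PiF = full$prior$prec, Sprior = full$prior$cov,
    etaR = reduced_prior$mean, PiR = reduced_prior$prec,
    excl = which(excl), cidx = cidx, v = v, fidx = which(free & !excl),
    tol = tol)

  post_mean <- full$posterior$mean
  post_cov <- matrix(0, d, d)
  fidx <- which(free & !excl)
  if (length(fidx)) {
    post_mean[fidx] <- out$mu_i
    post_cov[fidx, fidx] <- out$C_i
  }
  post_mean[cidx] <- v
  posterior <- gaussian_density(post_mean, covariance = post_cov,
                                labels = full$posterior$labels)
  F_i <- full$free_energy + out$delta_f
  .reduced_result(F_i, out$delta_f, posterior, reduced_prior,
                  clamped_indices = cidx, clamped_values = v)
}

# Core partitioned computation shared by reduce_model and the fast search
# path. Returns delta_f plus the free-block posterior mean/covariance.
.reduce_partitioned <- function(mu, P, Cpost, etaF, PiF, Sprior,
                                etaR, PiR, excl, cidx, v, fidx, tol) {
  delta_sd <- 0
  if (length(cidx)) {
    # Savage-Dickey term: posterior vs prior marginal log-density at v
    Ccc <- Cpost[cidx, cidx, drop = FALSE]
    Scc <- Sprior[cidx, cidx, drop = FALSE]
    lq <- .ldmvnorm(v, mu[cidx], Ccc)
    lp <- .ldmvnorm(v, etaF[cidx], Scc)
    delta_sd <- lq - lp
  }
  if (!length(fidx)) {
    return(list(delta_f = delta_sd, mu_i = numeric(0),
                C_i = matrix(0, 0, 0)))
  }
  # condition posterior and full prior on the clamped block (precision form:
  # the free-block precision is the plain sub-block)
  Prr <- P[fidx, fidx, drop = FALSE]
  mu_r <- mu[fidx]
  if (length(cidx)) {
    mu_r <- mu_r - as.numeric(solve(Prr, P[fidx, cidx, drop = FALSE] %*%
                                      (v - mu[cidx])))
  }
  PiF_rr <- PiF[fidx, fidx, drop = FALSE]
  etaF_r <- etaF[fidx]
  if (length(cidx)) {
    etaF_r <- etaF_r - as.numeric(solve(PiF_rr,
                                        PiF[fidx, cidx, drop = FALSE] %*%
                                          (v - etaF[cidx])))
  }
  PiR_rr <- PiR[fidx, fidx, drop = FALSE]
  etaR_r <- etaR[fidx]

  P_i <- Prr + PiR_rr - PiF_rr
  P_i <- (P_i + t(P_i)) / 2
  Ri <- tryCatch(chol(P_i), error = function(e) NULL)
  if (is.null(Ri) || any(diag(Ri)^2 <= tol * max(diag(Ri)^2))) {
    ev <- eigen(P_i, symmetric = TRUE)
    k <- which.min(ev$values)
    dir <- which.max(abs(ev$vectors[, k]))
    stop(sprintf(paste0("invalid reduction: reduced posterior precision is ",
                        "not positive definite (eigenvalue %g, dominant ",
                        "coordinate %d)"), min(ev$values), fidx[dir]),
         call. = FALSE)
  }
  rhs <- Prr %*% mu_r + PiR_rr %*% etaR_r - PiF_rr %*% etaF_r
  mu_i <- backsolve(Ri, backsolve(Ri, rhs, transpose = TRUE))
  mu_i <- as.numeric(mu_i)
  # determinants of each matrix separately, never of products
  Fterm <- 0.5 * (.logdet_pd(PiR_rr) + .logdet_pd(Prr) -
                    2 * sum(log(diag(Ri))) - .logdet_pd(PiF_rr)) -
    0.5 * (sum(mu_r * (Prr %*% mu_r)) + sum(etaR_r * (PiR_rr %*% etaR_r)) -
             sum(etaF_r * (PiF_rr %*% etaF_r)) - sum(mu_i * (P_i %*% mu_i)))
  list(delta_f = delta_sd + Fterm, mu_i = mu_i,
       C_i = chol2inv(Ri))
}

#' Savage-Dickey point-mass reduction (parameter clamping)
#'
#' Fixes a subset of parameters at given values -- the limit of shrinking
#' their prior variance to zero. The log-Bayes factor in favour of the
#' clamped model is the Savage-Dickey density ratio: the full posterior
#' marginal log-density at the clamp values minus the full prior marginal
#' log-density there. The reduced posterior over the remaining parameters is
#' the full-posterior conditional given the clamped values.
#'
#' @param full a [full_model()].
#' @param indices integer indices of the parameters to clamp.
#' @param values numeric clamp values (default all zero).
#'
#' @return A `bmr_reduced` object; see [reduce_model()].
#' @examples
#' pr <- gaussian_density(c(0, 0), covariance = diag(c(4, 4)))
#' po <- gaussian_density(c(1, 2), covariance = diag(c(0.5, 0.5)))
#' clamp_parameters(full_model(pr, po), 2, 0)
#' @export
clamp_parameters <- function(full, indices, values = rep(0, length(indices))) {
  stopifnot(inherits(full, "bmr_full_model"))
  d <- length(full$prior$mean)
  indices <- as.integer(indices)
  if (!length(indices) || anyDuplicated(indices) ||
      any(indices < 1L) || any(indices > d))
    stop("indices must be distinct and within the model dimension",
         call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != length(indices))
    stop("values must match indices in length", call. = FALSE)
  if (any(full$prior$fixed[indices]) || any(full$posterior$fixed[indices]))
    stop("degenerate marginal: clamped coordinate already has zero variance",
         call. = FALSE)

  Ccc <- full$posterior$cov[indices, indices, drop = FALSE]
  Scc <- full$prior$cov[indices, indices, drop = FALSE]
  delta <- .ldmvnorm(values, full$posterior$mean[indices], Ccc) -
    .ldmvnorm(values, full$prior$mean[indices], Scc)

  r <- setdiff(seq_len(d), indices)
  post_mean <- numeric(d)
  post_cov <- matrix(0, d, d)
  prior_mean <- numeric(d)
  prior_cov <- matrix(0, d, d)
  if (length(r)) {
    cond_post <- density_conditional(full$posterior, indices, values)
    cond_prior <- density_conditional(full$prior, indices, values)
    post_mean[r] <- cond_post$mean
    post_cov[r, r] <- cond_post$cov
    prior_mean[r] <- cond_prior$mean
    prior_cov[r, r] <- cond_prior$cov
  }
  post_mean[indices] <- values
  prior_mean[indices] <- values
  posterior <- gaussian_density(post_mean, covariance = post_cov,
                                labels = full$posterior$labels)
  reduced_prior <- gaussian_density(prior_mean, covariance = prior_cov,
                                    labels = full$prior$labels)
  .reduced_result(full$free_energy + delta, delta, posterior, reduced_prior,
                  clamped_indices = indices, clamped_values = values)
}

#' Posterior model probabilities from log-evidences
#'
#' Under flat priors over models, the posterior probability of model k is the
#' softmax of the log-evidences (free energies):
#' \eqn{p(m_k|y) = e^{F_k} / \sum_j e^{F_j}}, computed stably by subtracting
#' the maximum. A log-Bayes factor of 3 corresponds to an odds ratio of about
#' twenty to one.
#'
#' @param free_energies numeric vector of log-evidences (or free-energy
#'   differences; any common constant cancels).
#' @return probability vector summing to one.
#' @examples
#' model_posterior(c(3, 0))
#' @export
model_posterior <- function(free_energies) {
  f <- as.numeric(free_energies)
  if (!length(f)) stop("empty free-energy vector", call. = FALSE)
  if (any(!is.finite(f))) stop("free energies must be finite", call. = FALSE)
  w <- exp(f - max(f))
  w / sum(w)
}

#' Fixed-effects pooling of log-evidence over subjects
#'
#' Treating models as fixed effects across conditionally independent
#' subjects, the group log-evidence of each model is the sum of its
#' per-subject log-evidences (free-energy differences).
#'
#' @param per_subject_delta_f numeric matrix, models x subjects.
#' @return list with `pooled_delta_f` (row sums) and `posterior_probs`
#'   (their [model_posterior()]).
#' @examples
#' pool_subjects(cbind(c(1, 2), c(2, 1)))
#' @export
pool_subjects <- function(per_subject_delta_f) {
  m <- as.matrix(per_subject_delta_f)
  if (any(!is.finite(m))) stop("free energies must be finite", call. = FALSE)
  pooled <- rowSums(m)
  list(pooled_delta_f = pooled, posterior_probs = model_posterior(pooled))
}
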