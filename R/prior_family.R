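#' Continuous model spaces: hyperparameterized prior families
#'
#' A prior family is a differentiable map from hyperparameters
#' \eqn{\lambda} to a Gaussian prior \eqn{(\eta(\lambda), \Pi(\lambda))},
#' defining a continuum of models whose free energy \eqn{F(\lambda)} can be
#' evaluated by analytic reduction and maximized
#' (\eqn{\lambda^* = \arg\max_\lambda F(\lambda)}).
#'
#' Two declarative families cover the common cases:
#' \describe{
#'   \item{`family_shared_mean_variance(base_prior, indices)`}{two
#'     hyperparameters, a shared prior mean and a shared prior variance
#'     applied to every indexed parameter (the hierarchical constraint that
#'     those parameters are exchangeable a priori).}
#'   \item{`family_per_param_variance(base_prior, indices, gamma)`}{one
#'     prior-variance hyperparameter per indexed parameter with mean fixed at
#'     zero -- automatic relevance determination, where the variance of an
#'     irrelevant parameter collapses toward zero.}
#' }
#'
#' @param param_fn function mapping a numeric hyperparameter vector to a
#'   [gaussian_density()] of constant dimension.
#' @param bounds numeric h x 2 matrix of closed per-hyperparameter intervals.
#' @param transform character vector, `"identity"` (means) or `"log"`
#'   (variances); variance-type hyperparameters are optimized on the log
#'   scale.
#' @param labels optional hyperparameter names.
#' @return An object of class `bmr_prior_family`.
#' @export
prior_family <- function(param_fn, bounds, transform, labels = NULL) {
  stopifnot(is.function(param_fn))
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  h <- nrow(bounds)
  transform <- match.arg(transform, c("identity", "log"), several.ok = TRUE)
  transform <- rep_len(transform, h)
  if (any(bounds[, 1] >= bounds[, 2]))
    stop("each bound interval must have lower < upper", call. = FALSE)
  if (any(transform == "log" & bounds[, 1] <= 0))
    stop("log-transformed hyperparameters need positive lower bounds",
         call. = FALSE)
  structure(list(param_fn = param_fn, bounds = bounds, transform = transform,
                 n_hyper = h, labels = labels),
            class = "bmr_prior_family")
}

#' @rdname prior_family
#' @param base_prior the full model's prior.
#' @param indices parameters governed by the family.
#' @export
family_shared_mean_variance <- function(base_prior, indices) {
  stopifnot(inherits(base_prior, "bmr_density"))
  indices <- as.integer(indices)
  fn <- function(lambda) {
    S <- base_prior$cov
    m <- base_prior$mean
    S[indices, ] <- 0; S[, indices] <- 0
    diag(S)[indices] <- lambda[2]
    m[indices] <- lambda[1]
    gaussian_density(m, covariance = S, labels = base_prior$labels)
  }
  vmax <- max(diag(base_prior$cov)[indices])
  prior_family(fn,
               bounds = rbind(c(-100, 100), c(exp(-16) * vmax, 1e6)),
               transform = c("identity", "log"),
               labels = c("prior_mean", "prior_variance"))
}

#' @rdname prior_family
#' @param gamma reference variance scale; the lower bound of each variance
#'   hyperparameter is `exp(-16) * gamma`, reported as an exact zero
#'   (collapse) in [optimize_prior()] output.
#' @export
family_per_param_variance <- function(base_prior, indices, gamma = NULL) {
  stopifnot(inherits(base_prior, "bmr_density"))
  indices <- as.integer(indices)
  if (is.null(gamma)) gamma <- max(diag(base_prior$cov)[indices])
  h <- length(indices)
  fn <- function(lambda) {
    S <- base_prior$cov
    m <- base_prior$mean
    S[indices, ] <- 0; S[, indices] <- 0
    diag(S)[indices] <- lambda
    m[indices] <- 0
    gaussian_density(m, covariance = S, labels = base_prior$labels)
  }
  fam <- prior_family(fn,
                      bounds = cbind(rep(exp(-16) * gamma, h), rep(1e6, h)),
                      transform = rep("log", h),
                      labels = paste0("var_", indices))
  fam$collapse_floor <- exp(-16) * gamma
  fam$indices <- indices
  fam
}

#' Free energy of one member of a prior family
#'
#' Evaluates \eqn{F(\lambda)} by reducing the full model to the prior the
#' family assigns to `lambda`. An invalid reduction (indefinite reduced
#' posterior precision) yields `-Inf` with attribute `invalid = TRUE` rather
#' than an error, so that optimizers can treat it as infeasible.
#'
#' @param full a [full_model()].
#' @param family a [prior_family()].
#' @param lambda hyperparameter vector within the family's bounds.
#' @return scalar \eqn{F(\lambda)} (nats).
#' @export
free_energy_of <- function(full, family, lambda) {
  stopifnot(inherits(full, "bmr_full_model"),
            inherits(family, "bmr_prior_family"))
  lambda <- as.numeric(lambda)
  if (length(lambda) != family$n_hyper)
    stop("lambda length must match the number of hyperparameters",
         call. = FALSE)
  if (any(lambda < family$bounds[, 1] - 1e-12) ||
      any(lambda > family$bounds[, 2] + 1e-12))
    stop("lambda outside the family bounds", call. = FALSE)
  red <- tryCatch(reduce_model(full, family$param_fn(lambda)),
                  error = function(e) e)
  if (inherits(red, "error")) {
    if (grepl("invalid reduction", conditionMessage(red)))
      return(structure(-Inf, invalid = TRUE))
    stop(red)
  }
  red$free_energy
}

#' Free-energy landscape of a prior family over a grid
#'
#' Deterministically evaluates \eqn{F(\lambda)} at each grid point, in grid
#' order; used to draw evidence landscapes over prior means and variances.
#'
#' @param full a [full_model()].
#' @param family a [prior_family()].
#' @param grid matrix (rows = hyperparameter vectors) or list of vectors.
#' @return data.frame with one column per hyperparameter and a
#'   `free_energy` column, rows in grid order.
#' @export
profile_family <- function(full, family, grid) {
  if (is.list(grid)) grid <- do.call(rbind, grid)
  grid <- matrix(as.numeric(grid), ncol = family$n_hyper)
  if (!nrow(grid)) stop("empty grid", call. = FALSE)
  f <- vapply(seq_len(nrow(grid)), function(i)
    as.numeric(free_energy_of(full, family, grid[i, ])), numeric(1))
  out <- as.data.frame(grid)
  names(out) <- if (!is.null(family$labels)) family$labels
                else paste0("lambda", seq_len(family$n_hyper))
  out$free_energy <- f
  out
}

# map lambda to/from the optimizer's working scale
.to_working <- function(family, lambda) {
  k <- family$transform == "log"
  lambda[k] <- log(lambda[k])
  lambda
}
.from_working <- function(family, w) {
  ifelse(family$transform == "log", exp(w), w)
}

#' Maximize reduced free energy over a prior family
#'
#' Ascends \eqn{F(\lambda)} with a quasi-Newton scheme (bounded BFGS with
#' numerically estimated gradients and curvature) on the working scale set by
#' each hyperparameter's link (`log` for variances), restarted from `lambda0`
#' plus seeded jitters to guard against local maxima. The returned optimum is
#' the best point ever evaluated, so \eqn{F(\lambda^*) \ge F(\lambda_0)} is
#' guaranteed. Variance-type hyperparameters that end at their lower bound
#' are reported as collapsed (exact zero) when the family defines a collapse
#' floor.
#'
#' @param full a [full_model()].
#' @param family a [prior_family()].
#' @param lambda0 feasible starting vector with finite \eqn{F(\lambda_0)}.
#' @param n_starts number of starts (`lambda0` plus `n_starts - 1` jitters).
#' @param max_iter iteration cap per start.
#' @param tol convergence tolerance on \eqn{\Delta F} (nats).
#' @param seed seed for the jittered restarts.
#'
#' @return list with `lambda_star`, `free_energy`, `reduced` (the
#'   [reduce_model()] result at the optimum), `collapsed` (logical per
#'   hyperparameter, variance families only), `trajectory` (data.frame of all
#'   evaluations), `converged`.
#' @export
optimize_prior <- function(full, family, lambda0, n_starts = 5L,
                           max_iter = 128L, tol = 1e-4, seed = 1L) {
  stopifnot(inherits(full, "bmr_full_model"),
            inherits(family, "bmr_prior_family"))
  lambda0 <- as.numeric(lambda0)
  f0 <- free_energy_of(full, family, lambda0)
  if (!is.finite(f0))
    stop("stuck: F(lambda0) is not finite; supply a feasible start",
         call. = FALSE)
  lo <- .to_working(family, family$bounds[, 1])
  hi <- .to_working(family, family$bounds[, 2])
  w0 <- .to_working(family, lambda0)

  evals <- new.env(parent = emptyenv())
  evals$lambda <- list(); evals$f <- numeric(0)
  objective <- function(w) {
    lam <- pmin(pmax(.from_working(family, w), family$bounds[, 1]),
                family$bounds[, 2])
    f <- as.numeric(free_energy_of(full, family, lam))
    evals$lambda[[length(evals$lambda) + 1L]] <- lam
    evals$f[length(evals$f) + 1L] <- f
    if (!is.finite(f)) 1e10 else -f
  }

  starts <- list(w0)
  if (n_starts > 1L) {
    jit <- .with_seed(derive_seed(seed, "optimize_prior"), function()
      matrix(stats::rnorm((n_starts - 1L) * length(w0), sd = 0.5),
             nrow = n_starts - 1L))
    for (j in seq_len(n_starts - 1L))
      starts[[j + 1L]] <- pmin(pmax(w0 + jit[j, ], lo), hi)
  }
  conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = max_iter,
                                  factr = tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$convergence == 0) conv <- TRUE
  }
  objective(w0)  # ensure the start itself is in the evaluation record
  ok <- is.finite(evals$f)
  best <- which(ok)[which.max(evals$f[ok])]
  lambda_star <- evals$lambda[[best]]
  f_star <- evals$f[best]
  # boundary polish: quasi-Newton steps stall where the landscape flattens on
  # the log scale, so test each variance-type hyperparameter at its lower
  # bound and keep the bound whenever the free energy is within the
  # convergence tolerance (indistinguishable optima resolve to the more
  # parsimonious prior)
  logk <- which(family$transform == "log")
  if (length(logk)) {
    for (pass in 1:3) {
      changed <- FALSE
      for (k in logk) {
        if (lambda_star[k] <= family$bounds[k, 1] * (1 + 1e-6)) next
        cand <- lambda_star
        cand[k] <- family$bounds[k, 1]
        f_cand <- as.numeric(free_energy_of(full, family, cand))
        if (is.finite(f_cand) && f_cand >= f_star - tol) {
          lambda_star <- cand
          f_star <- f_cand
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  collapsed <- rep(FALSE, family$n_hyper)
  if (!is.null(family$collapse_floor)) {
    collapsed <- family$transform == "log" &
      lambda_star <= family$collapse_floor * (1 + 1e-6)
  }
  red <- reduce_model(full, family$param_fn(lambda_star))
  traj <- as.data.frame(do.call(rbind, evals$lambda))
  names(traj) <- if (!is.null(family$labels)) family$labels
                 else paste0("lambda", seq_len(family$n_hyper))
  traj$free_energy <- evals$f
  list(lambda_star = lambda_star, free_energy = red$free_energy,
       reduced = red, collapsed = collapsed, trajectory = traj,
       converged = conv)
}
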