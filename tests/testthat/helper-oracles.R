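# Independent numeric oracles used across the suite.

# Log-density of N(m, S) evaluated at the rows of a matrix of points.
.oracle_ldn_rows <- function(pts, m, S) {
  d <- length(m)
  R <- chol((S + t(S)) / 2)
  z <- backsolve(R, t(pts) - m, transpose = TRUE)
  -d / 2 * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

# Quadrature oracle for delta_f in d <= 3 dimensions: trapezoid tensor grid
# over +/- 10 standard deviations around the posterior mean (spectrally
# accurate for smooth decaying integrands). Integrand is the reduced model's
# q(theta) p_i(theta) / p_F(theta).
quad_delta_f <- function(full, reduced_prior, n_grid = 161L, half_width = 10) {
  d <- length(full$posterior$mean)
  stopifnot(d <= 3)
  # center the grid on the integrand's mode, found numerically (independent
  # of the closed form under test), with scale from a numeric Hessian
  nll <- function(th) -(.oracle_ldn_rows(matrix(th, 1), full$posterior$mean,
                                         full$posterior$cov) +
                        .oracle_ldn_rows(matrix(th, 1), reduced_prior$mean,
                                         reduced_prior$cov) -
                        .oracle_ldn_rows(matrix(th, 1), full$prior$mean,
                                         full$prior$cov))
  opt <- stats::optim(full$posterior$mean, nll, method = "BFGS",
                      hessian = TRUE)
  sdv <- sqrt(diag(solve((opt$hessian + t(opt$hessian)) / 2)))
  grids <- lapply(seq_len(d), function(k)
    seq(opt$par[k] - half_width * sdv[k],
        opt$par[k] + half_width * sdv[k],
        length.out = n_grid))
  h <- vapply(grids, function(g) g[2] - g[1], numeric(1))
  pts <- as.matrix(expand.grid(grids))
  lw <- .oracle_ldn_rows(pts, full$posterior$mean, full$posterior$cov) +
    .oracle_ldn_rows(pts, reduced_prior$mean, reduced_prior$cov) -
    .oracle_ldn_rows(pts, full$prior$mean, full$prior$cov)
  mx <- max(lw)
  mx + log(sum(exp(lw - mx))) + sum(log(h))
}

# Exact conjugate full model for y = X beta + noise with *known* noise
# variance: Gaussian posterior and exact log evidence.
conjugate_full_model <- function(y, X, prior_mean, prior_var,
                                 noise_var = 1) {
  p <- ncol(X)
  V0 <- diag(prior_var, p)
  P <- crossprod(X) / noise_var + diag(1 / prior_var, p)
  S <- solve((P + t(P)) / 2)
  mu <- as.numeric(S %*% (crossprod(X, y) / noise_var + prior_mean / prior_var))
  ev <- closed_form_evidence(glm_data(y, X),
                             gaussian_density(prior_mean, covariance = V0),
                             noise_var)
  full_model(gaussian_density(prior_mean, covariance = V0),
             gaussian_density(mu, covariance = (S + t(S)) / 2),
             free_energy = ev)
}

# A small random proper full model (prior and PD posterior) of dimension d.
random_full_model <- function(d, seed) {
  set.seed(seed)
  rnd_spd <- function() {
    A <- matrix(stats::rnorm(d * d), d)
    crossprod(A) / d + diag(d) * 0.5
  }
  full_model(gaussian_density(stats::rnorm(d), covariance = rnd_spd()),
             gaussian_density(stats::rnorm(d), covariance = rnd_spd()),
             free_energy = stats::rnorm(1))
}
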