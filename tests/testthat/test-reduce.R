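test_that("reducing to the full prior is the identity", {
  fm <- random_full_model(4, seed = 11)
  red <- reduce_model(fm, fm$prior)
  expect_equal(red$delta_f, 0, tolerance = 1e-10)
  expect_equal(red$free_energy, fm$free_energy, tolerance = 1e-10)
  expect_equal(red$posterior$mean, fm$posterior$mean, tolerance = 1e-10)
  expect_equal(red$posterior$cov, fm$posterior$cov, tolerance = 1e-10)
})

test_that("1-D reduction matches the quadrature oracle", {
  # full prior N(0,4), posterior N(1,0.25), reduced prior N(0,1);
  # oracle value frozen from adaptive quadrature of the reduced-evidence
  # integrand
  fm <- full_model(gaussian_density(0, covariance = matrix(4)),
                   gaussian_density(1, covariance = matrix(0.25)))
  rp <- gaussian_density(0, covariance = matrix(1))
  red <- reduce_model(fm, rp)
  expect_equal(red$delta_f, 0.291432578412, tolerance = 1e-9)
  # and recomputed here by adaptive quadrature
  orc <- integrate(function(th)
    dnorm(th, 1, 0.5) * dnorm(th, 0, 1) / dnorm(th, 0, 2),
    -15, 15, rel.tol = 1e-12)
  expect_equal(red$delta_f, log(orc$value), tolerance = 1e-9)
})

test_that("2-D and 3-D reductions match the quadrature oracle to 1e-6", {
  for (d in 2:3) {
    fm <- random_full_model(d, seed = 100 + d)
    set.seed(200 + d)
    A <- matrix(rnorm(d * d), d)
    rp <- gaussian_density(rnorm(d), covariance = crossprod(A) / d + 0.3 * diag(d))
    red <- reduce_model(fm, rp)
    expect_equal(red$delta_f, quad_delta_f(fm, rp) - 0, tolerance = 1e-6)
  }
})

test_that("reduction reproduces conjugate evidence differences to 1e-8", {
  set.seed(5)
  n <- 40; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% c(1, 0.5, 0) + rnorm(n, sd = 0.7)
  fm <- conjugate_full_model(y, X, prior_mean = rep(0, p),
                             prior_var = rep(4, p), noise_var = 0.49)
  # reduced prior: tighter variance on all three coefficients
  rp <- gaussian_density(rep(0, p), covariance = diag(0.5, p))
  ev_red <- closed_form_evidence(glm_data(y, X), rp, 0.49)
  red <- reduce_model(fm, rp)
  expect_equal(red$delta_f, ev_red - fm$free_energy, tolerance = 1e-8)
  # point-mass path against a re-fit on the restricted design
  cl <- clamp_parameters(fm, 3L, 0)
  rp2 <- gaussian_density(rep(0, 2), covariance = diag(4, 2))
  ev2 <- closed_form_evidence(glm_data(y, X[, 1:2]), rp2, 0.49)
  expect_equal(cl$delta_f, ev2 - fm$free_energy, tolerance = 1e-8)
})

test_that("clamp is the epsilon-variance limit of reduce", {
  # diagonal prior (the package's standard case), correlated posterior; with
  # a diagonal prior the point-mass limit of the prior is unambiguous
  set.seed(21)
  A <- matrix(rnorm(16), 4)
  fm <- full_model(gaussian_density(rnorm(4), covariance = diag(runif(4, 1, 3))),
                   gaussian_density(rnorm(4),
                                    covariance = crossprod(A) / 4 + 0.5 * diag(4)))
  v <- c(0.3, -0.2)
  cl <- clamp_parameters(fm, c(2, 4), v)
  eps <- 1e-6 * max(diag(fm$prior$cov))
  S <- fm$prior$cov
  S[c(2, 4), ] <- 0; S[, c(2, 4)] <- 0
  diag(S)[c(2, 4)] <- eps
  m <- fm$prior$mean; m[c(2, 4)] <- v
  red <- reduce_model(fm, gaussian_density(m, covariance = S))
  expect_equal(cl$delta_f, red$delta_f, tolerance = 1e-3)
  expect_equal(cl$posterior$mean, red$posterior$mean, tolerance = 1e-3)
})

test_that("clamped posterior records point masses at the clamp values", {
  fm <- random_full_model(3, seed = 31)
  cl <- clamp_parameters(fm, 2L, 0.7)
  expect_equal(cl$posterior$mean[2], 0.7)
  expect_equal(cl$posterior$cov[2, ], rep(0, 3))
  expect_identical(cl$clamped_indices, 2L)
  expect_equal(cl$free_energy - fm$free_energy, cl$delta_f)
})

test_that("no data means no evidence change: clamp of posterior = prior", {
  pr <- gaussian_density(c(0.5, -1), covariance = matrix(c(2, 0.4, 0.4, 1), 2))
  fm <- full_model(pr, pr)
  for (v in c(-1, 0, 2))
    expect_equal(clamp_parameters(fm, 1L, v)$delta_f, 0, tolerance = 1e-12)
})

test_that("clamp delta_f is monotone in posterior Mahalanobis distance", {
  # informative-data case (prior wider than posterior, shared mean): the
  # Savage-Dickey ratio is a concave quadratic peaked at the mean, so
  # delta_f decays monotonically with the Mahalanobis distance of the clamp
  set.seed(77)
  for (rep in 1:5) {
    d <- 3
    A <- matrix(rnorm(d * d), d)
    Spost <- crossprod(A) / d + 0.3 * diag(d)
    mu <- rnorm(d)
    fm <- full_model(gaussian_density(mu, covariance = diag(d) * 10),
                     gaussian_density(mu, covariance = Spost))
    i <- sample(d, 1)
    sd_ <- sqrt(Spost[i, i])
    dirn <- sample(c(-1, 1), 1)
    df <- vapply(c(0, 0.5, 1.5, 3), function(k)
      clamp_parameters(fm, i, mu[i] + dirn * k * sd_)$delta_f, numeric(1))
    expect_true(all(diff(df) < 0))
  }
  # general claim: clamping far from the posterior mean is always worse than
  # clamping at the posterior mean itself
  fm <- random_full_model(3, seed = 405)
  i <- 2
  mu <- fm$posterior$mean[i]; sd_ <- sqrt(fm$posterior$cov[i, i])
  expect_lt(clamp_parameters(fm, i, mu + 10 * sd_)$delta_f,
            clamp_parameters(fm, i, mu)$delta_f)
})

test_that("delta_f depends only on the marginals of altered parameters", {
  fm <- random_full_model(3, seed = 51)
  rp <- gaussian_density(c(0, 0, 0), covariance = diag(c(1, 0.5, 2)))
  base <- reduce_model(fm, rp)$delta_f

  # pad with two independent nuisance parameters (prior untouched)
  pad <- function(dens, extra_mean, extra_cov) {
    d <- length(dens$mean)
    S <- matrix(0, d + 2, d + 2)
    S[1:d, 1:d] <- dens$cov
    S[d + 1:2, d + 1:2] <- extra_cov
    gaussian_density(c(dens$mean, extra_mean), covariance = S)
  }
  nuis_prior <- matrix(c(3, 0.2, 0.2, 2), 2)
  nuis_post <- matrix(c(1, -0.1, -0.1, 0.8), 2)
  fm_pad <- full_model(pad(fm$prior, c(1, -1), nuis_prior),
                       pad(fm$posterior, c(0.2, 0.1), nuis_post),
                       free_energy = fm$free_energy)
  rp_pad <- pad(rp, c(1, -1), nuis_prior)  # nuisance prior unchanged
  expect_equal(reduce_model(fm_pad, rp_pad)$delta_f, base, tolerance = 1e-9)

  # permuting coordinates (consistently) leaves delta_f unchanged
  perm <- c(3, 1, 2)
  permute <- function(dens) gaussian_density(dens$mean[perm],
                                             covariance = dens$cov[perm, perm])
  fm_perm <- full_model(permute(fm$prior), permute(fm$posterior),
                        free_energy = fm$free_energy)
  expect_equal(reduce_model(fm_perm, permute(rp))$delta_f, base,
               tolerance = 1e-9)
})

test_that("posterior precision identity holds on the non-clamped block", {
  fm <- random_full_model(4, seed = 61)
  S <- fm$prior$cov
  S[2, ] <- 0; S[, 2] <- 0  # clamp coordinate 2
  m <- fm$prior$mean; m[2] <- 0
  S[-2, -2] <- diag(c(1, 2, 0.5))
  red <- reduce_model(fm, gaussian_density(m, covariance = S))
  free <- c(1, 3, 4)
  P_i <- solve(red$posterior$cov[free, free])
  P_F <- fm$posterior$prec[free, free]
  Pi_i <- red$reduced_prior$prec[free, free]
  Pi_F <- fm$prior$prec[free, free]
  expect_equal(P_i - P_F, Pi_i - Pi_F, tolerance = 1e-7)
})

test_that("reduction errors are informative", {
  fm <- random_full_model(3, seed = 71)
  expect_error(reduce_model(fm, gaussian_density(c(0, 0),
                                                 covariance = diag(2))),
               "dimension mismatch")
  lab_prior <- gaussian_density(fm$prior$mean, covariance = fm$prior$cov,
                                labels = c("a", "b", "c"))
  lab_fm <- full_model(lab_prior,
                       gaussian_density(fm$posterior$mean,
                                        covariance = fm$posterior$cov,
                                        labels = c("a", "b", "c")),
                       fm$free_energy)
  wrong <- gaussian_density(fm$prior$mean, covariance = fm$prior$cov,
                            labels = c("a", "c", "b"))
  expect_error(reduce_model(lab_fm, wrong), "label mismatch")
  # widening the prior far beyond the posterior makes P_i indefinite
  wide <- gaussian_density(fm$prior$mean,
                           covariance = fm$prior$cov * 1e6)
  expect_error(reduce_model(fm, wide), "invalid reduction")
  # support violation: full prior fixes a coordinate the reduced prior frees
  Sfix <- fm$prior$cov; Sfix[3, ] <- 0; Sfix[, 3] <- 0
  fm_fix <- full_model(gaussian_density(fm$prior$mean, covariance = Sfix),
                       fm$posterior, fm$free_energy)
  expect_error(reduce_model(fm_fix, fm$prior), "support violation")
})

test_that("model_posterior matches its contract", {
  expect_equal(model_posterior(c(0, 0)), c(0.5, 0.5))
  p <- model_posterior(c(3, 0))
  expect_equal(p, c(exp(3), 1) / (1 + exp(3)), tolerance = 1e-12)
  expect_equal(p[1] / p[2], exp(3), tolerance = 1e-12)
  f <- c(-2, 1, 0.5, 7)
  expect_equal(model_posterior(f), model_posterior(f + 123.4),
               tolerance = 1e-12)
  expect_equal(sum(model_posterior(rnorm(20))), 1, tolerance = 1e-12)
  expect_error(model_posterior(numeric(0)), "empty")
  expect_error(model_posterior(c(1, Inf)), "finite")
})

test_that("pool_subjects sums log-evidence over subjects", {
  one <- pool_subjects(matrix(c(1, 3), ncol = 1))
  expect_equal(one$pooled_delta_f, c(1, 3))
  expect_equal(one$posterior_probs, model_posterior(c(1, 3)))

  two <- pool_subjects(cbind(c(1, 1), c(2, 2)))
  expect_equal(two$pooled_delta_f, c(3, 3))
  expect_equal(two$posterior_probs, c(0.5, 0.5))

  # pooled winner differing from every single-subject winner: model 1 is
  # second-best for both subjects but wins on the summed log-evidence
  m <- cbind(c(2.5, 3, 0), c(2.5, 0, 3))
  res <- pool_subjects(m)
  expect_identical(which.max(res$pooled_delta_f), 1L)
  expect_false(1L %in% apply(m, 2, which.max))
})
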