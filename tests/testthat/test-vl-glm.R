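test_that("glm_data validates its inputs", {
  expect_error(glm_data(1:3, matrix(0, 2, 1)), "row counts")
  expect_error(glm_data(c(1, NA), matrix(0, 2, 1)), "missing")
  expect_error(glm_data(1:3, matrix(0, 3, 1), c(1, 3, 3)), "non-empty")
  d <- glm_data(1:3, matrix(rnorm(3), 3, 1), c(1, 2, 1))
  expect_identical(d$n_groups, 2L)
})

test_that("glm_priors validates moments", {
  expect_error(glm_priors(2, 1, beta_variance = c(1, -1)), "positive")
  expect_error(glm_priors(2, 1, logprec_mean = Inf), "finite")
  p <- glm_priors(3, 2)
  expect_equal(p$beta_variance, rep(32, 3))
  expect_equal(p$logprec_variance, rep(32, 2))
})

test_that("simulators honor their generating contracts", {
  # zero noise: y is exactly the regressor sum
  sim0 <- simulate_optimization_dataset(3, noise_scale = 0)
  expect_equal(sim0$data$y, as.numeric(sim0$data$X %*% rep(1, 4)),
               tolerance = 1e-12)
  sel0 <- simulate_selection_dataset(3, noise_scale = 0)
  expect_equal(sel0$data$y, rowSums(sel0$data$X[, 1:4]), tolerance = 1e-12)
  expect_identical(dim(sel0$data$X), c(16L, 12L))
  expect_identical(sel0$truth$support, 1:4)

  # determinism
  expect_identical(simulate_optimization_dataset(9),
                   simulate_optimization_dataset(9))
  expect_identical(simulate_selection_dataset(9),
                   simulate_selection_dataset(9))
  expect_false(identical(simulate_selection_dataset(9),
                         simulate_selection_dataset(10)))

  # noise law: group-1 variance ~ exp(-2), selection noise variance ~ 0.5
  v1 <- mean(vapply(1:1000, function(s) {
    sim <- simulate_optimization_dataset(s)
    mean((sim$data$y - sim$data$X %*% rep(1, 4))[1:32]^2)
  }, numeric(1)))
  expect_equal(v1, exp(-2), tolerance = 0.05)
  v2 <- mean(vapply(1:1000, function(s) {
    sim <- simulate_selection_dataset(s)
    mean((sim$data$y - rowSums(sim$data$X[, 1:4]))^2)
  }, numeric(1)))
  expect_equal(v2, 0.5, tolerance = 0.05)
})

test_that("known-precision limit matches the conjugate closed form", {
  set.seed(13)
  n <- 48; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(1, -1, 0.5)) + rnorm(n, sd = 0.5)
  true_logprec <- log(1 / 0.25)
  pri <- glm_priors(p, 1, beta_variance = rep(4, p),
                    logprec_mean = true_logprec, logprec_variance = 1e-8)
  fit <- invert_glm(glm_data(y, X), pri)
  fm_conj <- conjugate_full_model(y, X, rep(0, p), rep(4, p),
                                  noise_var = 0.25)
  expect_equal(fit$posterior$mean[1:p], fm_conj$posterior$mean,
               tolerance = 1e-6)
  expect_equal(fit$posterior$cov[1:p, 1:p], fm_conj$posterior$cov,
               tolerance = 1e-6)
  expect_equal(fit$free_energy, fm_conj$free_energy, tolerance = 0.01)
})

test_that("free energy is non-decreasing over sweeps", {
  for (s in c(1, 5, 9)) {
    fit <- invert_glm(simulate_optimization_dataset(s)$data)
    expect_true(all(diff(fit$meta$F_trajectory) > -1e-3))
    expect_true(fit$meta$converged)
  }
})

test_that("log-precision posteriors cover the generating values", {
  ok <- 0L; okb <- 0L
  for (s in 1:100) {
    sim <- simulate_optimization_dataset(s)
    fm <- invert_glm(sim$data)
    mg <- fm$posterior$mean[5:6]
    sg <- sqrt(diag(fm$posterior$cov)[5:6])
    if (all(abs(mg - c(2, 1)) <= 3 * sg)) ok <- ok + 1L
    mb <- fm$posterior$mean[1:4]
    sb <- sqrt(diag(fm$posterior$cov)[1:4])
    if (all(abs(mb - 1) <= 3 * sb)) okb <- okb + 1L
  }
  expect_gte(ok, 90L)
  expect_gte(okb, 90L)
})

test_that("p = 0 free energy matches 1-D quadrature over the log-precision", {
  set.seed(17)
  y <- rnorm(10, sd = 0.8)
  g0 <- 0.5; u0 <- 2
  fit <- invert_glm(glm_data(y, matrix(numeric(0), 10, 0)),
                    glm_priors(0, 1, logprec_mean = g0,
                               logprec_variance = u0))
  n <- length(y); ssq <- sum(y^2)
  orc <- integrate(Vectorize(function(g)
    exp(n / 2 * g - n / 2 * log(2 * pi) - exp(g) * ssq / 2) *
      dnorm(g, g0, sqrt(u0))), -12, 6, rel.tol = 1e-11)
  expect_equal(fit$free_energy, log(orc$value), tolerance = 0.01)
})

test_that("reduction of the inverted model is conjugate-consistent", {
  set.seed(19)
  n <- 48; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(1, 1, 0, 0)) + rnorm(n, sd = 0.5)
  # known-precision limit: BMR on the beta block reproduces closed-form
  # evidence differences
  pri <- glm_priors(p, 1, beta_variance = rep(8, p),
                    logprec_mean = log(4), logprec_variance = 1e-8)
  fit <- invert_glm(glm_data(y, X), pri)
  cl <- clamp_parameters(fit, 3:4, c(0, 0))
  ev_full <- closed_form_evidence(glm_data(y, X),
                                  gaussian_density(rep(0, p),
                                                   covariance = diag(8, p)),
                                  0.25)
  ev_red <- closed_form_evidence(glm_data(y, X[, 1:2]),
                                 gaussian_density(rep(0, 2),
                                                  covariance = diag(8, 2)),
                                 0.25)
  expect_equal(cl$delta_f, ev_red - ev_full, tolerance = 1e-6)
})

test_that("closed_form_evidence contracts hold", {
  set.seed(23)
  y <- rnorm(12, sd = 1.3)
  X0 <- matrix(0, 12, 1)
  pr <- gaussian_density(0, covariance = matrix(4))
  ev0 <- closed_form_evidence(glm_data(y, X0), pr, 1.69)
  expect_equal(ev0, sum(dnorm(y, 0, 1.3, log = TRUE)), tolerance = 1e-10)

  X <- matrix(rnorm(24), 12, 2)
  prior2 <- gaussian_density(c(0.2, -0.1), covariance = diag(c(2, 3)))
  grp <- rep(1:2, each = 6)
  ev <- closed_form_evidence(glm_data(y, X, grp), prior2, c(1, 2))
  perm <- sample(12)
  ev_p <- closed_form_evidence(glm_data(y[perm], X[perm, ], grp[perm]),
                               prior2, c(1, 2))
  expect_equal(ev, ev_p, tolerance = 1e-10)

  # 1-D quadrature cross-check
  x1 <- matrix(rnorm(8), 8, 1)
  y1 <- as.numeric(x1 * 0.7) + rnorm(8, sd = 0.5)
  ev1 <- closed_form_evidence(glm_data(y1, x1),
                              gaussian_density(0, covariance = matrix(2)),
                              0.25)
  orc <- integrate(Vectorize(function(b)
    exp(sum(dnorm(y1, x1 * b, 0.5, log = TRUE))) * dnorm(b, 0, sqrt(2))),
    -10, 10, rel.tol = 1e-11)
  expect_equal(ev1, log(orc$value), tolerance = 1e-8)

  expect_error(closed_form_evidence(glm_data(y1, x1),
                                    gaussian_density(0, covariance = matrix(0)),
                                    0.25), "proper")
  expect_error(closed_form_evidence(glm_data(y1, x1), pr, -1), "positive")
})

test_that("inversion is deterministic and labels the parameter blocks", {
  sim <- simulate_optimization_dataset(31)
  f1 <- invert_glm(sim$data)
  f2 <- invert_glm(sim$data)
  expect_identical(f1$posterior$mean, f2$posterior$mean)
  expect_identical(f1$free_energy, f2$free_energy)
  expect_identical(f1$prior$labels,
                   c("beta_1", "beta_2", "beta_3", "beta_4",
                     "gamma_1", "gamma_2"))
  # mean-field block structure: zero cross-precision between beta and gamma
  expect_true(all(f1$posterior$prec[1:4, 5:6] == 0))
})
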