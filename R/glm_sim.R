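#' General linear model data with group-wise noise precisions
#'
#' @param y numeric response vector of length n.
#' @param X n x p design matrix (p may be 0).
#' @param partition length-n integer vector of noise-group indices in
#'   `1..G`; all groups must be non-empty. Default: a single group.
#' @return An object of class `bmr_glm_data`.
#' @export
glm_data <- function(y, X, partition = rep(1L, length(y))) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y and X row counts differ", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed", call. = FALSE)
  partition <- as.integer(partition)
  if (length(partition) != length(y))
    stop("partition length must equal n", call. = FALSE)
  G <- max(partition)
  if (any(partition < 1L) || !all(seq_len(G) %in% partition))
    stop("noise groups must be 1..G with every group non-empty", call. = FALSE)
  structure(list(y = y, X = X, partition = partition, n_groups = G),
            class = "bmr_glm_data")
}

#' @export
print.bmr_glm_data <- function(x, ...) {
  cat(sprintf("GLM data: n = %d, p = %d, %d noise group(s)\n",
              length(x$y), ncol(x$X), x$n_groups))
  invisible(x)
}

#' Gaussian priors for the variational-Laplace GLM
#'
#' Independent Gaussian priors on the p regression coefficients and on the G
#' noise log-precisions. The defaults are uninformative shrinkage priors with
#' mean zero and variance 32 on every parameter.
#'
#' @param p number of regression coefficients.
#' @param n_groups number of noise groups.
#' @param beta_mean,beta_variance length-p prior moments for the
#'   coefficients.
#' @param logprec_mean,logprec_variance length-G prior moments for the noise
#'   log-precisions.
#' @return An object of class `bmr_glm_priors`.
#' @export
glm_priors <- function(p, n_groups = 1L,
                       beta_mean = rep(0, p), beta_variance = rep(32, p),
                       logprec_mean = rep(0, n_groups),
                       logprec_variance = rep(32, n_groups)) {
  beta_mean <- rep_len(as.numeric(beta_mean), p)
  beta_variance <- rep_len(as.numeric(beta_variance), p)
  logprec_mean <- rep_len(as.numeric(logprec_mean), n_groups)
  logprec_variance <- rep_len(as.numeric(logprec_variance), n_groups)
  if (any(!is.finite(c(beta_mean, beta_variance, logprec_mean,
                       logprec_variance))) ||
      any(beta_variance <= 0) || any(logprec_variance <= 0))
    stop("prior moments must be finite with positive variances",
         call. = FALSE)
  structure(list(beta_mean = beta_mean, beta_variance = beta_variance,
                 logprec_mean = logprec_mean,
                 logprec_variance = logprec_variance),
            class = "bmr_glm_priors")
}

#' Simulated GLM for prior optimization on noise log-precisions
#'
#' Sixty-four observations from four standard-normal regressors with unit
#' coefficients; Gaussian noise with log-precision 2 on the first half of the
#' observations and log-precision 1 on the second half (two noise groups of
#' 32). Fully determined by the seed.
#'
#' @param seed integer seed.
#' @param noise_scale multiplier on the noise amplitude (0 gives noise-free
#'   data for exact checks).
#' @return list with `data` (a [glm_data()]) and `truth` (generating values).
#' @export
simulate_optimization_dataset <- function(seed, noise_scale = 1) {
  .with_seed(seed, function() {
    n <- 64L; p <- 4L
    X <- matrix(stats::rnorm(n * p), n, p)
    beta <- rep(1, p)
    logprec <- c(2, 1)
    partition <- rep(1:2, each = n / 2)
    eps <- stats::rnorm(n, sd = exp(-logprec[partition] / 2)) * noise_scale
    y <- as.numeric(X %*% beta) + eps
    list(data = glm_data(y, X, partition),
         truth = list(beta = beta, logprec = logprec, seed = seed))
  })
}

#' Simulated GLM for automatic model selection over regressors
#'
#' Sixteen observations generated as the sum of four standard-normal
#' regressors (unit coefficients) plus Gaussian noise with precision 2, with
#' a further eight standard-normal decoy regressors (true coefficient zero)
#' appended before inversion: twelve candidate regressors of which the true
#' support is \{1, 2, 3, 4\}.
#'
#' @inheritParams simulate_optimization_dataset
#' @return list with `data` and `truth` (including `support = 1:4`).
#' @export
simulate_selection_dataset <- function(seed, noise_scale = 1) {
  .with_seed(seed, function() {
    n <- 16L
    X_true <- matrix(stats::rnorm(n * 4L), n, 4L)
    eps <- stats::rnorm(n, sd = sqrt(1 / 2)) * noise_scale
    y <- rowSums(X_true) + eps
    X_decoy <- matrix(stats::rnorm(n * 8L), n, 8L)
    X <- cbind(X_true, X_decoy)
    list(data = glm_data(y, X),
         truth = list(beta = c(rep(1, 4), rep(0, 8)), support = 1:4,
                      noise_precision = 2, seed = seed))
  })
}
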