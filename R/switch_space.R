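#' Discrete model space defined by binary switch priors
#'
#' A switch space maps binary vectors \eqn{\lambda \in \{0,1\}^K} to reduced
#' priors: each switchable parameter gets a zero-mean prior whose variance is
#' either zero (switched off -- an exact point mass at zero) or a fixed value
#' `gamma` (switched on). Constraint groups force sets of switches (for
#' example reciprocal connection pairs) to share one value, so the number of
#' free switches is the number of groups plus the number of ungrouped
#' switchable parameters.
#'
#' @param base_prior the full model's prior, a [gaussian_density()].
#' @param switchable integer indices of switchable parameters.
#' @param gamma positive prior variance given to switched-on parameters.
#' @param pairs list of integer vectors; each group must be a disjoint subset
#'   of `switchable` and shares a single switch value.
#'
#' @return An object of class `bmr_switch_space`.
#' @examples
#' pr <- gaussian_density(rep(0, 3), covariance = diag(32, 3))
#' switch_space(pr, switchable = 1:3, gamma = 8)
#' @export
switch_space <- function(base_prior, switchable, gamma, pairs = list()) {
  stopifnot(inherits(base_prior, "bmr_density"))
  d <- length(base_prior$mean)
  switchable <- sort(unique(as.integer(switchable)))
  if (any(switchable < 1L) || any(switchable > d))
    stop("switchable indices out of range", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  if (any(base_prior$fixed[switchable]))
    stop("switchable parameters must have a proper base prior", call. = FALSE)
  pairs <- lapply(pairs, function(g) sort(as.integer(g)))
  allg <- unlist(pairs)
  if (length(allg)) {
    if (anyDuplicated(allg))
      stop("constraint groups must be disjoint", call. = FALSE)
    if (!all(allg %in% switchable))
      stop("constraint groups must be subsets of switchable", call. = FALSE)
  }
  ungrouped <- setdiff(switchable, allg)
  groups <- c(pairs, as.list(ungrouped))
  # deterministic group order: by smallest member index
  groups <- groups[order(vapply(groups, min, integer(1)))]
  structure(list(n_params = d, switchable = switchable, gamma = gamma,
                 groups = groups, base_prior = base_prior),
            class = "bmr_switch_space")
}

#' @export
print.bmr_switch_space <- function(x, ...) {
  cat(sprintf(paste0("Switch space: %d parameters, %d switchable, ",
                     "%d free switches, gamma = %g\n"),
              x$n_params, length(x$switchable), length(x$groups), x$gamma))
  cat(sprintf("model count: %s\n", format(model_count(x), big.mark = ",")))
  invisible(x)
}

#' Number of free switches in a switch space
#' @param space a [switch_space()].
#' @return integer count of independent binary switches.
#' @export
n_free_switches <- function(space) {
  stopifnot(inherits(space, "bmr_switch_space"))
  length(space$groups)
}

#' Closed-form model count of a switch space
#'
#' Returns \eqn{2^K} for K free switches as a double, so counts far beyond
#' enumerable sizes (for example the \eqn{2^{64} \approx 1.84\times 10^{19}}
#' permutations of an 8-node full adjacency matrix) are still exact in the
#' closed form.
#'
#' @param space a [switch_space()].
#' @return numeric model count.
#' @export
model_count <- function(space) {
  2^n_free_switches(space)
}

#' Enumerate all switch vectors of a discrete model space
#'
#' Produces every assignment of the free switches in deterministic
#' lexicographic order (first free switch most significant; the all-zero
#' vector first), expanded to full switch vectors over `space$switchable`
#' with constraint groups sharing one value.
#'
#' @param space a [switch_space()].
#' @param max_free hard cap on free switches for exhaustive enumeration.
#' @return integer matrix with one row per model and one column per
#'   switchable parameter (columns named by parameter index).
#' @export
enumerate_switches <- function(space, max_free = 24L) {
  stopifnot(inherits(space, "bmr_switch_space"))
  K <- n_free_switches(space)
  if (K > max_free)
    stop(sprintf(paste0("%d free switches exceed the exhaustive cap (%d); ",
                        "use greedy_search() for large model spaces"),
                 K, max_free), call. = FALSE)
  n <- 2^K
  free <- matrix(0L, nrow = n, ncol = K)
  if (K > 0L) {
    for (k in seq_len(K)) {
      # bit k (1 = most significant) of the row index in lexicographic order
      period <- 2^(K - k)
      free[, k] <- as.integer(((seq_len(n) - 1L) %/% period) %% 2L)
    }
  }
  lam <- matrix(0L, nrow = n, ncol = length(space$switchable))
  colnames(lam) <- as.character(space$switchable)
  for (k in seq_len(K)) {
    cols <- match(space$groups[[k]], space$switchable)
    lam[, cols] <- free[, k]
  }
  lam
}

#' Reduced prior for one switch vector
#'
#' The reduced prior equals the base prior except on switchable parameters,
#' which get mean zero and variance `gamma * lambda_k`; switched-off
#' parameters (zero variance) are point masses at zero and take the exact
#' clamp path inside [reduce_model()].
#'
#' @param space a [switch_space()].
#' @param lambda integer 0/1 vector over `space$switchable` (one row of
#'   [enumerate_switches()]).
#' @return a [gaussian_density()] reduced prior.
#' @export
prior_for_switches <- function(space, lambda) {
  stopifnot(inherits(space, "bmr_switch_space"))
  lambda <- as.integer(lambda)
  if (length(lambda) != length(space$switchable) || !all(lambda %in% 0:1))
    stop("lambda must be a 0/1 vector over the switchable indices",
         call. = FALSE)
  for (g in space$groups) {
    vals <- lambda[match(g, space$switchable)]
    if (length(unique(vals)) > 1L)
      stop("lambda violates a constraint group", call. = FALSE)
  }
  S <- space$base_prior$cov
  m <- space$base_prior$mean
  sw <- space$switchable
  S[sw, ] <- 0
  S[, sw] <- 0
  diag(S)[sw] <- space$gamma * lambda
  m[sw] <- 0
  gaussian_density(m, covariance = S, labels = space$base_prior$labels)
}
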