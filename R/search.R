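#' @rdname exhaustive_search
#' @export
search_result <- function(switch_vectors, delta_f, space, full, meta = list()) {
  probs <- model_posterior(delta_f)
  best <- .best_model_index(switch_vectors, delta_f)
  best_red <- reduce_model(full, prior_for_switches(space,
                                                    switch_vectors[best, ]))
  structure(list(switch_vectors = switch_vectors, delta_f = delta_f,
                 posterior_probs = probs, best_index = best,
                 best_reduced = best_red, space = space, meta = meta),
            class = "bmr_search")
}

# ties broken toward parsimony (fewest ON switches), then enumeration order
.best_model_index <- function(switch_vectors, delta_f) {
  mx <- max(delta_f)
  tie <- which(delta_f >= mx - 1e-12 * max(1, abs(mx)))
  if (length(tie) > 1L) {
    non <- rowSums(switch_vectors[tie, , drop = FALSE])
    tie <- tie[non == min(non)]
  }
  tie[1L]
}

#' @export
print.bmr_search <- function(x, ...) {
  cat(sprintf("Model search over %d models\n", length(x$delta_f)))
  b <- x$best_index
  cat(sprintf("best model #%d: delta F = %.4f, posterior prob = %.4f\n",
              b, x$delta_f[b], x$posterior_probs[b]))
  on <- x$space$switchable[x$switch_vectors[b, ] == 1L]
  cat("switched on:", if (length(on)) paste(on, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Exhaustive post-hoc search over a discrete model space
#'
#' Scores every model of a [switch_space()] by the closed-form reduced free
#' energy, using the posterior of a single full-model inversion. The
#' per-model computation partitions the parameters into the switched-off
#' block (an exact Savage-Dickey clamp at zero) and the remaining block
#' (analytic reduction), with the full model's factorizations precomputed
#' once; results are identical to calling [reduce_model()] model by model.
#'
#' @param full a [full_model()].
#' @param space a [switch_space()] built on `full$prior`.
#' @param max_free cap on free switches (default 24) passed to
#'   [enumerate_switches()].
#'
#' @return An object of class `bmr_search` with `switch_vectors` (one row per
#'   model, enumeration order), `delta_f`, `posterior_probs`
#'   (= [model_posterior()] of `delta_f`), `best_index` (maximal `delta_f`;
#'   ties broken toward fewer switched-on parameters, then lexicographic) and
#'   `best_reduced` (the winning [reduce_model()] result).
#' @examples
#' pr <- gaussian_density(rep(0, 2), covariance = diag(8, 2))
#' po <- gaussian_density(c(2, 0.05), covariance = diag(0.1, 2))
#' fm <- full_model(pr, po)
#' exhaustive_search(fm, switch_space(pr, 1:2, gamma = 8))
#' @export
exhaustive_search <- function(full, space, max_free = 24L) {
  stopifnot(inherits(full, "bmr_full_model"),
            inherits(space, "bmr_switch_space"))
  if (space$n_params != length(full$prior$mean))
    stop("space and full model dimensions differ", call. = FALSE)
  lam <- enumerate_switches(space, max_free = max_free)
  delta <- .score_switch_models(full, space, lam)
  search_result(lam, delta, space, full)
}

# Vector of delta_f for a matrix of switch vectors (rows), sharing all
# full-model factorizations across models.
.score_switch_models <- function(full, space, lam) {
  d <- space$n_params
  sw <- space$switchable
  nonsw <- setdiff(seq_len(d), sw)
  mu <- full$posterior$mean; P <- full$posterior$prec
  Cpost <- full$posterior$cov
  etaF <- full$prior$mean; PiF <- full$prior$prec; Sprior <- full$prior$cov
  # reduced-prior statistics shared across models
  etaR <- etaF; etaR[sw] <- 0
  PiR <- matrix(0, d, d)
  if (length(nonsw)) {
    Snn <- Sprior[nonsw, nonsw, drop = FALSE]
    fx <- full$prior$fixed[nonsw]
    if (any(!fx)) {
      ii <- nonsw[!fx]
      PiR[ii, ii] <- chol2inv(chol(Sprior[ii, ii, drop = FALSE]))
    }
  }
  diag(PiR)[sw] <- 1 / space$gamma
  excl <- which(full$prior$fixed)

  n <- nrow(lam)
  delta <- numeric(n)
  for (m in seq_len(n)) {
    off <- sw[lam[m, ] == 0L]
    fidx <- setdiff(seq_len(d), c(off, excl))
    out <- .reduce_partitioned(mu = mu, P = P, Cpost = Cpost,
                               etaF = etaF, PiF = PiF, Sprior = Sprior,
                               etaR = etaR, PiR = PiR,
                               excl = excl, cidx = off,
                               v = rep(0, length(off)), fidx = fidx,
                               tol = 1e-8)
    delta[m] <- out$delta_f
  }
  delta
}

#' Greedy search for very large discrete model spaces
#'
#' When exhaustive enumeration is infeasible, parameters (or constraint
#' groups) are removed iteratively: groups are ranked by the free-energy
#' change of switching each group off alone (the ones whose removal costs
#' least evidence first), the `block_size` weakest groups are searched
#' exhaustively (all \eqn{2^{block\_size}} submodels, every other active
#' group on), groups switched off in the winning submodel are removed
#' permanently, and the procedure repeats until no group is removed or all
#' groups have been considered.
#'
#' @param full a [full_model()].
#' @param space a [switch_space()].
#' @param block_size number of groups searched exhaustively per sweep
#'   (max 16).
#' @return A `bmr_search` object over all distinct submodels evaluated, with
#'   the greedy winner as `best_index` and the per-sweep trajectory in
#'   `meta$trajectory`.
#' @export
greedy_search <- function(full, space, block_size = 8L) {
  stopifnot(inherits(full, "bmr_full_model"),
            inherits(space, "bmr_switch_space"))
  block_size <- as.integer(block_size)
  if (block_size < 1L || block_size > 16L)
    stop("block_size must be between 1 and 16", call. = FALSE)
  groups <- space$groups
  K <- length(groups)
  active <- rep(TRUE, K)
  considered <- rep(FALSE, K)
  trajectory <- list()

  lam_for <- function(on_groups) {
    lam <- integer(length(space$switchable))
    for (k in which(on_groups))
      lam[match(groups[[k]], space$switchable)] <- 1L
    lam
  }
  seen <- new.env(parent = emptyenv())
  all_lam <- list(); all_delta <- numeric(0)
  note <- function(lam, delta) {
    key <- paste(lam, collapse = "")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      all_lam[[length(all_lam) + 1L]] <<- lam
      all_delta[length(all_delta) + 1L] <<- delta
    }
  }

  repeat {
    cand <- which(active & !considered)
    if (!length(cand)) break
    # rank candidates by the cost of switching each off alone
    on_now <- active
    single <- vapply(cand, function(k) {
      og <- on_now; og[k] <- FALSE
      lam <- lam_for(og)
      .score_switch_models(full, space, matrix(lam, nrow = 1))
    }, numeric(1))
    ord <- cand[order(single, decreasing = TRUE)]
    block <- ord[seq_len(min(block_size, length(ord)))]
    # exhaustive over the block, everything else at its current state
    b <- length(block)
    nsub <- 2^b
    sub_lam <- matrix(0L, nsub, length(space$switchable))
    sub_delta <- numeric(nsub)
    for (s in seq_len(nsub)) {
      bits <- as.integer(((s - 1L) %/% 2^(b - seq_len(b))) %% 2L)
      og <- active
      og[block] <- bits == 1L
      lam <- lam_for(og)
      sub_lam[s, ] <- lam
      sub_delta[s] <- .score_switch_models(full, space,
                                           matrix(lam, nrow = 1))
      note(lam, sub_delta[s])
    }
    win <- .best_model_index(sub_lam, sub_delta)
    bits_win <- sub_lam[win, ]
    off_groups <- block[vapply(block, function(k) {
      all(bits_win[match(groups[[k]], space$switchable)] == 0L)
    }, logical(1))]
    trajectory[[length(trajectory) + 1L]] <-
      list(block = block, removed = off_groups, delta_f = sub_delta[win])
    considered[block] <- TRUE
    if (length(off_groups)) active[off_groups] <- FALSE else break
  }
  lam_final <- lam_for(active)
  note(lam_final,
       .score_switch_models(full, space, matrix(lam_final, nrow = 1)))
  lam_mat <- do.call(rbind, all_lam)
  colnames(lam_mat) <- as.character(space$switchable)
  search_result(lam_mat, all_delta, space, full,
                meta = list(trajectory = trajectory,
                            final_lambda = lam_final))
}
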