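#' Cross-Entropy Monte Carlo parameters
#'
#' Tuning parameters of the Cross-Entropy permutation optimizer, mirroring the
#' documented defaults of the rank-aggregation literature: a Monte Carlo
#' sample of `10 k^2` permutations per iteration for `k` items, elite fraction
#' `rho = 0.1`, smoothing weight `w = 0.25` on the previous probability
#' matrix, and convergence after 7 iterations without improvement.
#'
#' @param sample_size Permutations sampled per iteration (`NULL`: `10 k^2`).
#' @param rho Elite (rarity) fraction in (0, 1).
#' @param w Smoothing weight on the previous probability matrix, in `[0, 1)`.
#' @param max_iter Iteration cap.
#' @param converged_after Stop after this many iterations without objective
#'   improvement.
#' @return A list of class `"ce_params"`.
#' @export
ce_params <- function(sample_size = NULL, rho = 0.1, w = 0.25,
                      max_iter = 1000, converged_after = 7) {
  stopifnot(rho > 0, rho < 1, w >= 0, w < 1, max_iter >= 1,
            converged_after >= 1)
  structure(list(sample_size = sample_size, rho = rho, w = w,
                 max_iter = max_iter, converged_after = converged_after),
            class = "ce_params")
}

#' Consensus ranking by Cross-Entropy Monte Carlo
#'
#' Heuristic minimizer of the summed (weighted) Spearman footrule objective
#' for problems too large for exhaustive search. The optimizer maintains a
#' k x k item-by-position probability matrix, initially uniform. Each
#' iteration samples `N` permutations position by position without
#' replacement, with items drawn proportionally to the matrix column; scores
#' them; takes the best `ceiling(rho * N)` (the elite set); re-estimates the
#' matrix from the elites' empirical item-position frequencies; and blends it
#' with the previous matrix using smoothing weight `w` (which also keeps every
#' probability positive, so no column can degenerate). Iterations stop after
#' `converged_after` rounds without improvement of the best objective seen, or
#' at `max_iter`. Results are fully reproducible given `seed`.
#'
#' @inheritParams footrule_cost
#' @param params A [ce_params()] object.
#' @param seed Integer seed for the sampler.
#' @return A list of class `"consensus"`: `consensus`, `objective`,
#'   `optimizer = "cemc"`, `per_list`, `seed`, and `trace` (best objective
#'   after each iteration, non-increasing).
#' @export
aggregate_cemc <- function(lists, weights = rep(1, length(lists)),
                           params = ce_params(), seed = 1L) {
  cost <- footrule_cost(lists, weights)
  k <- nrow(cost)
  if (k < 3) stop("Cross-Entropy aggregation requires at least 3 items")
  items <- rownames(cost)
  N <- if (is.null(params$sample_size)) 10L * k^2 else params$sample_size
  n_elite <- ceiling(params$rho * N)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  prob <- matrix(1 / k, k, k)
  best_obj <- Inf
  best_perm <- NULL
  trace <- numeric()
  stall <- 0L
  for (iter in seq_len(params$max_iter)) {
    # sample N permutations in parallel via the Gumbel-max trick:
    # at each position, argmax over still-available items of
    # log(prob) + Gumbel noise is a draw proportional to prob
    perms <- matrix(0L, N, k)
    avail <- matrix(TRUE, N, k)
    for (j in seq_len(k)) {
      g <- -log(-log(matrix(stats::runif(N * k), N, k)))
      score <- matrix(log(prob[, j]), N, k, byrow = TRUE) + g
      score[!avail] <- -Inf
      pick <- max.col(score, ties.method = "first")
      perms[, j] <- pick
      avail[cbind(seq_len(N), pick)] <- FALSE
    }
    obj <- numeric(N)
    for (j in seq_len(k)) obj <- obj + cost[cbind(perms[, j], j)]
    ord <- order(obj)
    elite <- perms[ord[seq_len(n_elite)], , drop = FALSE]
    if (obj[ord[1]] < best_obj) {
      best_obj <- obj[ord[1]]
      best_perm <- perms[ord[1], ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, best_obj)
    freq <- matrix(0, k, k)
    for (j in seq_len(k)) {
      tab <- tabulate(elite[, j], nbins = k)
      freq[, j] <- tab / n_elite
    }
    prob <- params$w * prob + (1 - params$w) * freq
    if (stall >= params$converged_after) break
  }
  structure(list(consensus = items[best_perm], objective = best_obj,
                 optimizer = "cemc",
                 per_list = vapply(lists, footrule_distance, 0, b = items[best_perm]),
                 seed = as.integer(seed), trace = trace,
                 iterations = length(trace)),
            class = "consensus")
}
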