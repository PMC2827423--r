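#' Spearman footrule distance between two rankings
#'
#' The footrule distance between two full rankings of the same items is the
#' sum over items of the absolute difference of their (1-based) rank
#' positions. It is a metric on permutations, symmetric, zero only for
#' identical lists, always even, and maximal at `2 * floor(k^2 / 4)` for a
#' list against its reversal.
#'
#' @param a,b Character vectors: full rankings (best first) of the same item
#'   set, without ties or omissions.
#' @return A non-negative integer.
#' @export
#' @examples
#' footrule_distance(c("A", "B", "C"), c("C", "B", "A"))  # 4
footrule_distance <- function(a, b) {
  if (anyDuplicated(a) || anyDuplicated(b) || !setequal(a, b) ||
      length(a) != length(b)) {
    stop("inputs must be permutations of the same item set; difference: ",
         paste(union(setdiff(a, b), setdiff(b, a)), collapse = ", "))
  }
  sum(abs(seq_along(a) - match(a, b)))
}

#' Footrule cost matrix of an aggregation problem
#'
#' The summed weighted footrule objective decomposes over (item, position)
#' pairs, which reduces consensus search to a linear assignment problem:
#' `cost[item, pos] = sum over lists of weight * |pos - rank_list(item)|`.
#'
#' @param lists List of character rankings (each a permutation of the same
#'   items, best first).
#' @param weights Non-negative per-list weights, default all 1 (unweighted).
#' @return A k x k matrix with items as rows (alphabetical) and positions as
#'   columns.
#' @export
footrule_cost <- function(lists, weights = rep(1, length(lists))) {
  stopifnot(length(lists) >= 2, length(weights) == length(lists),
            all(weights >= 0))
  items <- sort(lists[[1]])
  for (l in lists) {
    if (anyDuplicated(l) || !setequal(l, items)) {
      stop("all lists must be full permutations of the same item set")
    }
  }
  k <- length(items)
  cost <- matrix(0, k, k, dimnames = list(items, NULL))
  for (i in seq_along(lists)) {
    r <- match(items, lists[[i]])
    cost <- cost + weights[i] * abs(outer(r, seq_len(k), "-"))
  }
  cost
}

#' Exact consensus ranking under the Spearman footrule
#'
#' Finds the consensus ordering minimizing the summed (weighted) footrule
#' distance to a set of input rankings. Two exact routes are provided:
#' exhaustive enumeration of all `k!` permutations (refused for `k > 10`),
#' and reduction to a k x k linear assignment problem solved by the Hungarian
#' algorithm, which scales far beyond that. Ties in the objective are broken
#' by lexicographic order of the consensus permutation (by item label), so
#' both routes return the identical, deterministic answer.
#'
#' @inheritParams footrule_cost
#' @param method `"assignment"` (default), `"exhaustive"`, or `"both"` (run
#'   both and verify they agree — useful as a self-check).
#' @return A list of class `"consensus"`: `consensus` (character vector, best
#'   first), `objective`, `optimizer`, and `per_list` (footrule distance of
#'   the consensus to each input list).
#' @export
aggregate_exact <- function(lists, weights = rep(1, length(lists)),
                            method = c("assignment", "exhaustive", "both")) {
  method <- match.arg(method)
  cost <- footrule_cost(lists, weights)
  k <- nrow(cost)
  items <- rownames(cost)

  solve_exh <- function() {
    if (k > 10) {
      stop("exhaustive search is limited to 10 items (", k,
           " given); use method = 'assignment' or aggregate_cemc()")
    }
    perms <- .all_perms(k)  # rows in lexicographic order of item indices
    obj <- numeric(nrow(perms))
    for (j in seq_len(k)) obj <- obj + cost[cbind(perms[, j], j)]
    best <- which.min(obj)  # first minimum = lexicographically smallest
    list(consensus = items[perms[best, ]], objective = obj[best])
  }
  solve_asg <- function() {
    sol <- .hungarian(cost)
    z <- sum(cost[cbind(sol, seq_len(k))])
    # lexicographic refinement: fix positions left to right with the
    # alphabetically first item that preserves global optimality
    fixed <- integer(0)
    for (pos in seq_len(k)) {
      cand <- setdiff(seq_len(k), fixed)
      for (it in cand) {
        sub <- cost[setdiff(seq_len(k), c(fixed, it)),
                    setdiff(seq_len(k), seq_len(pos)), drop = FALSE]
        head_cost <- sum(cost[cbind(c(fixed, it), seq_len(pos))])
        tail_cost <- if (nrow(sub) == 0) 0 else {
          ssol <- .hungarian(sub)
          sum(sub[cbind(ssol, seq_len(ncol(sub)))])
        }
        if (head_cost + tail_cost <= z + 1e-9) {
          fixed <- c(fixed, it)
          break
        }
      }
    }
    list(consensus = items[fixed], objective = z)
  }

  sol <- switch(method,
                exhaustive = solve_exh(),
                assignment = solve_asg(),
                both = {
                  s1 <- solve_exh(); s2 <- solve_asg()
                  if (abs(s1$objective - s2$objective) > 1e-9 ||
                      !identical(s1$consensus, s2$consensus)) {
                    stop("internal error: enumeration and assignment solvers disagree")
                  }
                  s1
                })
  structure(list(consensus = sol$consensus, objective = sol$objective,
                 optimizer = method,
                 per_list = vapply(lists, footrule_distance, 0, b = sol$consensus)),
            class = "consensus")
}

#' @export
print.consensus <- function(x, ...) {
  cat(sprintf("Consensus ranking (%s optimizer), footrule objective %.4g:\n",
              x$optimizer, x$objective))
  cat(" ", paste(x$consensus, collapse = " > "), "\n")
  invisible(x)
}

# all permutations of 1..n as an n! x n integer matrix, rows in
# lexicographic order (so the first minimizer found is the lexicographic one)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  blocks <- lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  })
  do.call(rbind, blocks)
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting path,
# O(n^3)); returns row index assigned to each column, minimizing total cost.
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L               # index 1 plays the role of the virtual column 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          u[p[j] + 1] <- u[p[j] + 1] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  assignment <- integer(n)
  assignment[1:n] <- p[2:(n + 1)]
  assignment
}

#' Read rank lists from a CSV
#'
#' Reads a table shaped like a published ranking table: rows are rank
#' positions (best first), columns are ranking methods, cells are item
#' labels. An optional `position` column is ignored.
#'
#' @param path CSV path.
#' @return A named list of character rankings.
#' @export
read_rank_lists <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[, setdiff(names(d), c("position", "rank")), drop = FALSE]
  lists <- lapply(d, as.character)
  items <- sort(lists[[1]])
  for (nm in names(lists)) {
    if (anyDuplicated(lists[[nm]]) || !setequal(lists[[nm]], items)) {
      stop("column '", nm, "' is not a permutation of the common item set")
    }
  }
  lists
}

#' Published Petunia reference-gene rankings
#'
#' Stability rankings of nine candidate reference genes (ACT, CYP, EF1a,
#' GAPDH, RAN1, RPS13, SAND, TUB, UBQ) in two Petunia hybrida lines (Mitchell
#' and V30) produced by five methods — NormFinder, BestKeeper, the qBase M
#' and CV statistics, and stepwise geNorm M — as published for a flower and
#' leaf development study. These five full rankings per line are the standard
#' worked example for consensus aggregation.
#'
#' @param line `"Mitchell"` or `"V30"`.
#' @return A named list of five character rankings (best first).
#' @export
petunia_rankings <- function(line = c("Mitchell", "V30")) {
  line <- match.arg(line)
  path <- system.file("extdata", "petunia_rankings.csv", package = "refstab",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[d$line == line, setdiff(names(d), c("line", "position")), drop = FALSE]
  lapply(d, as.character)
}
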