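#' Non-parametric group-difference testing cascade
#'
#' For each gene, runs the testing cascade used to screen candidate reference
#' genes for expression differences between sample groups (developmental
#' stages): per-group Shapiro-Wilk normality checks, a Kruskal-Wallis omnibus
#' test across all groups (with tie correction), and — only when the omnibus
#' test is significant — all pairwise two-sided Wilcoxon rank-sum tests with
#' Bonferroni correction. The rank-sum tests use the exact null distribution
#' when both group sizes are at most 10 (ties force the normal approximation
#' with continuity correction), and the Bonferroni factor is the number of
#' pairs actually tested, capped so adjusted p-values never exceed 1.
#'
#' The non-parametric branch is always computed regardless of the normality
#' outcome: the Shapiro-Wilk p-values are reported for inspection only. A
#' parametric (ANOVA) branch is deliberately not provided.
#'
#' @param cm A `"ct_matrix"` (observations are the technical-replicate-
#'   averaged CTs, one per biological replicate) or a plain genes x samples
#'   matrix.
#' @param groups Group label per sample; defaults to the `groups` element of
#'   `cm`.
#' @param alpha Significance level, default 0.05.
#' @return A list of class `"group_tests"`, one element per gene, each a list
#'   with `shapiro_p` (named per-group vector, `NA` where not computable),
#'   `kruskal_stat`, `kruskal_p`, `pairwise_p` (symmetric matrix of adjusted
#'   p-values, `NULL` when the omnibus test was not significant), and
#'   `significant_pairs` (two-column matrix of group labels).
#' @export
compare_groups <- function(cm, groups = NULL, alpha = 0.05) {
  m <- if (inherits(cm, "ct_matrix")) cm$ct else cm
  if (is.null(groups) && inherits(cm, "ct_matrix")) groups <- cm$groups
  stopifnot(is.matrix(m), length(groups) == ncol(m), alpha > 0, alpha < 1)
  groups <- as.character(groups)
  glev <- unique(groups)
  if (length(glev) < 2) stop("at least 2 groups are required")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  pairs <- utils::combn(glev, 2)

  res <- lapply(rownames(m), function(gene) {
    x <- m[gene, ]
    shapiro_p <- vapply(glev, function(g) {
      xi <- x[groups == g]
      if (length(xi) < 3 || stats::sd(xi) == 0) return(NA_real_)
      stats::shapiro.test(xi)$p.value
    }, 0)
    kw <- stats::kruskal.test(x, factor(groups, levels = glev))
    pairwise_p <- NULL
    sig <- matrix(character(), 0, 2)
    if (is.finite(kw$p.value) && kw$p.value < alpha) {
      n_pairs <- ncol(pairs)
      pairwise_p <- matrix(NA_real_, length(glev), length(glev),
                           dimnames = list(glev, glev))
      for (p in seq_len(n_pairs)) {
        a <- x[groups == pairs[1, p]]
        b <- x[groups == pairs[2, p]]
        exact <- length(a) <= 10 && length(b) <= 10
        raw <- suppressWarnings(
          stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
        adj <- min(1, raw * n_pairs)
        pairwise_p[pairs[1, p], pairs[2, p]] <- adj
        pairwise_p[pairs[2, p], pairs[1, p]] <- adj
      }
      hit <- which(upper.tri(pairwise_p) & pairwise_p < alpha, arr.ind = TRUE)
      sig <- cbind(glev[hit[, 1]], glev[hit[, 2]])
    }
    list(shapiro_p = shapiro_p, kruskal_stat = unname(kw$statistic),
         kruskal_p = kw$p.value, pairwise_p = pairwise_p,
         significant_pairs = sig)
  })
  names(res) <- rownames(m)
  structure(res, alpha = alpha, class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("Group-difference cascade (alpha = %.2f):\n", alpha))
  for (gene in names(x)) {
    r <- x[[gene]]
    n_sig <- nrow(r$significant_pairs)
    cat(sprintf("  %-8s Kruskal-Wallis p = %.4g; %d significant pair(s)\n",
                gene, r$kruskal_p, n_sig))
  }
  invisible(x)
}

#' Flatten group-test results to a long table
#'
#' @param x A `"group_tests"` object.
#' @return A `data.frame` with one row per gene and tested group pair:
#'   columns `gene`, `group_a`, `group_b`, `adj_p`, `significant`. Genes whose
#'   omnibus test was not significant contribute no rows.
#' @export
group_tests_table <- function(x) {
  alpha <- attr(x, "alpha")
  rows <- lapply(names(x), function(gene) {
    pw <- x[[gene]]$pairwise_p
    if (is.null(pw)) return(NULL)
    idx <- which(upper.tri(pw), arr.ind = TRUE)
    data.frame(gene = gene,
               group_a = rownames(pw)[idx[, 1]],
               group_b = colnames(pw)[idx[, 2]],
               adj_p = pw[idx],
               significant = pw[idx] < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), group_a = character(),
                      group_b = character(), adj_p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  }
  out
}
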