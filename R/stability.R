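#' geNorm expression-stability measure M
#'
#' For each gene in the panel, M is the average pairwise variation of that
#' gene with all other panel genes: for genes *j*, *k* the pairwise variation
#' `V(j,k)` is the standard deviation (n-1 denominator) over samples of the
#' log2 expression ratio `log2(rq_j / rq_k)`, and `M(j)` is the mean of
#' `V(j,k)` over all partners `k != j`. Lower M means more stable expression.
#' Because M is built from log ratios it is invariant to rescaling any gene's
#' RQ column by a positive constant.
#'
#' @param rq An `"rq_matrix"` from [compute_rq()], or a plain positive
#'   genes x samples matrix.
#' @param panel Optional character vector restricting the panel; default all
#'   genes.
#' @return Named numeric vector of M values (one per panel gene).
#' @references Vandesompele, J. et al. (2002) Accurate normalization of
#'   real-time quantitative RT-PCR data by geometric averaging of multiple
#'   internal control genes. Genome Biology 3, research0034.
#' @export
genorm_m <- function(rq, panel = NULL) {
  m <- .rq_mat(rq)
  if (!is.null(panel)) {
    stopifnot(all(panel %in% rownames(m)))
    m <- m[panel, , drop = FALSE]
  }
  k <- nrow(m)
  if (k < 2) stop("geNorm M requires a panel of at least 2 genes")
  lm2 <- log2(m)
  v <- matrix(0, k, k)
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      v[j, l] <- v[l, j] <- stats::sd(lm2[j, ] - lm2[l, ])
    }
  }
  out <- rowSums(v) / (k - 1)
  names(out) <- rownames(m)
  out
}

.rq_mat <- function(rq) {
  m <- if (inherits(rq, "rq_matrix")) rq$rq else rq
  stopifnot(is.matrix(m), all(m > 0), !is.null(rownames(m)))
  m
}

#' geNorm stepwise exclusion ranking
#'
#' Repeatedly computes [genorm_m()] on the remaining panel and removes the
#' gene with the highest M (least stable) until two genes remain; those two
#' cannot be distinguished by the pairwise measure and share the top of the
#' ranking. Ties at the argmax are broken alphabetically (the alphabetically
#' first tied gene is excluded) and recorded in the trace.
#'
#' @inheritParams genorm_m
#' @return A list of class `"genorm_ranking"` with elements `ranking`
#'   (character vector, most to least stable; the final indistinguishable pair
#'   is listed alphabetically in positions 1-2), `m` (named vector: for
#'   excluded genes the panel M at exclusion, for the final pair their shared
#'   final M), `trace` (list of steps, each with `excluded`, `m_values`,
#'   `tie`), and `final_pair`.
#' @export
genorm_stepwise <- function(rq) {
  m <- .rq_mat(rq)
  if (nrow(m) < 3) stop("stepwise exclusion requires at least 3 genes")
  remaining <- rownames(m)
  excluded <- character()
  m_at_exclusion <- numeric()
  trace <- list()
  while (length(remaining) > 2) {
    mv <- genorm_m(m, panel = remaining)
    worst_m <- max(mv)
    tied <- sort(names(mv)[mv == worst_m])
    worst <- tied[1]
    trace[[length(trace) + 1]] <- list(excluded = worst, m_values = mv,
                                       tie = length(tied) > 1)
    excluded <- c(excluded, worst)
    m_at_exclusion <- c(m_at_exclusion, worst_m)
    remaining <- setdiff(remaining, worst)
  }
  final_pair <- sort(remaining)
  final_m <- genorm_m(m, panel = final_pair)
  ranking <- c(final_pair, rev(excluded))
  mvals <- c(final_m, rev(m_at_exclusion))
  names(mvals) <- ranking
  structure(list(ranking = ranking, m = mvals, trace = trace,
                 final_pair = final_pair),
            class = "genorm_ranking")
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("geNorm stepwise ranking (most to least stable):\n")
  print(round(x$m, 4))
  invisible(x)
}

#' geNorm pairwise variation V(n/n+1)
#'
#' Determines how many reference genes a normalization factor (NF) needs.
#' `NF_n(s)` is the geometric mean of the RQs of the `n` top-ranked genes in
#' sample `s`; `V(n/n+1)` is the standard deviation over samples of
#' `log2(NF_n / NF_{n+1})`, the effect of adding the (n+1)-th gene. The
#' smallest `n` with `V(n/n+1)` below the cutoff (conventionally 0.15) is the
#' recommended number of genes; below the cutoff additional genes are
#' considered not to improve normalization.
#'
#' @inheritParams genorm_m
#' @param ranking Character vector of genes from most to least stable,
#'   typically `genorm_stepwise(rq)$ranking`.
#' @param cutoff Pairwise-variation cutoff, default 0.15.
#' @return A list of class `"pairwise_variation"`: `v` (named vector,
#'   `"2/3"`, `"3/4"`, ...), `recommended_n` (integer, or `NA` with
#'   `not_reached = TRUE` when no V falls below the cutoff), `cutoff`.
#' @export
pairwise_variation <- function(rq, ranking = NULL, cutoff = 0.15) {
  m <- .rq_mat(rq)
  if (is.null(ranking)) ranking <- genorm_stepwise(m)$ranking
  stopifnot(setequal(ranking, rownames(m)))
  g <- length(ranking)
  if (g < 3) stop("pairwise variation requires at least 3 genes")
  lm2 <- log2(m[ranking, , drop = FALSE])
  # log2 NF_n = column mean of the first n rows
  v <- numeric(g - 2)
  for (n in 2:(g - 1)) {
    lnf_n <- colMeans(lm2[1:n, , drop = FALSE])
    lnf_n1 <- colMeans(lm2[1:(n + 1), , drop = FALSE])
    v[n - 1] <- stats::sd(lnf_n - lnf_n1)
  }
  names(v) <- paste(2:(g - 1), 3:g, sep = "/")
  hit <- which(v < cutoff)
  recommended_n <- if (length(hit) > 0) unname(hit[1]) + 1L else NA_integer_
  structure(list(v = v, recommended_n = recommended_n,
                 not_reached = length(hit) == 0, cutoff = cutoff),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("Pairwise variation V(n/n+1):\n")
  print(round(x$v, 4))
  if (x$not_reached) {
    cat(sprintf("no V below the %.2f cutoff; more genes than tested may be needed\n",
                x$cutoff))
  } else {
    cat(sprintf("recommended number of reference genes: %d (cutoff %.2f)\n",
                x$recommended_n, x$cutoff))
  }
  invisible(x)
}

#' qBase-style M value and coefficient of variation
#'
#' The qBase variant of the stability analysis computes M on the full panel
#' without any stepwise exclusion, plus a coefficient of variation for each
#' gene: the gene's RQs are normalized by the per-sample geometric mean of all
#' panel genes (the whole-panel normalization factor, the gene itself
#' included), and `CV = sd / mean` of these normalized relative quantities
#' over samples. Both statistics are lower for more stably expressed genes.
#'
#' @inheritParams genorm_m
#' @return A list with named numeric vectors `m` and `cv`.
#' @references Hellemans, J. et al. (2007) qBase relative quantification
#'   framework and software for management and automated analysis of
#'   real-time quantitative PCR data. Genome Biology 8, R19.
#' @export
qbase_m_cv <- function(rq) {
  m <- .rq_mat(rq)
  if (nrow(m) < 2) stop("qBase statistics require at least 2 genes")
  nf <- exp(colMeans(log(m)))  # geometric mean over all panel genes
  nrq <- sweep(m, 2, nf, "/")
  cv <- apply(nrq, 1, function(x) stats::sd(x) / mean(x))
  list(m = genorm_m(m), cv = cv)
}

#' BestKeeper index and per-gene correlation
#'
#' The BestKeeper index merges all candidate genes into one per-sample
#' normalization factor: the geometric mean of their CT values (the gene under
#' evaluation included). Each gene's stability is then read as the coefficient
#' of determination r^2 of its CTs against the index (Pearson correlation over
#' samples); higher r^2 means the gene tracks the common signal more
#' faithfully and is more suitable. A gene with zero CT variance has an
#' undefined correlation; it is reported as `NA` and ranked last with a
#' warning.
#'
#' @param cm A `"ct_matrix"` from [average_replicates()], or a plain positive
#'   genes x samples matrix of CT values.
#' @return A list of class `"bestkeeper"`: `index` (per-sample geometric mean
#'   CT), `r` and `r2` (named per-gene vectors).
#' @references Pfaffl, M.W. et al. (2004) Determination of stable housekeeping
#'   genes, differentially regulated target genes and sample integrity:
#'   BestKeeper. Biotechnology Letters 26, 509-515.
#' @export
bestkeeper <- function(cm) {
  m <- if (inherits(cm, "ct_matrix")) cm$ct else cm
  stopifnot(is.matrix(m), all(m > 0), nrow(m) >= 2)
  index <- exp(colMeans(log(m)))
  r <- apply(m, 1, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, index)
  })
  if (anyNA(r)) {
    warning("gene(s) with zero CT variance, correlation undefined: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  }
  structure(list(index = index, r = r, r2 = r^2), class = "bestkeeper")
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat("BestKeeper coefficients of determination (higher is more stable):\n")
  print(round(sort(x$r2, decreasing = TRUE), 4))
  invisible(x)
}

#' NormFinder model-based stability value
#'
#' Fits the variance-components model behind NormFinder: log-scale expression
#' `y(i, j, g)` for gene `i`, sample `j` in group `g` is decomposed into an
#' intergroup difference `d(i, g)` and an intragroup variance
#' `sigma^2(i, g)`, both estimated after centring each sample on its
#' gene-panel mean (which removes sample-specific loading). The intragroup
#' variance estimate is corrected for the centring-induced coupling between
#' genes,
#' `sigma2(i,g) = max(0, I/(I-2) * (v(i,g) - sum(v(.,g)) / (I (I-1))))`,
#' with `v(i,g)` the sample variance of centred values and `I` the number of
#' genes. Estimated intergroup differences are shrunk toward zero by an
#' empirical-Bayes factor `gamma2 / (gamma2 + sigma2/n_g)` where `gamma2` is
#' the excess of the mean squared difference over its sampling variance
#' (disable with `shrink = FALSE` to cross-check simpler reimplementations).
#' The stability value is the average over groups of
#' `|d_shrunk| + sqrt(sigma2 / n_g)`; lower means more stable. With one group
#' the intergroup terms vanish and genes are ranked by intragroup standard
#' error alone.
#'
#' @param y Genes x samples matrix of log2-scale expression (e.g.
#'   `log2(rq$rq)`).
#' @param groups Group label per sample (length `ncol(y)`); each group needs
#'   at least 2 samples.
#' @param shrink Apply intergroup-difference shrinkage (default `TRUE`).
#' @return A list of class `"normfinder"`: `stability` (named per-gene
#'   vector, lower is more stable), `intra` (genes x groups matrix of
#'   `sigma2` estimates), `inter` (genes x groups matrix of shrunk
#'   differences), `gamma2`.
#' @references Andersen, C.L., Jensen, J.L. and Orntoft, T.F. (2004)
#'   Normalization of real-time quantitative reverse transcription-PCR data:
#'   a model-based variance estimation approach. Cancer Research 64,
#'   5245-5250.
#' @export
normfinder <- function(y, groups, shrink = TRUE) {
  stopifnot(is.matrix(y), length(groups) == ncol(y))
  I <- nrow(y)
  if (I < 3) stop("NormFinder requires at least 3 genes")
  groups <- as.character(groups)
  glev <- unique(groups)
  G <- length(glev)
  ng <- table(factor(groups, levels = glev))
  if (any(ng < 2)) stop("every group needs at least 2 samples")

  # centre each sample (column) on its gene-panel mean
  z <- sweep(y, 2, colMeans(y))

  v <- matrix(NA_real_, I, G, dimnames = list(rownames(y), glev))
  zbar <- v
  for (g in seq_along(glev)) {
    zg <- z[, groups == glev[g], drop = FALSE]
    v[, g] <- apply(zg, 1, stats::var)
    zbar[, g] <- rowMeans(zg)
  }
  sigma2 <- (I / (I - 2)) * sweep(v, 2, colSums(v) / (I * (I - 1)))
  sigma2[sigma2 < 0] <- 0
  d <- sweep(zbar, 1, rowMeans(zbar))
  n_mat <- matrix(as.numeric(ng), I, G, byrow = TRUE)

  gamma2 <- 0
  d_shrunk <- d * 0
  if (G > 1) {
    if (shrink) {
      gamma2 <- max(0, mean(d^2) - mean(sigma2 / n_mat))
      denom <- gamma2 + sigma2 / n_mat
      d_shrunk <- ifelse(denom > 0, d * gamma2 / denom, 0)
    } else {
      d_shrunk <- d
    }
  }
  stability <- rowMeans(abs(d_shrunk) + sqrt(sigma2 / n_mat))
  names(stability) <- rownames(y)
  structure(list(stability = stability, intra = sigma2, inter = d_shrunk,
                 gamma2 = gamma2, shrink = shrink),
            class = "normfinder")
}

#' @export
print.normfinder <- function(x, ...) {
  cat("NormFinder stability values (lower is more stable):\n")
  print(round(sort(x$stability), 4))
  invisible(x)
}

#' Convert per-gene statistics into a stability table
#'
#' @param statistic Named per-gene numeric vector.
#' @param method Label of the producing method.
#' @param direction `"lower_is_stable"` (M, CV, NormFinder) or
#'   `"higher_is_stable"` (BestKeeper r^2). Missing statistics rank last;
#'   ties are broken alphabetically by gene label.
#' @param ranking Optional explicit ranking overriding the statistic order
#'   (used for the stepwise geNorm ranking).
#' @return A `data.frame` of class `"stability_table"` with columns `gene`,
#'   `statistic`, `rank`, ordered most to least stable; attributes `method`
#'   and `direction`.
#' @export
stability_table <- function(statistic, method,
                            direction = c("lower_is_stable", "higher_is_stable"),
                            ranking = NULL) {
  direction <- match.arg(direction)
  genes <- names(statistic)
  if (is.null(ranking)) {
    key <- if (direction == "lower_is_stable") statistic else -statistic
    key[is.na(key)] <- Inf
    ranking <- genes[order(key, genes)]
  }
  stopifnot(setequal(ranking, genes))
  out <- data.frame(gene = ranking, statistic = unname(statistic[ranking]),
                    rank = seq_along(ranking), stringsAsFactors = FALSE)
  structure(out, method = method, direction = direction,
            class = c("stability_table", "data.frame"))
}
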