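#' Reference-gene stability analysis
#'
#' Runs the complete reference-gene validation pipeline, independently for
#' each line in the input (lines are analysed separately throughout): raw
#' curves (optional) are converted to CT values and per-well efficiencies;
#' technical replicates are quality-controlled and averaged; relative
#' quantities (RQ) are computed with efficiency correction; five stability
#' statistics are evaluated — stepwise geNorm M, qBase-style full-panel M and
#' CV, the BestKeeper index r^2 and the NormFinder variance-components value;
#' the pairwise-variation series determines the number of genes a
#' normalization factor needs; CT differences between sample groups are
#' screened with the non-parametric cascade; and the five method rankings are
#' merged into a consensus ordering under the Spearman footrule by the
#' Cross-Entropy optimizer, verified against the exact assignment solution
#' whenever the panel has at most 10 genes.
#'
#' The same stability statistics are additionally computed on sample subsets
#' (each single developmental stage, all flower stages, all leaf stages)
#' through the identical code path, provided the subset keeps at least three
#' samples.
#'
#' @param reactions A reaction `data.frame` (see [read_reactions()]) or a
#'   path to a reaction CSV. Ignored when `curves` is given.
#' @param curves Optional named list of fluorescence vectors (or a path to a
#'   curve CSV); requires `wellmap`.
#' @param wellmap Well metadata `data.frame` or CSV path (with `curves`).
#' @param control A [refstab_control()] object.
#' @param seed Integer seed for the Cross-Entropy optimizer.
#' @param subsets Compute per-stage subset statistics (default `TRUE`).
#' @return An object of class `"refstab"`: a list with one element per line
#'   (each holding `ct`, `rq`, `stability` — the five
#'   [stability_table()]s —, `pv`, `group_tests`, `rank_lists`, `consensus`,
#'   `exact`, `subsets`, `qc`) plus `control`, `seed` and `call`.
#' @seealso [summary.refstab()], [coef.refstab()], [plot.refstab()]
#' @export
#' @examples
#' spec <- simulation_spec(lines = "Mitchell")
#' study <- simulate_ct_table(spec, seed = 42)
#' fit <- refstab(study$reactions, seed = 42)
#' summary(fit)
refstab <- function(reactions = NULL, curves = NULL, wellmap = NULL,
                    control = refstab_control(), seed = 1L, subsets = TRUE) {
  cl <- match.call()
  if (!is.null(curves)) {
    if (is.character(curves)) curves <- read_curves(curves)
    if (is.character(wellmap)) wellmap <- read_wellmap(wellmap)
    if (is.null(wellmap)) stop("curves require a well map")
    reactions <- call_reactions(curves, wellmap, control)
  } else if (is.character(reactions)) {
    reactions <- read_reactions(reactions, control)
  }
  stopifnot(is.data.frame(reactions), nrow(reactions) > 0)

  lines <- unique(reactions$line)
  per_line <- lapply(lines, function(ln) {
    .refstab_line(reactions[reactions$line == ln, , drop = FALSE],
                  control, seed, subsets)
  })
  names(per_line) <- lines
  structure(list(lines = per_line, control = control, seed = as.integer(seed),
                 call = cl),
            class = "refstab")
}

.refstab_line <- function(reactions, control, seed, subsets) {
  qc <- suppressMessages(
    filter_technical_replicates(reactions, control$replicate_max_range))
  cm <- average_replicates(qc$kept, control)
  rq <- compute_rq(cm, control$global_reference)

  gn <- genorm_stepwise(rq)
  qb <- qbase_m_cv(rq)
  bk <- bestkeeper(cm)
  nf <- normfinder(log2(rq$rq), rq$groups)

  tables <- list(
    genorm_M = stability_table(gn$m, "genorm_M", "lower_is_stable",
                               ranking = gn$ranking),
    qbase_M = stability_table(qb$m, "qbase_M", "lower_is_stable"),
    qbase_CV = stability_table(qb$cv, "qbase_CV", "lower_is_stable"),
    bestkeeper_r2 = stability_table(bk$r2, "bestkeeper_r2", "higher_is_stable"),
    normfinder = stability_table(nf$stability, "normfinder", "lower_is_stable"))

  pv <- pairwise_variation(rq, gn$ranking, control$pv_cutoff)
  gt <- compare_groups(cm, alpha = control$alpha)

  rank_lists <- lapply(tables, function(t) t$gene)
  cemc <- aggregate_cemc(rank_lists, seed = seed,
                         params = if (is.null(control$ce_params)) ce_params()
                                  else control$ce_params)
  exact <- NULL
  consensus <- cemc
  if (nrow(cm$ct) <= 10) {
    exact <- aggregate_exact(rank_lists, method = "assignment")
    consensus <- exact
  }

  sub <- NULL
  if (subsets) sub <- .refstab_subsets(cm, rq, control)

  list(ct = cm, rq = rq, stability = tables, genorm = gn, normfinder = nf,
       bestkeeper = bk, pv = pv, group_tests = gt, rank_lists = rank_lists,
       consensus = consensus, cemc = cemc, exact = exact, subsets = sub,
       qc = list(kept = nrow(qc$kept), discarded = nrow(qc$discarded)))
}

.refstab_subsets <- function(cm, rq, control) {
  defs <- list()
  for (g in unique(cm$groups)) defs[[g]] <- cm$groups == g
  organs <- cm$samples$organ
  for (o in unique(organs)) {
    if (sum(organs == o) > 0 && length(unique(cm$groups[organs == o])) > 1) {
      defs[[paste0(o, ".all")]] <- organs == o
    }
  }
  lapply(defs, function(sel) {
    if (sum(sel) < 3) return(NULL)
    rq_s <- subset_samples(rq, sel)
    cm_s <- subset_samples(cm, sel)
    gn <- genorm_stepwise(rq_s)
    qb <- qbase_m_cv(rq_s)
    pv <- pairwise_variation(rq_s, gn$ranking, control$pv_cutoff)
    list(best_pair = gn$final_pair, genorm_m = gn$m, qbase_m = qb$m,
         qbase_cv = qb$cv, recommended_n = pv$recommended_n, pv = pv$v)
  })
}

#' @export
print.refstab <- function(x, ...) {
  cat("Reference-gene stability analysis\n")
  for (ln in names(x$lines)) {
    l <- x$lines[[ln]]
    cat(sprintf("\nLine %s: %d genes, %d samples, %d reactions kept (%d discarded)\n",
                ln, nrow(l$ct$ct), ncol(l$ct$ct), l$qc$kept, l$qc$discarded))
    cat(sprintf("  consensus (%s): %s\n", l$consensus$optimizer,
                paste(l$consensus$consensus, collapse = " > ")))
  }
  invisible(x)
}

#' Summarise a reference-gene stability analysis
#'
#' @param object A `"refstab"` fit.
#' @param ... Unused.
#' @return A list of class `"summary.refstab"` with, per line, the combined
#'   per-gene statistic table (genes x methods), the method rankings, the
#'   pairwise-variation series with the recommended gene number, the number
#'   of significant group pairs per gene, and the consensus ordering.
#' @export
summary.refstab <- function(object, ...) {
  out <- lapply(object$lines, function(l) {
    stats_mat <- coef_line(l)
    ranks <- vapply(l$stability, function(t) t$gene, character(nrow(stats_mat)))
    sig <- vapply(l$group_tests, function(g) nrow(g$significant_pairs), 0L)
    list(statistics = stats_mat, rankings = ranks, pv = l$pv,
         significant_pairs = sig, consensus = l$consensus)
  })
  structure(list(lines = out, seed = object$seed), class = "summary.refstab")
}

coef_line <- function(l) {
  genes <- sort(l$stability[[1]]$gene)
  vapply(l$stability, function(t) {
    stats::setNames(t$statistic, t$gene)[genes]
  }, stats::setNames(numeric(length(genes)), genes))
}

#' @export
print.summary.refstab <- function(x, ...) {
  for (ln in names(x$lines)) {
    l <- x$lines[[ln]]
    cat(sprintf("=== Line %s ===\n", ln))
    cat("Per-gene stability statistics:\n")
    print(round(l$statistics, 4))
    cat("\nPairwise variation:\n")
    print(round(l$pv$v, 4))
    if (!l$pv$not_reached) {
      cat(sprintf("Recommended number of reference genes: %d\n",
                  l$pv$recommended_n))
    }
    cat("\nGenes with significant group differences: ",
        if (any(l$significant_pairs > 0)) {
          paste(names(l$significant_pairs)[l$significant_pairs > 0],
                collapse = ", ")
        } else "none", "\n", sep = "")
    cat(sprintf("\nConsensus (%s, objective %g):\n  %s\n\n",
                l$consensus$optimizer, l$consensus$objective,
                paste(l$consensus$consensus, collapse = " > ")))
  }
  invisible(x)
}

#' Extract per-gene stability statistics
#'
#' @param object A `"refstab"` fit.
#' @param line Line to extract; default the first.
#' @param ... Unused.
#' @return A genes x methods numeric matrix (geNorm M, qBase M, qBase CV,
#'   BestKeeper r^2, NormFinder stability).
#' @export
coef.refstab <- function(object, line = names(object$lines)[1], ...) {
  coef_line(object$lines[[line]])
}

#' Plot a reference-gene stability analysis
#'
#' @param x A `"refstab"` fit.
#' @param type `"m"` — geNorm M values in stepwise order; `"pv"` — the
#'   pairwise-variation series with its cutoff; `"trace"` — the Cross-Entropy
#'   optimizer objective trace.
#' @param line Line to plot; default the first.
#' @param ... Passed to the underlying plotting functions.
#' @return `x`, invisibly.
#' @export
plot.refstab <- function(x, type = c("m", "pv", "trace"),
                         line = names(x$lines)[1], ...) {
  type <- match.arg(type)
  l <- x$lines[[line]]
  if (type == "m") {
    graphics::barplot(rev(l$genorm$m), las = 2,
                      ylab = "geNorm M (lower = more stable)",
                      main = paste("Stepwise geNorm M,", line), ...)
  } else if (type == "pv") {
    graphics::barplot(l$pv$v, las = 2, ylab = "V(n/n+1)",
                      main = paste("Pairwise variation,", line), ...)
    graphics::abline(h = l$pv$cutoff, lty = 2)
  } else {
    graphics::plot(l$cemc$trace, type = "s", xlab = "iteration",
                   ylab = "best footrule objective",
                   main = paste("Cross-Entropy trace,", line), ...)
  }
  invisible(x)
}
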