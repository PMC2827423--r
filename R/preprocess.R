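.sample_id <- function(d) paste(d$line, d$organ, d$stage, d$bio_rep, sep = ".")

#' Technical-replicate quality control
#'
#' Keeps a technical-replicate group (same sample and gene) only when its CT
#' values differ by less than `max_range` cycles, the classical "technical
#' repetitions differing by less than one cycle" rule; the comparison is
#' strict, so a spread equal to `max_range` is discarded. Groups in which no
#' reaction amplified are discarded with flag `"no_amplification"`; groups
#' that fail the spread rule carry `"replicate_spread"`.
#'
#' @param reactions Reaction `data.frame` (see [read_reactions()]).
#' @param max_range Maximum allowed CT range in cycles, default 1.
#' @return A list with elements `kept` and `discarded`, both reaction
#'   `data.frame`s; the discarded rows have their `qc_flags` set.
#' @export
filter_technical_replicates <- function(reactions, max_range = 1) {
  pre_discarded <- reactions$qc_flags == "discarded"
  grp <- paste(.sample_id(reactions), reactions$gene, sep = "\r")
  keep_grp <- vapply(split(seq_len(nrow(reactions)), grp), function(idx) {
    idx <- idx[!pre_discarded[idx]]
    cts <- reactions$ct[idx]
    cts <- cts[!is.na(cts)]
    if (length(cts) == 0) return("no_amplification")
    if (max(cts) - min(cts) < max_range) "" else "replicate_spread"
  }, "")
  flag <- unname(keep_grp[grp])
  disc <- flag != "" | pre_discarded | is.na(reactions$ct)
  kept <- reactions[!disc, , drop = FALSE]
  discarded <- reactions[disc, , drop = FALSE]
  if (nrow(discarded) > 0) {
    f <- flag[disc]
    discarded$qc_flags <- ifelse(pre_discarded[disc], "discarded",
                                 ifelse(f != "", f, "no_amplification"))
  }
  n_groups <- length(keep_grp)
  message(sprintf("technical-replicate QC: kept %d of %d groups (%d discarded)",
                  sum(keep_grp == ""), n_groups, sum(keep_grp != "")))
  list(kept = kept, discarded = discarded)
}

#' Average technical replicates into a CT matrix
#'
#' Collapses the technical level by arithmetic averaging of CT values (the
#' instrument-native, approximately log-scale quantity); biological replicates
#' stay separate samples. Per-cell efficiencies are resolved according to
#' `control$efficiency_mode`: the fixed value, the gene-wise mean of observed
#' per-reaction efficiencies, or the within-cell mean.
#'
#' Genes missing in more than 20% of samples are dropped with a warning, then
#' samples missing any retained gene are dropped with a warning, so the
#' returned matrix has no missing cells.
#'
#' @param kept Reaction `data.frame` that passed
#'   [filter_technical_replicates()].
#' @param control A [refstab_control()] object.
#' @return An object of class `"ct_matrix"`: a list with `ct` and
#'   `efficiency` (genes x samples matrices), `samples` (a `data.frame` of
#'   sample keys with `tech_rep` absent), and `groups` (organ.stage labels).
#' @export
average_replicates <- function(kept, control = refstab_control()) {
  stopifnot(nrow(kept) > 0)
  sid <- .sample_id(kept)
  genes <- sort(unique(kept$gene))
  sample_tab <- unique(kept[, c("line", "organ", "stage", "bio_rep")])
  sample_tab <- sample_tab[order(sample_tab$organ, sample_tab$stage,
                                 sample_tab$bio_rep), , drop = FALSE]
  sids <- paste(sample_tab$line, sample_tab$organ, sample_tab$stage,
                sample_tab$bio_rep, sep = ".")
  rownames(sample_tab) <- NULL

  ct <- matrix(NA_real_, length(genes), length(sids),
               dimnames = list(genes, sids))
  eff <- ct
  cell <- paste(sid, kept$gene, sep = "\r")
  ct_means <- tapply(kept$ct, cell, mean)
  eff_means <- tapply(kept$efficiency, cell, function(x) mean(x, na.rm = TRUE))
  for (g in genes) {
    for (s in sids) {
      k <- paste(s, g, sep = "\r")
      if (k %in% names(ct_means)) {
        ct[g, s] <- ct_means[[k]]
        eff[g, s] <- eff_means[[k]]
      }
    }
  }

  if (control$efficiency_mode == "fixed") {
    eff[] <- control$fixed_efficiency
  } else if (control$efficiency_mode == "per_gene") {
    gene_eff <- tapply(kept$efficiency, kept$gene, function(x) mean(x, na.rm = TRUE))
    eff[] <- gene_eff[rep(genes, ncol(eff))]
  }

  gene_missing <- rowMeans(is.na(ct))
  drop_genes <- gene_missing > 0.20
  if (any(drop_genes)) {
    warning("dropping gene(s) missing in > 20% of samples: ",
            paste(genes[drop_genes], collapse = ", "))
    ct <- ct[!drop_genes, , drop = FALSE]
    eff <- eff[!drop_genes, , drop = FALSE]
  }
  sample_missing <- colSums(is.na(ct)) > 0
  if (any(sample_missing)) {
    warning("dropping sample(s) missing a retained gene: ",
            paste(colnames(ct)[sample_missing], collapse = ", "))
    ct <- ct[, !sample_missing, drop = FALSE]
    eff <- eff[, !sample_missing, drop = FALSE]
    sample_tab <- sample_tab[!sample_missing, , drop = FALSE]
  }
  structure(list(ct = ct, efficiency = eff, samples = sample_tab,
                 groups = paste(sample_tab$organ, sample_tab$stage, sep = ".")),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("CT matrix: %d genes x %d samples (%d groups)\n",
              nrow(x$ct), ncol(x$ct), length(unique(x$groups))))
  invisible(x)
}

#' Efficiency-corrected relative quantities
#'
#' Converts a CT matrix into relative quantities (RQ) by the
#' efficiency-corrected delta-Ct rule: for gene *g* and sample *s*,
#' `rq = E(g,s) ^ (ctmin(g) - ct(g,s))` where `ctmin(g)` is the lowest CT of
#' that gene. Each gene's rescaling reference is therefore its own lowest-CT
#' sample, whose RQ is exactly 1; with `global_reference = TRUE` the single
#' sample holding the lowest CT anywhere in the matrix is used as the common
#' calibrator instead. With a fixed efficiency of 2 the values reduce to the
#' classical `2^(-dCt)` quantities.
#'
#' @param cm A `"ct_matrix"` from [average_replicates()].
#' @param global_reference Logical; see Description.
#' @return An object of class `"rq_matrix"`: list with `rq` (genes x samples,
#'   all positive), `efficiency`, `samples`, `groups`, `reference_sample`
#'   (named per-gene vector) and `efficiency_mode` attributes carried over.
#' @export
compute_rq <- function(cm, global_reference = FALSE) {
  stopifnot(inherits(cm, "ct_matrix"))
  if (any(cm$efficiency <= 1, na.rm = TRUE)) {
    bad <- which(cm$efficiency <= 1, arr.ind = TRUE)[1, ]
    stop("efficiency <= 1 at gene ", rownames(cm$ct)[bad[1]],
         ", sample ", colnames(cm$ct)[bad[2]], ": RQ undefined")
  }
  if (global_reference) {
    ref_col <- which.min(apply(cm$ct, 2, min))
    ref <- rep(colnames(cm$ct)[ref_col], nrow(cm$ct))
    ct_ref <- cm$ct[, ref_col]
  } else {
    ref_idx <- apply(cm$ct, 1, which.min)
    ref <- colnames(cm$ct)[ref_idx]
    ct_ref <- apply(cm$ct, 1, min)
  }
  names(ref) <- rownames(cm$ct)
  rq <- cm$efficiency ^ (ct_ref - cm$ct)
  structure(list(rq = rq, efficiency = cm$efficiency, samples = cm$samples,
                 groups = cm$groups, reference_sample = ref),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("RQ matrix: %d genes x %d samples\n", nrow(x$rq), ncol(x$rq)))
  invisible(x)
}

#' Subset a CT or RQ matrix by sample
#'
#' @param x A `"ct_matrix"` or `"rq_matrix"`.
#' @param samples Logical or integer index over samples (columns).
#' @return An object of the same class restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  for (nm in intersect(c("ct", "rq", "efficiency"), names(x))) {
    x[[nm]] <- x[[nm]][, samples, drop = FALSE]
  }
  x$samples <- x$samples[samples, , drop = FALSE]
  x$groups <- x$groups[samples]
  x
}
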