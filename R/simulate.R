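.default_genes <- c("ACT", "CYP", "EF1a", "GAPDH", "RAN1", "RPS13", "SAND",
                    "TUB", "UBQ")
.default_eff <- c(ACT = 1.75, CYP = 1.64, EF1a = 1.62, GAPDH = 1.83,
                  RAN1 = 1.71, RPS13 = 1.70, SAND = 1.61, TUB = 1.61,
                  UBQ = 1.67)

#' Specification of a synthetic qPCR reference-gene study
#'
#' Describes the simulated study design and noise structure. The defaults
#' emulate a two-line Petunia flower/leaf development design: 9 candidate
#' genes with gene-specific amplification efficiencies between 1.6 and 1.85,
#' six sample groups (flower stages A-D plus leaf stages A and C), 3
#' biological x 3 technical replicates, technical CT noise of 0.15 cycles and
#' biological scatter of 0.25 log2 units per gene.
#'
#' The intergroup shift matrix `delta` plants true expression differences
#' between groups (log2 units); a gene with non-zero `delta` spread is a
#' genuinely unstable reference candidate. The generator records a composite
#' ground-truth instability score for each gene, `range(delta) + 2 *
#' sigma_bio`, defining the ordering that recovery tests check against.
#'
#' @param lines Character vector of line labels.
#' @param genes Character vector of gene labels.
#' @param efficiency Named per-gene true amplification factors in (1, 2].
#' @param base_log2 Named per-gene baseline abundance (log2 scale); also sets
#'   the gene's typical CT via `ct0 - base_log2 / log2(E)`.
#' @param delta Genes x groups matrix of intergroup shifts (log2 units);
#'   default all zero (a null study).
#' @param sigma_bio Named per-gene biological SD (log2 units), default 0.25.
#' @param sigma_tech Technical CT noise SD in cycles, shared across genes
#'   (instrument-dominated), default 0.15.
#' @param groups Data frame with columns `organ` and `stage`; default the six
#'   design groups (flower A-D, leaf A and C).
#' @param n_bio,n_tech Biological / technical replicates per group, default 3.
#' @param ct0 Baseline cycle offset (cycles), default 28.
#' @param curve List of amplification-curve parameters: `cycles` (40),
#'   `plateau` (carrying capacity, 1e9 molecules), `n0_scale` (template
#'   molecules at `base_log2 = 0`, 8), `alpha` (fluorescence per molecule),
#'   `b0`, `b1` (linear background), `noise` (read noise SD as a fraction of
#'   the plateau fluorescence, 0.002).
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(lines = c("Mitchell", "V30"),
                            genes = .default_genes,
                            efficiency = .default_eff,
                            base_log2 = NULL,
                            delta = NULL,
                            sigma_bio = NULL,
                            sigma_tech = 0.15,
                            groups = NULL,
                            n_bio = 3, n_tech = 3,
                            ct0 = 28,
                            curve = list()) {
  if (is.null(groups)) {
    groups <- data.frame(organ = c(rep("flower", 4), rep("leaf", 2)),
                         stage = c("A", "B", "C", "D", "A", "C"),
                         stringsAsFactors = FALSE)
  }
  stopifnot(length(genes) >= 2, n_bio >= 1, n_tech >= 1, sigma_tech >= 0)
  if (is.null(names(efficiency))) names(efficiency) <- genes
  efficiency <- efficiency[genes]
  stopifnot(all(efficiency > 1), all(efficiency <= 2))
  if (is.null(base_log2)) {
    # spread typical CTs over roughly 15-22 cycles
    base_log2 <- stats::setNames(seq(4, 8, length.out = length(genes)), genes)
  }
  base_log2 <- base_log2[genes]
  gid <- paste(groups$organ, groups$stage, sep = ".")
  if (is.null(delta)) {
    delta <- matrix(0, length(genes), nrow(groups),
                    dimnames = list(genes, gid))
  }
  stopifnot(nrow(delta) == length(genes), ncol(delta) == nrow(groups))
  dimnames(delta) <- list(genes, gid)
  if (is.null(sigma_bio)) sigma_bio <- stats::setNames(rep(0.25, length(genes)), genes)
  sigma_bio <- sigma_bio[genes]
  stopifnot(all(sigma_bio >= 0))
  curve_def <- list(cycles = 40L, plateau = 1e9, n0_scale = 8,
                    alpha = 1e-9, b0 = 0.05, b1 = 0.001, noise = 0.002)
  curve_def[names(curve)] <- curve
  truth_score <- apply(delta, 1, function(x) diff(range(x))) + 2 * sigma_bio
  structure(list(lines = lines, genes = genes, efficiency = efficiency,
                 base_log2 = base_log2, delta = delta, sigma_bio = sigma_bio,
                 sigma_tech = sigma_tech, groups = groups, n_bio = n_bio,
                 n_tech = n_tech, ct0 = ct0, curve = curve_def,
                 truth_score = truth_score,
                 truth_ordering = names(sort(truth_score))),
            class = "simulation_spec")
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate a qPCR reaction table
#'
#' Draws a complete reaction table under the model: the true log2 quantity of
#' gene *g* in biological replicate *b* of group *G* is
#' `q = base_log2(g) + delta(g, G) + Normal(0, sigma_bio(g))`, and each
#' technical replicate observes
#' `CT = ct0 - q / log2(E_g) + Normal(0, sigma_tech)` — one cycle of delay per
#' `1 / log2(E)` halvings of template. Identical `(spec, seed)` inputs give
#' identical output.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return A list of class `"simulated_study"`: `reactions` (reaction
#'   `data.frame` covering every line), `truth` (list with `q` — the
#'   per-line true log2 quantities — plus the spec's `score` and `ordering`),
#'   and `spec`.
#' @export
simulate_ct_table <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(seed, {
    gid <- paste(spec$groups$organ, spec$groups$stage, sep = ".")
    bio <- expand.grid(bio_rep = seq_len(spec$n_bio),
                       grp = seq_len(nrow(spec$groups)),
                       gene = spec$genes,
                       line = spec$lines,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    q <- spec$base_log2[bio$gene] +
      spec$delta[cbind(bio$gene, gid[bio$grp])] +
      stats::rnorm(nrow(bio), 0, spec$sigma_bio[bio$gene])
    ct_true <- spec$ct0 - q / log2(spec$efficiency[bio$gene])

    idx <- rep(seq_len(nrow(bio)), each = spec$n_tech)
    reactions <- data.frame(
      line = bio$line[idx],
      organ = spec$groups$organ[bio$grp][idx],
      stage = spec$groups$stage[bio$grp][idx],
      bio_rep = bio$bio_rep[idx],
      tech_rep = rep(seq_len(spec$n_tech), nrow(bio)),
      gene = bio$gene[idx],
      ct = ct_true[idx] + stats::rnorm(length(idx), 0, spec$sigma_tech),
      efficiency = unname(spec$efficiency[bio$gene][idx]),
      qc_flags = "", stringsAsFactors = FALSE)
    structure(list(reactions = reactions,
                   truth = list(q = stats::setNames(
                                  q, paste(bio$line, bio$gene, gid[bio$grp],
                                           bio$bio_rep, sep = "\r")),
                                score = spec$truth_score,
                                ordering = spec$truth_ordering),
                   spec = spec),
              class = "simulated_study")
  })
}

#' Simulate a single amplification curve
#'
#' Logistic-resource amplification: the amplicon count follows
#' `N(c+1) = N(c) * (1 + (E - 1) * (1 - N(c) / K))`, so early cycles multiply
#' by the true per-cycle efficiency `E` (the exponential phase exists by
#' construction) and growth saturates at the carrying capacity `K`.
#' Fluorescence is `F(c) = alpha * N(c) + b0 + b1 * c + Normal(0, noise *
#' alpha * K)`.
#'
#' @param efficiency True per-cycle amplification factor in (1, 2].
#' @param n0 Starting template (molecules).
#' @param curve Curve parameter list as in [simulation_spec()].
#' @return Numeric fluorescence vector of length `curve$cycles`.
#' @export
simulate_curve <- function(efficiency, n0, curve = simulation_spec()$curve) {
  n_cyc <- curve$cycles
  n <- numeric(n_cyc)
  x <- n0
  for (c in seq_len(n_cyc)) {
    x <- x * (1 + (efficiency - 1) * (1 - x / curve$plateau))
    n[c] <- x
  }
  f <- curve$alpha * n + curve$b0 + curve$b1 * seq_len(n_cyc)
  if (curve$noise > 0) {
    f <- f + stats::rnorm(n_cyc, 0, curve$noise * curve$alpha * curve$plateau)
  }
  f
}

#' Simulate a study with raw amplification curves
#'
#' Like [simulate_ct_table()] but additionally generates one amplification
#' curve per reaction, with starting template `n0 = n0_scale * 2^q` set by the
#' same true quantity that drives the CT model. The reaction table's CT values
#' are produced by running [call_ct()] on each generated curve, so the curves
#' and the table are consistent by construction; the per-reaction efficiency
#' column carries the [estimate_efficiency()] output for each curve.
#'
#' @inheritParams simulate_ct_table
#' @param control A [refstab_control()] used for CT calling.
#' @return A `"simulated_study"` with additional elements `curves` (named
#'   list of fluorescence vectors) and `wellmap` (well metadata
#'   `data.frame`).
#' @export
simulate_curves <- function(spec, seed = 1L, control = refstab_control()) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(seed, {
    rows <- list()
    curves <- list()
    q_truth <- list()
    well <- 0L
    for (line in spec$lines) {
      for (gi in seq_along(spec$genes)) {
        g <- spec$genes[gi]
        e <- spec$efficiency[g]
        for (grp in seq_len(nrow(spec$groups))) {
          gid <- paste(spec$groups$organ[grp], spec$groups$stage[grp], sep = ".")
          for (b in seq_len(spec$n_bio)) {
            q <- spec$base_log2[g] + spec$delta[g, gid] +
              stats::rnorm(1, 0, spec$sigma_bio[g])
            q_truth[[paste(line, g, gid, b, sep = "\r")]] <- q
            for (t in seq_len(spec$n_tech)) {
              well <- well + 1L
              wid <- sprintf("W%04d", well)
              n0 <- spec$curve$n0_scale * 2^(q + stats::rnorm(1, 0, spec$sigma_tech * log2(e)))
              curves[[wid]] <- simulate_curve(e, n0, spec$curve)
              rows[[length(rows) + 1]] <- data.frame(
                well = wid, line = line, organ = spec$groups$organ[grp],
                stage = spec$groups$stage[grp], bio_rep = b, tech_rep = t,
                gene = g, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    wellmap <- do.call(rbind, rows)
    rownames(wellmap) <- NULL
    reactions <- call_reactions(curves, wellmap, control)
    structure(list(reactions = reactions, curves = curves, wellmap = wellmap,
                   truth = list(q = unlist(q_truth),
                                score = spec$truth_score,
                                ordering = spec$truth_ordering),
                   spec = spec),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated qPCR study: %d reactions (%d lines, %d genes, %d groups)%s\n",
              nrow(x$reactions), length(x$spec$lines), length(x$spec$genes),
              nrow(x$spec$groups),
              if (!is.null(x$curves)) sprintf(", %d curves", length(x$curves)) else ""))
  invisible(x)
}
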