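#' Baseline-correct an amplification curve
#'
#' Fits a straight line to the fluorescence over the baseline window (default
#' cycles 3-10, before detectable amplification) and subtracts its
#' extrapolation from the whole series. This removes both the constant
#' reporter offset and any linear background drift, which would otherwise
#' bias the ratio of successive readings used for efficiency estimation.
#'
#' @param fluorescence Numeric vector of fluorescence readings, one per cycle
#'   starting at cycle 1.
#' @param baseline_window Integer vector `c(first, last)` of cycles used as
#'   background, or `NULL` to leave the curve untouched.
#' @return The corrected fluorescence vector.
#' @export
baseline_correct <- function(fluorescence, baseline_window = c(3L, 10L)) {
  if (is.null(baseline_window)) return(fluorescence)
  stopifnot(length(fluorescence) >= baseline_window[2])
  win <- baseline_window[1]:baseline_window[2]
  fit <- stats::lm.fit(cbind(1, win), fluorescence[win])
  cyc <- seq_along(fluorescence)
  fluorescence - (fit$coefficients[1] + fit$coefficients[2] * cyc)
}

#' Call the cycle threshold (CT) of an amplification curve
#'
#' The CT is the fractional cycle at which the baseline-corrected fluorescence
#' first crosses `threshold_fraction` of the plateau, where the plateau is the
#' maximum corrected reading. The crossing cycle is linearly interpolated
#' between the bracketing integer cycles, so the result is scale-free: the
#' same CT is returned if the whole series is multiplied by any positive
#' constant.
#'
#' @param fluorescence Numeric fluorescence vector indexed by cycle (cycle 1
#'   first). At least 15 cycles are required.
#' @param threshold_fraction Fraction of the plateau at which the threshold is
#'   set. Default 0.20, i.e. 20% of total fluorescence.
#' @param baseline_window Passed to [baseline_correct()]; `NULL` for curves
#'   already corrected.
#' @return The fractional CT (a single number strictly between 1 and the cycle
#'   count), or `NA` with attribute `flag` set to `"no_amplification"` (the
#'   threshold is never reached from below) or `"bad_baseline"` (plateau not
#'   positive after correction).
#' @export
#' @examples
#' f <- c(rep(0, 16), 18, 24, 60, 90, 100, 100)
#' call_ct(f, baseline_window = NULL)  # 17 + (20 - 18) / (24 - 18)
call_ct <- function(fluorescence, threshold_fraction = 0.20,
                    baseline_window = c(3L, 10L)) {
  stopifnot(length(fluorescence) >= 15,
            threshold_fraction > 0, threshold_fraction < 1)
  f <- baseline_correct(fluorescence, baseline_window)
  plateau <- max(f)
  # the plateau must be positive and above numerical residue of the correction
  if (!is.finite(plateau) || plateau <= 1e-8 * max(abs(fluorescence), 1)) {
    return(structure(NA_real_, flag = "bad_baseline"))
  }
  thr <- threshold_fraction * plateau
  n_cyc <- length(f)
  # first upward crossing: f[c] < thr <= f[c + 1]
  below <- f[-n_cyc] < thr
  above <- f[-1] >= thr
  hit <- which(below & above)
  if (length(hit) == 0) {
    return(structure(NA_real_, flag = "no_amplification"))
  }
  c0 <- hit[1]
  c0 + (thr - f[c0]) / (f[c0 + 1] - f[c0])
}

#' Estimate PCR efficiency from a single amplification curve
#'
#' Single-curve efficiency estimation anchored at the second-derivative
#' maximum (SDM): the evaluation cycle `n` is the first cycle at which the
#' corrected fluorescence reaches 20% of its value at the SDM, which places
#' it inside the exponential phase of the reaction. The SDM itself is located
#' by centred finite differences on a 3-point moving average of the corrected
#' curve (raw second differences are noise dominated); ties in its argmax are
#' broken toward the earlier cycle.
#'
#' Two estimators of the amplification efficiency E (product gain per cycle,
#' 2 = perfect doubling) are available:
#'
#' * `method = "ratio"` — the classical two-reading form
#'   `E = F(n) / F(n - 1)`. It is exact on ideal noise-free curves but its
#'   variance is set entirely by the two readings nearest the noise floor.
#' * `method = "window"` (default) — each per-cycle ratio from `n` up to the
#'   cycle where the curve reaches 60% of its plateau is converted to an
#'   efficiency estimate by inverting the logistic resource-depletion model,
#'   `E_c = 1 + (F(c)/F(c-1) - 1) / (1 - F(c-1)/P)` with `P` the plateau, and
#'   the estimates are combined by inverse-variance weights (read noise is
#'   approximately constant per cycle, so a ratio's precision grows with the
#'   signal). On a noise-free logistic curve every `E_c` equals the true
#'   efficiency, so the estimator inherits the exactness of the ratio form
#'   while averaging the read noise down.
#'
#' @inheritParams call_ct
#' @param method `"window"` (default) or `"ratio"`, see Details.
#' @return A list of class `"efficiency_estimate"` with elements `e` (the
#'   estimated per-cycle amplification factor, or `NA`), `sdm_cycle`,
#'   `eval_cycle` (the cycle `n`), `method`, and `diagnostics` (character
#'   vector; empty when the estimate is clean, otherwise one of `"no_sdm"`,
#'   `"below_noise"`, `"out_of_range"`).
#' @references Liu, W. and Saint, D.A. (2002) A new quantitative method of
#'   real time reverse transcription polymerase chain reaction assay based on
#'   simulation of polymerase chain reaction kinetics. Analytical
#'   Biochemistry 302, 52-59.
#' @export
estimate_efficiency <- function(fluorescence, baseline_window = c(3L, 10L),
                                method = c("window", "ratio")) {
  method <- match.arg(method)
  stopifnot(length(fluorescence) >= 15)
  f <- baseline_correct(fluorescence, baseline_window)
  n_cyc <- length(f)

  # 3-point moving average, ends kept as-is
  s <- f
  s[2:(n_cyc - 1)] <- (f[1:(n_cyc - 2)] + f[2:(n_cyc - 1)] + f[3:n_cyc]) / 3
  d2 <- s[3:n_cyc] - 2 * s[2:(n_cyc - 1)] + s[1:(n_cyc - 2)]
  sdm <- which.max(d2) + 1L  # which.max returns the first (earliest) maximum
  res <- list(e = NA_real_, sdm_cycle = sdm, eval_cycle = NA_integer_,
              method = method, diagnostics = character())
  class(res) <- "efficiency_estimate"
  if (sdm <= 2L || sdm >= n_cyc - 1L) {
    res$diagnostics <- "no_sdm"
    return(res)
  }
  level <- 0.20 * f[sdm]
  n <- which(f >= level)[1]
  # the evaluation point stays inside the exponential phase
  if (is.na(n) || n > sdm) n <- sdm
  if (n < 2 || f[n - 1] <= 0) {
    res$diagnostics <- "below_noise"
    res$eval_cycle <- n
    return(res)
  }
  res$eval_cycle <- n
  if (method == "ratio") {
    res$e <- f[n] / f[n - 1]
  } else {
    plateau <- max(f)
    below <- which(f <= 0.6 * plateau)
    cmax <- max(sdm, if (length(below)) max(below) else sdm)
    cc <- n:cmax
    dep <- 1 - f[cc - 1] / plateau
    g <- 1 + (f[cc] / f[cc - 1] - 1) / dep
    w <- dep^2 / (1 / f[cc]^2 + 1 / f[cc - 1]^2)
    res$e <- sum(g * w) / sum(w)
  }
  if (res$e > 2) res$diagnostics <- "out_of_range"
  if (res$e <= 1) res$diagnostics <- c(res$diagnostics, "below_noise")
  res
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat("PCR efficiency estimate\n")
  cat("  E            :", if (is.na(x$e)) "NA" else format(x$e, digits = 4), "\n")
  cat("  SDM cycle    :", x$sdm_cycle, "\n")
  cat("  eval cycle n :", x$eval_cycle, "\n")
  if (length(x$diagnostics)) cat("  diagnostics  :", paste(x$diagnostics, collapse = ", "), "\n")
  invisible(x)
}

#' Build a reaction table from amplification curves
#'
#' Runs [call_ct()] and [estimate_efficiency()] on every well and joins the
#' results to the well map, yielding the same reaction table shape produced by
#' [read_reactions()]. Wells whose threshold is never reached are kept with a
#' missing CT and a `"no_amplification"` flag.
#'
#' @param curves Named list of fluorescence vectors as from [read_curves()].
#' @param wellmap Well metadata as from [read_wellmap()].
#' @param control A [refstab_control()] object (threshold fraction, baseline
#'   window and efficiency mode are taken from it).
#' @return A reaction `data.frame`; when `control$efficiency_mode` is
#'   `"fixed"` the efficiency column is the fixed value, otherwise the
#'   per-well estimate.
#' @export
call_reactions <- function(curves, wellmap, control = refstab_control()) {
  missing_wells <- setdiff(names(curves), wellmap$well)
  if (length(missing_wells) > 0) {
    stop("well(s) present in curves but absent from well map: ",
         paste(missing_wells, collapse = ", "))
  }
  wm <- wellmap[match(names(curves), wellmap$well), , drop = FALSE]
  ct <- numeric(length(curves))
  eff <- numeric(length(curves))
  flags <- character(length(curves))
  for (i in seq_along(curves)) {
    ci <- call_ct(curves[[i]], control$threshold_fraction, control$baseline_window)
    ct[i] <- as.numeric(ci)
    if (is.na(ct[i])) flags[i] <- attr(ci, "flag")
    ee <- estimate_efficiency(curves[[i]], control$baseline_window)
    eff[i] <- if (length(ee$diagnostics) == 0) ee$e else NA_real_
  }
  if (control$efficiency_mode == "fixed") {
    eff <- rep(control$fixed_efficiency, length(curves))
  }
  data.frame(line = wm$line, organ = wm$organ, stage = wm$stage,
             bio_rep = as.integer(wm$bio_rep), tech_rep = as.integer(wm$tech_rep),
             gene = wm$gene, ct = ct, efficiency = eff, qc_flags = flags,
             stringsAsFactors = FALSE)
}
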