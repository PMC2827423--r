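---
title: "Assessing reference-gene stability for qPCR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing reference-gene stability for qPCR: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

Relative quantification by qPCR reports the abundance of a transcript of
interest divided by a normalization factor derived from one or more
*reference genes*. The entire construction rests on the reference genes
being equally expressed in every sample compared; when that fails, the
normalisation error propagates into every fold change. `refstab` implements
the standard validation workflow: measure a panel of candidate genes across
the conditions of interest, score each candidate with several stability
statistics, decide how many genes the normalization factor needs, and merge
the (often disagreeing) statistics into one consensus ranking.

The package is organised as a single fitting function, `refstab()`, which
runs the whole chain per line/genotype and returns a classed object with
`print()`, `summary()`, `coef()` and `plot()` methods; every stage is also
exported on its own.

# From fluorescence to CT and efficiency

**Baseline correction.** Raw well fluorescence contains a constant reporter
offset and, on real instruments, a slow drift. We fit a straight line to the
readings in the baseline window (default cycles 3–10, before detectable
amplification) and subtract its extrapolation. Subtracting only the window
*mean* would leave the drift in place; because the efficiency estimate below
is a ratio of successive readings taken near the noise floor, even a small
residual slope biases it by far more than the tolerances we care about, so
the linear fit is the default and only behaviour. A curve that is already
corrected can be passed with `baseline_window = NULL`.

**CT calling.** The cycle threshold is the fractional cycle at which the
corrected fluorescence first crosses `threshold_fraction` (default 0.20,
i.e. 20 % of total fluorescence) of the plateau, the maximum corrected
reading. The crossing is linearly interpolated between the bracketing
cycles. Because the threshold is a *fraction of the curve's own plateau*,
CT is invariant to rescaling the fluorescence axis — a property the tests
assert. Curves whose plateau is not meaningfully positive are flagged
`bad_baseline`; monotonically falling curves that never cross the threshold
from below are flagged `no_amplification`.

**Single-curve efficiency.** The amplification efficiency E (per-cycle gain;
2 = perfect doubling) is estimated from each curve individually, anchored at
the classical evaluation point: the first cycle `n` at which the corrected
fluorescence reaches 20 % of its value at the second-derivative maximum
(SDM). The SDM is located on a 3-point moving average of the curve — raw
second differences are noise-dominated — with argmax ties broken toward the
earlier cycle for determinism.

Two estimators are provided:

* `method = "ratio"`: the literal two-reading form `E = F(n)/F(n−1)`. It is
  exact on ideal curves but its variance is set entirely by the two readings
  nearest the noise floor; with read noise of a few tenths of a percent of
  the plateau its standard error is of order 0.1–0.3 in E, which is too
  coarse to distinguish the 1.6–1.85 efficiencies typical of real assays.
* `method = "window"` (default): every per-cycle ratio from `n` up to the
  cycle where the curve reaches 60 % of its plateau is converted to an
  efficiency estimate by inverting the logistic resource-depletion model,
  `E_c = 1 + (F(c)/F(c−1) − 1)/(1 − F(c−1)/P)` with `P` the plateau, and the
  `E_c` are averaged with inverse-variance weights (read noise is roughly
  constant per cycle, so a ratio's precision grows with its signal). On a
  noise-free logistic curve every `E_c` equals the true efficiency exactly,
  so the estimator keeps the ratio form's exactness while averaging the
  noise down by roughly the square root of the window length. The 60 %
  ceiling keeps the depletion correction well-conditioned (beyond it,
  `1 − F/P` is small and the correction amplifies noise faster than the
  signal grows).

Estimates above 2 are never truncated; they are returned with an
`out_of_range` diagnostic so the caller can decide. A curve whose SDM falls
at the boundary of the cycle range gets `no_sdm`; an evaluation point at or
below the noise floor gets `below_noise`.

# Preprocessing

**Replicate QC.** Technical replicate groups are kept only when their CT
range is strictly below `replicate_max_range` (default 1 cycle, the
conventional "differing by less than one cycle" rule; equality discards).
Groups in which nothing amplified are discarded as `no_amplification`.

**Averaging.** Technical replicates are averaged on the CT scale — the
instrument-native, approximately log-scale quantity — never on the RQ scale.
Biological replicates are *not* averaged: they are the samples, and the
stability statistics need the within-group replication. Genes missing in
more than 20 % of samples are dropped, then samples missing any retained
gene, each with a warning, so the matrices passed downstream are complete.

**Relative quantities.** `RQ(g, s) = E(g,s)^(CTmin(g) − CT(g,s))`. The
efficiency entering each cell is controlled by `efficiency_mode`: a single
`fixed` value (default 2), a `per_gene` mean of the observed per-reaction
estimates, or the `per_reaction` (cell-wise) mean. By default the rescaling
reference — the sample with the lowest CT, whose RQ is exactly 1 — is chosen
per gene; `global_reference = TRUE` instead uses the single sample holding
the lowest CT anywhere in the matrix as a common calibrator. We default to
per-gene because it keeps every gene's RQ column in (0, 1] and is what the
downstream statistics (all built from log-ratios or normalized quantities)
are invariant to anyway; the switch exists because either reading of "the
sample with the lowest CT value" is defensible.

# The stability statistics

All logarithms are base 2 and all standard deviations use the n−1
denominator, the conventions of the source tools.

**geNorm M** for gene *j* is the mean over partner genes *k* of the SD over
samples of `log2(RQ_j/RQ_k)`. Proportional genes give M = 0; rescaling a
gene's column changes nothing. `genorm_stepwise()` repeatedly removes the
highest-M gene until two remain; the final pair is intrinsically unordered
under the pairwise measure and is listed alphabetically. Ties at the argmax
(exactly degenerate panels) are broken alphabetically and recorded in the
trace.

**Pairwise variation.** `V(n/n+1)` is the SD over samples of
`log2(NF_n/NF_{n+1})` where `NF_n` is the geometric mean RQ of the top *n*
genes in the stepwise ranking. The smallest *n* with `V < pv_cutoff`
(default 0.15, the conventional threshold below which an extra gene no
longer improves normalisation) is the recommended panel size.

**qBase-style M and CV.** M here is the full-panel geNorm M without any
exclusion — this is the documented procedural difference between the two
tools. CV(j) is the coefficient of variation over samples of
`RQ(j,s)/NF_all(s)` with `NF_all` the geometric mean over *all* panel genes,
the gene itself included. Including the gene is the simplest defensible
reading; it shrinks every CV by the same panel-size-dependent factor and so
does not reorder genes.

**BestKeeper.** The index is the per-sample geometric mean of the *CT*
values (not RQs) of all candidates, the gene under evaluation included, and
each gene is scored by the coefficient of determination r² of its CTs
against the index; higher is better. A gene with zero CT variance has no
defined correlation and is reported `NA`, ranked last, with a warning.

**NormFinder.** Log-scale expression (by default `log2(RQ)`; a CT-scale
input can be supplied directly since CT is already logarithmic — the choice
is the caller's) is sample-centred on the gene-panel mean, removing
sample-specific loading. Per gene and group, the intragroup variance is
estimated with the correction
`σ²(i,g) = max(0, I/(I−2) · (v(i,g) − Σ_i′ v(i′,g)/(I(I−1))))`, which undoes
the coupling the centring induces between the I genes (the estimator is
unbiased, which the test suite verifies by Monte Carlo at n = 6000). The
intergroup difference `d(i,g)` is shrunk by the empirical-Bayes factor
`γ²/(γ² + σ²/n_g)`, with `γ²` the excess of the mean squared difference over
its sampling variance; `shrink = FALSE` disables this for cross-checking
against plainer implementations. The stability value averages
`|d̃| + sqrt(σ²/n_g)` over groups; with a single group it reduces to the
intragroup standard error. At least 3 genes are required (the variance
correction is undefined below that) and at least 2 samples per group.

# Group testing

For each gene the CT values (one per biological replicate) are screened for
stage differences: Shapiro-Wilk per group for inspection, then a
Kruskal-Wallis omnibus test, then — only when the omnibus p is below
`alpha` (default 0.05) — all pairwise two-sided Wilcoxon rank-sum tests with
a Bonferroni factor equal to the number of pairs actually tested. The exact
null distribution is used whenever both group sizes are at most 10, which
keeps the exact path active for the design sizes this package targets; ties
fall back to the normal approximation with continuity correction. The
non-parametric branch is always computed regardless of the normality
checks — with n = 3 per group a normality test has essentially no power, so
branching on it would be theatre. A parametric ANOVA branch is deliberately
absent.

Note a structural consequence of exact tests at small n: with 3 observations
per group the smallest attainable two-group p-value is 0.1, so after a
15-pair Bonferroni correction *no* pair can reach significance — pairwise
discrimination at that depth needs either more replicates or unaveraged
technical reactions. The aggregation level is the caller's choice of input.

# Consensus aggregation

Each stability table is converted to a full ranking (ties broken
alphabetically; missing statistics rank last) and the consensus is the
permutation minimizing the summed, optionally weighted, Spearman footrule
distance to the inputs. Because the footrule objective decomposes as
`Σ cost(gene, position)` with
`cost(g, p) = Σ_lists w · |p − rank_list(g)|`, the exact optimum is a linear
assignment problem; `aggregate_exact()` solves it with a Hungarian
(shortest-augmenting-path, O(k³)) solver and can verify it against
exhaustive enumeration for panels of up to 10 genes. Objective ties are
resolved to the lexicographically smallest permutation — enumeration visits
permutations in lexicographic order, and the assignment route fixes
positions left to right with the alphabetically first gene that preserves
the optimal objective, so both routes return the identical answer.

`aggregate_cemc()` is the Cross-Entropy Monte Carlo heuristic for larger
panels: a k×k gene-by-position probability matrix, initially uniform, is
iteratively re-estimated from the best `rho` fraction (default 0.1) of
`N = 10k²` sampled permutations and blended with its predecessor using
smoothing weight `w = 0.25` (weight on the previous matrix; it also keeps
all probabilities positive so no position can degenerate). Sampling is
position-by-position without replacement, implemented with the Gumbel-max
trick so all N permutations are drawn in parallel. Iteration stops after 7
rounds without improvement of the best objective seen, or at 1000 rounds.
These defaults mirror the documented defaults of the rank-aggregation
literature; all are exposed through `ce_params()`. The optimizer is seeded
explicitly, restores the caller's RNG state, and reports its full trace.
Input lists must be complete permutations of a common gene set — top-k lists
have materially different semantics and are rejected rather than imputed.

# The synthetic-data generator

`simulation_spec()` encodes the study design the package targets: two lines
analysed independently, nine genes with gene-specific efficiencies set near
values typical of optimised SYBR-green assays (1.61–1.83), six sample groups
(flower stages A–D, leaf stages A and C), 3 biological × 3 technical
replicates. The true log2 quantity of gene g in biological replicate b of
group G is `base_g + δ(g,G) + N(0, σ_bio,g)` and each technical replicate
observes `CT = ct0 − q/log2(E_g) + N(0, σ_tech)`. Defaults: σ_tech = 0.15
cycles (technical noise is instrument-dominated, so it is shared across
genes by default), σ_bio = 0.25 log2 units, δ = 0 (a null study); a planted
δ spread makes a gene genuinely unstable, and the generator records the
composite truth score `range(δ) + 2σ_bio` whose ordering the recovery tests
check. `simulate_curves()` additionally grows each reaction's amplicon count
through the discrete logistic `N(c+1) = N(c)(1 + (E−1)(1 − N(c)/K))` — so an
exponential phase with known per-cycle gain exists by construction — and
reads it out as fluorescence with a linear background and Gaussian read
noise (default 0.2 % of plateau). The reaction table accompanying simulated
curves is produced by actually calling `call_ct()` on each curve, making the
two representations consistent by construction. Starting template is
`n0_scale · 2^q` with `n0_scale = 8` molecules, which with the default base
abundances puts CTs in a realistic 17–30 cycle range and keeps the baseline
window free of signal.

What the generator does **not** model: amplification inhibitors,
primer-dimer artefacts, plate-position and inter-run effects, melting
behaviour, or heavy-tailed replicate outliers. Passing the recovery tests
therefore demonstrates that the statistics identify the planted
instabilities under idealised Gaussian noise, not that they are robust to
every pathology of real plates.

# Numerical and testing choices

Degenerate inputs are handled explicitly rather than by accident:
proportional RQ panels give exactly zero M/CV and alphabetical tie-breaks;
zero-variance genes are flagged in BestKeeper; γ² and σ² are floored at
zero and a 0/0 shrinkage factor is defined as no shrinkage. Oracle
comparisons in the test suite run at 1e−12 where the quantity is a finite
recombination of doubles, and at the scientifically meaningful tolerance
(±0.05 cycles for CT interpolation against a dense-grid oracle, ±0.05 for
noiseless efficiency recovery) where discretisation is inherent. Simulation
sizes in the suite — 50–100 seeds for rank-recovery rates, 500 replicates
for the type-I error of the testing cascade, n = 6000 for the
variance-estimator consistency check — were chosen so each Monte-Carlo
assertion has comfortable margin over its threshold while the whole suite
stays quick to run.

# Limitations

* BestKeeper's descriptive extras (per-gene CV %, x-fold ranges) and
  NormFinder's best-two-gene combination statistic are not implemented; the
  per-gene statistics used for ranking are.
* Standard-curve (dilution-series) efficiency estimation and melting-curve
  analytics are out of scope; efficiencies come from single curves or are
  supplied by the user.
* Exact aggregation is limited to 10 genes in exhaustive mode; the
  assignment solver and the Cross-Entropy optimizer scale far beyond that.
* Instrument-native binary exports are not parsed; data enter as CSV.
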