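Package: refstab
Title: Reference-Gene Stability Assessment for Quantitative PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation of candidate reference (housekeeping) genes for
    quantitative real-time PCR normalisation. Implements the complete analysis
    chain from raw amplification fluorescence to a consensus gene ranking:
    threshold-based cycle-threshold (CT) calling, single-curve PCR efficiency
    estimation at the second-derivative maximum, technical-replicate quality
    control, efficiency-corrected relative quantification, the geNorm M value
    with stepwise exclusion and pairwise-variation analysis, qBase-style M and
    coefficient-of-variation statistics, the BestKeeper index correlation,
    the NormFinder variance-components stability value, non-parametric
    group-difference testing, and unweighted rank aggregation under the
    Spearman footrule distance solved exactly (exhaustive search or assignment
    reduction) or heuristically by a Cross-Entropy Monte Carlo optimizer.
    Includes a synthetic-data generator emulating a two-line, six-group qPCR
    study design for validation of every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
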