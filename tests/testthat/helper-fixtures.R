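# shared fixture builders; everything is generated in code

# small rq matrix with named genes/samples; values given column by column
toy_rq <- function(values, genes) {
  n <- length(values) / length(genes)
  matrix(values, nrow = length(genes),
         dimnames = list(genes, paste0("s", seq_len(n))))
}

# a 3 genes x 4 samples matrix used across the geNorm/qBase oracle tests
toy_rq_3x4 <- function() {
  toy_rq(c(1.00, 0.80, 0.90,
           0.50, 0.44, 0.60,
           0.25, 0.20, 0.35,
           0.80, 0.70, 0.95),
         genes = c("g1", "g2", "g3"))
}

# brute-force geNorm M oracle: enumerates pairs, sd computed via the
# two-pass mean/sum-of-squares formula (different summation order from sd())
oracle_genorm_m <- function(m) {
  k <- nrow(m)
  sapply(rownames(m), function(j) {
    vs <- c()
    for (l in rownames(m)) {
      if (l == j) next
      a <- log2(m[j, ] / m[l, ])
      mu <- sum(a) / length(a)
      ss <- 0
      for (x in a) ss <- ss + (x - mu)^2
      vs <- c(vs, sqrt(ss / (length(a) - 1)))
    }
    mean(vs)
  })
}

# reaction table with n_tech technical replicates around given means
make_triplicates <- function(cts, gene = "g", line = "L", organ = "flower",
                             stage = "A", bio_rep = 1) {
  data.frame(line = line, organ = organ, stage = stage, bio_rep = bio_rep,
             tech_rep = seq_along(cts), gene = gene, ct = cts,
             efficiency = 2, qc_flags = "", stringsAsFactors = FALSE)
}

# noiseless default curve parameters
quiet_curve <- function(...) {
  cp <- simulation_spec(curve = list(noise = 0, ...))$curve
  cp
}

random_permutations <- function(k, n, items = LETTERS[seq_len(k)]) {
  replicate(n, sample(items), simplify = FALSE)
}
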