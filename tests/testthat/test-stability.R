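test_that("geNorm M vanishes on proportional genes and matches the pair oracle", {
  base <- c(1, 2, 4, 8)
  m <- rbind(a = base, b = 3 * base, c = 0.5 * base)
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unname(genorm_m(m)), c(0, 0, 0))

  toy <- toy_rq_3x4()
  expect_equal(genorm_m(toy), oracle_genorm_m(toy), tolerance = 1e-12)
})

test_that("geNorm M is invariant to rescaling one gene's column", {
  toy <- toy_rq_3x4()
  m0 <- genorm_m(toy)
  toy["g2", ] <- toy["g2", ] * 7
  expect_equal(genorm_m(toy), m0, tolerance = 1e-12)
})

test_that("stepwise exclusion removes the only incoherent gene first", {
  set.seed(42)
  base <- exp(rnorm(10))
  m <- rbind(a = base, b = 2 * base, c = 0.25 * base,
             w = exp(cumsum(rnorm(10, 0, 0.8))))
  colnames(m) <- paste0("s", 1:10)
  gs <- genorm_stepwise(m)
  expect_equal(gs$trace[[1]]$excluded, "w")
  expect_equal(tail(gs$ranking, 1), "w")
  # full-panel M equals the M of the first step of the trace
  expect_equal(gs$trace[[1]]$m_values, genorm_m(m), tolerance = 1e-12)
})

test_that("all-proportional panels resolve ties alphabetically", {
  base <- c(1, 2, 4, 8)
  m <- rbind(d = base, b = 2 * base, c = 4 * base, a = 8 * base)
  colnames(m) <- paste0("s", 1:4)
  gs <- genorm_stepwise(m)
  # alphabetically-first tied gene excluded each step -> last two survive
  expect_equal(gs$final_pair, c("c", "d"))
  expect_true(all(vapply(gs$trace, `[[`, TRUE, "tie")))
})

test_that("exclusion order recovers a planted noise ladder", {
  genes <- paste0("g", 1:6)
  sigmas <- seq(0.05, 1.0, length.out = 6)
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    m <- t(vapply(seq_along(genes),
                  function(i) exp(rnorm(20, 0, sigmas[i])),
                  numeric(20)))
    rownames(m) <- genes; colnames(m) <- paste0("s", 1:20)
    gs <- genorm_stepwise(m)
    # the two noisiest genes should occupy the two last ranks
    if (all(tail(gs$ranking, 2) %in% c("g5", "g6"))) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("pairwise variation is zero for proportional panels and matches a direct oracle", {
  base <- c(1, 2, 4, 8)
  m <- rbind(a = base, b = 2 * base, c = 4 * base)
  colnames(m) <- paste0("s", 1:4)
  pv <- pairwise_variation(m, ranking = c("a", "b", "c"))
  expect_equal(unname(pv$v), 0)
  expect_equal(pv$recommended_n, 2L)

  # 5-gene toy with rq powers of 2: spreadsheet-style recomputation
  set.seed(7)
  m <- matrix(2^sample(-3:6, 30, replace = TRUE), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  ranking <- paste0("g", 1:5)
  pv <- pairwise_variation(m, ranking)
  oracle <- sapply(2:4, function(n) {
    nf_n <- apply(m[ranking[1:n], , drop = FALSE], 2,
                  function(x) prod(x)^(1 / n))
    nf_n1 <- apply(m[ranking[1:(n + 1)], , drop = FALSE], 2,
                   function(x) prod(x)^(1 / (n + 1)))
    sd(log2(nf_n / nf_n1))
  })
  expect_equal(unname(pv$v), oracle, tolerance = 1e-12)
})

test_that("V series and recommended n follow the cutoff convention", {
  # build a panel whose V(2/3) is already below 0.15
  study <- simulate_ct_table(simulation_spec(lines = "Mitchell"), seed = 21)
  qc <- suppressMessages(filter_technical_replicates(study$reactions))
  rq <- compute_rq(average_replicates(qc$kept))
  gs <- genorm_stepwise(rq)
  pv <- pairwise_variation(rq, gs$ranking)
  if (pv$v[1] < 0.15) expect_equal(pv$recommended_n, 2L)
  expect_true(all(pv$v >= 0))
})

test_that("pairwise variation is invariant to per-gene rescaling", {
  toy <- toy_rq_3x4()
  pv0 <- pairwise_variation(toy, ranking = c("g1", "g2", "g3"))
  toy2 <- toy * c(5, 0.1, 19)
  pv1 <- pairwise_variation(toy2, ranking = c("g1", "g2", "g3"))
  expect_equal(pv1$v, pv0$v, tolerance = 1e-12)
})

test_that("qBase CV is zero for a gene tracking the panel NF and scale-invariant", {
  base <- c(1, 2, 4, 8)
  # gene a is the geometric mean of b and c, hence equals the panel NF exactly
  m <- rbind(a = sqrt(2 * base * 0.5 * base), b = 2 * base, c = 0.5 * base)
  colnames(m) <- paste0("s", 1:4)
  res <- qbase_m_cv(m)
  expect_equal(unname(res$cv["a"]), 0, tolerance = 1e-12)

  toy <- toy_rq_3x4()
  cv0 <- qbase_m_cv(toy)$cv
  toy["g3", ] <- toy["g3", ] * 11
  expect_equal(qbase_m_cv(toy)$cv["g3"], cv0["g3"], tolerance = 1e-12)
})

test_that("qBase CV matches a cell-wise oracle on the 3 x 4 toy", {
  toy <- toy_rq_3x4()
  res <- qbase_m_cv(toy)
  nf <- apply(toy, 2, function(x) prod(x)^(1 / nrow(toy)))
  for (g in rownames(toy)) {
    nrq <- toy[g, ] / nf
    expect_equal(unname(res$cv[g]), sd(nrq) / mean(nrq), tolerance = 1e-12)
  }
  # qBase M is the full-panel geNorm M, no exclusion
  expect_equal(res$m, genorm_m(toy), tolerance = 1e-15)
})

test_that("BestKeeper index and correlations behave as defined", {
  ct <- matrix(rep(c(18, 20, 22, 24), each = 3), 3, byrow = FALSE,
               dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  bk <- bestkeeper(ct)
  expect_equal(bk$index, ct["a", ])
  expect_equal(unname(bk$r), c(1, 1, 1))

  set.seed(3)
  m <- rbind(a = c(18, 19, 20, 21, 22), b = c(18.1, 19.2, 20.1, 21.3, 21.9),
             shuffled = c(20.8, 18.2, 21.1, 19.5, 18.9))
  colnames(m) <- paste0("s", 1:5)
  bk <- bestkeeper(m)
  expect_equal(names(which.min(bk$r2)), "shuffled")
  # Pearson oracle
  idx <- exp(colMeans(log(m)))
  expect_equal(unname(bk$r["a"]), cor(m["a", ], idx), tolerance = 1e-12)

  # mirroring a gene around its mean flips r but r^2 is still reported
  m3 <- rbind(a = c(18, 19, 20, 21, 22), b = c(18.2, 18.9, 20.1, 21.2, 21.8),
              c = c(17.9, 19.1, 19.9, 20.8, 22.1),
              mirrored = 40 - c(18, 19, 20, 21, 22))
  colnames(m3) <- paste0("s", 1:5)
  bk3 <- bestkeeper(m3)
  expect_lt(bk3$r["mirrored"], 0)
  expect_equal(bk3$r2["mirrored"], bk3$r["mirrored"]^2)
  # ranking by r^2 would still place it by magnitude, per the r^2 rule
  expect_gt(bk3$r2["mirrored"], 0.9)
})

test_that("BestKeeper handles zero-variance genes and joint sample reordering", {
  m <- rbind(a = c(18, 19, 20, 21), flat = c(20, 20, 20, 20))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(bk <- bestkeeper(m), "flat")
  expect_true(is.na(bk$r2["flat"]))

  set.seed(8)
  m <- matrix(runif(20, 18, 25), 4,
              dimnames = list(letters[1:4], paste0("s", 1:5)))
  perm <- sample(5)
  expect_equal(sort(bestkeeper(m[, perm])$r2), sort(bestkeeper(m)$r2),
               tolerance = 1e-12)
})

test_that("NormFinder is zero on degenerate input and honours its preconditions", {
  y <- matrix(5, 4, 12, dimnames = list(letters[1:4], NULL))
  groups <- rep(c("A", "B", "C"), each = 4)
  nf <- normfinder(y, groups)
  expect_equal(unname(nf$stability), rep(0, 4))
  expect_error(normfinder(y[1:2, ], groups), "3 genes")
  expect_error(normfinder(y, rep(c("A", "B"), c(11, 1))), "2 samples")
})

test_that("NormFinder is invariant to per-sample and per-gene additive shifts", {
  set.seed(10)
  y <- matrix(rnorm(9 * 12, 5, 1), 9, dimnames = list(paste0("g", 1:9), NULL))
  groups <- rep(c("A", "B", "C", "D"), each = 3)
  s0 <- normfinder(y, groups)$stability
  # per-sample constants are absorbed by sample centring
  y1 <- sweep(y, 2, rnorm(12, 0, 5), "+")
  expect_equal(normfinder(y1, groups)$stability, s0, tolerance = 1e-10)
  # per-gene constants are absorbed by group-mean differencing
  y2 <- sweep(y, 1, rnorm(9, 0, 5), "+")
  expect_equal(normfinder(y2, groups)$stability, s0, tolerance = 1e-10)
})

test_that("with a single group NormFinder ranks by intragroup standard error", {
  set.seed(11)
  y <- matrix(rnorm(5 * 30, 0, rep(c(0.1, 0.3, 0.5, 0.8, 1.2), 30)), 5,
              dimnames = list(paste0("g", 1:5), NULL))
  groups <- rep("all", 30)
  nf <- normfinder(y, groups)
  expect_equal(order(nf$stability), order(sqrt(nf$intra[, 1] / 30)))
  expect_equal(unname(nf$stability), unname(sqrt(nf$intra[, 1] / 30)),
               tolerance = 1e-12)
})

test_that("a gene with a large intergroup shift gets the worst stability value", {
  genes <- paste0("g", 1:6)
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    y <- matrix(rnorm(6 * 18, 0, 0.3), 6, dimnames = list(genes, NULL))
    groups <- rep(c("A", "B", "C"), each = 6)
    y["g4", groups == "B"] <- y["g4", groups == "B"] + 2
    if (names(which.max(normfinder(y, groups)$stability)) == "g4") hits <- hits + 1
  }
  expect_gte(hits, 47)
})

test_that("stability tables rank by statistic under their direction", {
  st <- stability_table(c(b = 0.3, a = 0.1, c = 0.2), "m", "lower_is_stable")
  expect_equal(st$gene, c("a", "c", "b"))
  st <- stability_table(c(b = 0.3, a = 0.1, c = NA), "r2", "higher_is_stable")
  expect_equal(st$gene, c("b", "a", "c"))  # NA ranks last
  expect_equal(st$rank, 1:3)
})
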