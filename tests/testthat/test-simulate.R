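test_that("the generator is deterministic given (spec, seed)", {
  spec <- simulation_spec()
  expect_identical(simulate_ct_table(spec, seed = 5),
                   simulate_ct_table(spec, seed = 5))
  sp_small <- simulation_spec(lines = "Mitchell", n_bio = 1, n_tech = 1)
  expect_identical(simulate_curves(sp_small, seed = 5)$reactions,
                   simulate_curves(sp_small, seed = 5)$reactions)
})

test_that("default spec matches the two-line six-group study design", {
  spec <- simulation_spec()
  study <- simulate_ct_table(spec, seed = 1)
  expect_equal(nrow(study$reactions), 2 * 9 * 6 * 3 * 3)
  expect_setequal(unique(study$reactions$line), c("Mitchell", "V30"))
  expect_equal(length(spec$genes), 9)
  expect_true(all(spec$efficiency > 1.5 & spec$efficiency <= 2))
  expect_equal(sort(unique(paste(study$reactions$organ, study$reactions$stage))),
               c("flower A", "flower B", "flower C", "flower D",
                 "leaf A", "leaf C"))
})

test_that("the noiseless null study degenerates every stability statistic to zero", {
  spec <- simulation_spec(lines = "Mitchell",
                          sigma_bio = setNames(rep(0, 9), simulation_spec()$genes),
                          sigma_tech = 0)
  study <- simulate_ct_table(spec, seed = 2)
  # CT constant within and across groups up to per-gene base differences
  per_gene_var <- tapply(study$reactions$ct, study$reactions$gene, var)
  expect_true(all(per_gene_var < 1e-20))
  qc <- suppressMessages(filter_technical_replicates(study$reactions))
  rq <- compute_rq(average_replicates(qc$kept,
                                      refstab_control(efficiency_mode = "per_reaction")))
  expect_equal(unname(genorm_m(rq$rq)), rep(0, 9), tolerance = 1e-10)
  expect_equal(unname(qbase_m_cv(rq$rq)$cv), rep(0, 9), tolerance = 1e-10)
  nf <- normfinder(log2(rq$rq), rq$groups)
  expect_equal(unname(nf$stability), rep(0, 9), tolerance = 1e-10)
})

test_that("a planted unstable gene is ranked worst by three methods", {
  genes <- simulation_spec()$genes
  delta <- matrix(0, 9, 6, dimnames = list(genes, NULL))
  delta["GAPDH", ] <- c(-1, -0.5, 0, 0.5, 1, 0)  # 2.0 log2-unit spread
  spec <- simulation_spec(lines = "Mitchell", delta = delta)
  expect_equal(tail(spec$truth_ordering, 1), "GAPDH")
  hits <- 0
  for (seed in 1:60) {
    study <- simulate_ct_table(spec, seed)
    qc <- suppressMessages(filter_technical_replicates(study$reactions))
    rq <- compute_rq(average_replicates(qc$kept))
    worst_genorm <- tail(genorm_stepwise(rq)$ranking, 1)
    worst_nf <- names(which.max(normfinder(log2(rq$rq), rq$groups)$stability))
    worst_cv <- names(which.max(qbase_m_cv(rq)$cv))
    if (worst_genorm == "GAPDH" && worst_nf == "GAPDH" && worst_cv == "GAPDH")
      hits <- hits + 1
  }
  expect_gte(hits, 57)
})

test_that("curve-based and table-based CTs are mutually consistent", {
  sp <- simulation_spec(lines = "Mitchell", n_bio = 1, n_tech = 1)
  sim <- simulate_curves(sp, seed = 31,
                         control = refstab_control(efficiency_mode = "per_reaction"))
  # reaction CTs come from calling the generated curves
  recalled <- vapply(seq_along(sim$curves), function(i) {
    call_ct(sim$curves[[i]])
  }, 0)
  expect_equal(unname(recalled), sim$reactions$ct, tolerance = 1e-12)
  # and they respect the analytic CT model up to a per-gene offset:
  # halving the template shifts the called CT by 1/log2(E)
  cp <- quiet_curve()
  for (e in c(1.62, 1.75)) {
    ct1 <- call_ct(simulate_curve(e, 800, cp))
    ct2 <- call_ct(simulate_curve(e, 400, cp))
    expect_equal(ct2 - ct1, 1 / log2(e), tolerance = 0.05)
  }
})

test_that("true efficiencies are recoverable from simulated curves", {
  cp <- simulation_spec()$curve  # default read noise
  set.seed(17)
  ok <- 0
  for (i in 1:50) {
    est <- estimate_efficiency(simulate_curve(1.7, 1000, cp))$e
    if (!is.na(est) && abs(est - 1.7) <= 0.1) ok <- ok + 1
  }
  expect_gte(ok, 47)
})

test_that("pipelines on paired curve and table simulations agree on extremes", {
  genes <- simulation_spec()$genes
  delta <- matrix(0, 9, 6, dimnames = list(genes, NULL))
  delta["GAPDH", ] <- c(-1, -0.5, 0, 0.5, 1, 0)
  delta["SAND", ] <- c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5)
  spec <- simulation_spec(lines = "Mitchell", delta = delta,
                          sigma_bio = setNames(rep(0.1, 9), genes),
                          sigma_tech = 0.05)
  ctl <- refstab_control(efficiency_mode = "per_reaction")
  agree <- 0
  for (seed in 1:5) {
    sim_c <- simulate_curves(spec, seed = seed, control = ctl)
    sim_t <- simulate_ct_table(spec, seed = seed)
    fit_c <- refstab(sim_c$reactions, control = ctl, seed = 1, subsets = FALSE)
    fit_t <- refstab(sim_t$reactions, control = ctl, seed = 1, subsets = FALSE)
    rank_c <- fit_c$lines$Mitchell$genorm$ranking
    rank_t <- fit_t$lines$Mitchell$genorm$ranking
    # the two planted unstable genes occupy the two last ranks in both runs,
    # with the heavier perturbation last
    if (setequal(tail(rank_c, 2), c("GAPDH", "SAND")) &&
        setequal(tail(rank_t, 2), c("GAPDH", "SAND")) &&
        tail(rank_c, 1) == tail(rank_t, 1)) agree <- agree + 1
  }
  expect_gte(agree, 4)
})
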