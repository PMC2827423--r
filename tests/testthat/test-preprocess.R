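test_that("technical-replicate groups are kept iff CT range < max_range", {
  kept_grp <- make_triplicates(c(20.1, 20.4, 20.9))
  bad_grp <- make_triplicates(c(20.1, 20.4, 21.2), gene = "h")
  both <- rbind(kept_grp, bad_grp)
  res <- suppressMessages(filter_technical_replicates(both, max_range = 1))
  expect_equal(unique(res$kept$gene), "g")       # range 0.8 < 1 survives
  expect_equal(unique(res$discarded$gene), "h")  # range 1.1 >= 1 discarded
  expect_true(all(res$discarded$qc_flags == "replicate_spread"))

  # boundary: range exactly equal to max_range is discarded (strict rule)
  edge <- make_triplicates(c(20.0, 20.5, 21.0))
  res <- suppressMessages(filter_technical_replicates(edge, max_range = 1))
  expect_equal(nrow(res$kept), 0)
})

test_that("groups with no amplification at all are discarded with the right flag", {
  g <- make_triplicates(c(NA, NA, NA))
  g$qc_flags <- "no_amplification"
  res <- suppressMessages(filter_technical_replicates(g, 1))
  expect_equal(nrow(res$kept), 0)
  expect_true(all(res$discarded$qc_flags == "no_amplification"))
})

test_that("replicate averaging is the arithmetic CT mean", {
  r1 <- make_triplicates(c(20.0, 20.2, 20.4))
  cm <- average_replicates(r1)
  expect_equal(unname(cm$ct["g", 1]), 20.2)
  r2 <- make_triplicates(c(18.0, 18.6))
  expect_equal(unname(average_replicates(r2)$ct["g", 1]), 18.3)
})

test_that("the full synthetic design averages to a complete 9 x 18 matrix", {
  study <- simulate_ct_table(simulation_spec(lines = "Mitchell"), seed = 9)
  qc <- suppressMessages(filter_technical_replicates(study$reactions))
  cm <- average_replicates(qc$kept)
  expect_equal(dim(cm$ct), c(9, 18))
  expect_false(anyNA(cm$ct))
  expect_equal(length(unique(cm$groups)), 6)
})

test_that("incomplete genes and samples are dropped with warnings", {
  study <- simulate_ct_table(simulation_spec(lines = "Mitchell"), seed = 9)
  reactions <- study$reactions
  # remove one gene from most samples: gene dropped
  drop <- reactions$gene == "ACT" & !(reactions$bio_rep == 1 & reactions$stage == "A")
  expect_warning(average_replicates(reactions[!drop, , drop = FALSE]),
                 "ACT")
})

test_that("RQ follows the efficiency-corrected delta-Ct rule", {
  cts <- matrix(c(20, 21, 22.5), 1, dimnames = list("g", c("s1", "s2", "s3")))
  cm <- structure(list(ct = cts,
                       efficiency = matrix(2, 1, 3, dimnames = dimnames(cts)),
                       samples = data.frame(line = "L", organ = "flower",
                                            stage = c("A", "B", "C"), bio_rep = 1),
                       groups = c("A", "B", "C")),
                  class = "ct_matrix")
  rq <- compute_rq(cm)
  expect_equal(unname(rq$rq["g", ]), c(1, 0.5, 2^-2.5))

  cm$efficiency[] <- 1.7
  rq <- compute_rq(cm)
  expect_equal(unname(rq$rq["g", 3]), 1.7^-2.5)
  # frozen from a 30-digit arbitrary-precision evaluation of 1.7^(-2.5)
  expect_equal(unname(rq$rq["g", 3]), 0.265385809289748, tolerance = 1e-12)
  # the reference sample (lowest CT) sits at RQ = 1
  expect_equal(max(rq$rq["g", ]), 1)
})

test_that("RQ is invariant to adding a constant to one gene's CTs", {
  study <- simulate_ct_table(simulation_spec(lines = "Mitchell"), seed = 4)
  qc <- suppressMessages(filter_technical_replicates(study$reactions))
  cm <- average_replicates(qc$kept)
  rq0 <- compute_rq(cm)
  cm$ct["CYP", ] <- cm$ct["CYP", ] + 3.17
  rq1 <- compute_rq(cm)
  expect_equal(rq1$rq["CYP", ], rq0$rq["CYP", ], tolerance = 1e-12)
})

test_that("fixed efficiency 2 reduces RQ to the classical 2^(-dCt)", {
  study <- simulate_ct_table(simulation_spec(lines = "Mitchell"), seed = 4)
  qc <- suppressMessages(filter_technical_replicates(study$reactions))
  cm <- average_replicates(qc$kept, refstab_control(efficiency_mode = "fixed"))
  rq <- compute_rq(cm)
  dct <- cm$ct - apply(cm$ct, 1, min)
  expect_equal(rq$rq, 2^(-dct), tolerance = 1e-12)
})

test_that("efficiency <= 1 is a hard error naming the cell", {
  cts <- matrix(c(20, 21), 1, dimnames = list("g", c("a", "b")))
  cm <- structure(list(ct = cts,
                       efficiency = matrix(1, 1, 2, dimnames = dimnames(cts)),
                       samples = data.frame(line = "L", organ = "f",
                                            stage = c("A", "B"), bio_rep = 1),
                       groups = c("A", "B")),
                  class = "ct_matrix")
  expect_error(compute_rq(cm), "g")
})
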