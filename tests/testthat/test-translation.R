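test_that("gene read counting follows the overlap/ambiguity rules", {
  models <- tibble::tibble(gene_id = c("gA", "gB"),
                           seqname = c("gA", "gB"), strand = "+",
                           start = 0L, end = c(500L, 300L),
                           length = c(500L, 300L))
  reads <- tibble::tibble(qname = paste0("r", 1:3),
                          ref = c("gA", "gA", "gB"),
                          start = c(10L, 450L, 0L),
                          seq = strrep("A", 50), qual = strrep("I", 50))
  rc <- gene_read_counts(reads, models)
  expect_equal(rc$read_count, c(2L, 1L))
  expect_error(gene_read_counts(reads, models[0, ]),
               class = "stamper_input_error")
  # brute-force overlap oracle on random reads over a shared reference
  models2 <- tibble::tibble(gene_id = c("g1", "g2"),
                            seqname = "chr", strand = "+",
                            start = c(0L, 400L), end = c(450L, 900L),
                            length = c(450L, 500L))
  set.seed(31)
  reads2 <- tibble::tibble(qname = paste0("r", 1:50), ref = "chr",
                           start = sample(0:800, 50, TRUE),
                           seq = strrep("A", 100), qual = strrep("I", 100))
  rc2 <- gene_read_counts(reads2, models2)
  ov <- function(s, e, gs, ge) s < ge & e > gs
  in1 <- ov(reads2$start, reads2$start + 100, 0, 450)
  in2 <- ov(reads2$start, reads2$start + 100, 400, 900)
  expect_equal(rc2$read_count, c(sum(in1 & !in2), sum(in2 & !in1)))
  expect_equal(attr(rc2, "ambiguous"), sum(in1 & in2))
})

test_that("EPR arithmetic and the min-reads floor behave", {
  ec <- tibble::tibble(gene_id = c("gA", "gB"), edit_count = c(30L, 0L))
  rc <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                       read_count = c(300L, 50L, 5L))
  out <- edits_per_read(ec, rc, min_reads = 10)
  expect_equal(out$epr[out$gene_id == "gA"], 0.1)
  expect_equal(out$epr[out$gene_id == "gB"], 0)
  expect_false("gC" %in% out$gene_id)
})

test_that("per-gene summaries match the simulator truth", {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = 15, target_fraction = 0, seed = 32))
  sim <- simulate_translation(tx, depth = 40, n_reps = 2, error_rate = 0,
                              seed = 33)
  summ <- epr_summaries(sim, min_confidence = 0.5)
  # truth-table oracle: edits per gene from the per-read truth records
  sr <- sim$control[[1]]
  truth_edits <- table(factor(sr$truth$read_edits$ref,
                              levels = tx$models$gene_id))
  truth_reads <- table(factor(sr$reads$ref, levels = tx$models$gene_id))
  got <- summ[summ$condition == "control" & summ$replicate == 1, ]
  for (g in got$gene_id) {
    expect_equal(got$read_count[got$gene_id == g],
                 as.integer(truth_reads[[g]]))
    # confident calls can only miss truth edits (coverage floor), never
    # invent them (error-free reads)
    expect_lte(got$edit_count[got$gene_id == g], truth_edits[[g]])
    expect_gte(got$edit_count[got$gene_id == g],
               0.8 * truth_edits[[g]])
  }
  # per-gene EPR tracks the generator's expectation
  exp_epr <- sim$truth$expected_epr
  joined <- merge(got, exp_epr[exp_epr$condition == "control", ],
                  by = "gene_id")
  expect_lt(median(abs(joined$epr - joined$expected_epr) /
                     joined$expected_epr), 0.25)
})

test_that("fold-change statistics equal the closed-form Welch test", {
  summ <- tidyr::expand_grid(gene_id = c("gA", "gB"),
                             condition = c("control", "treated"),
                             replicate = 1:3)
  eprs <- c(0.10, 0.11, 0.09, 0.05, 0.06, 0.05,   # gA ctrl, gA trt
            0.20, 0.21, 0.19, 0.20, 0.19, 0.21)   # gB ctrl, gB trt
  summ$epr <- eprs
  cmp <- epr_fold_change(summ, fdr = 0.05)
  a <- cmp[cmp$gene_id == "gA", ]
  expect_equal(a$t, oracle_welch_t(c(0.05, 0.06, 0.05),
                                   c(0.10, 0.11, 0.09)), tolerance = 1e-10)
  expect_equal(a$log2_fc,
               log2(mean(c(0.05, 0.06, 0.05)) + 1e-6) -
                 log2(mean(c(0.10, 0.11, 0.09)) + 1e-6))
  expect_equal(a$call, "decrease")
  b <- cmp[cmp$gene_id == "gB", ]
  expect_equal(b$call, "ns")
  expect_equal(cmp$q_value, bh_adjust(cmp$p_value))
  # identical replicate EPRs in both conditions: log2FC 0, ns, p = 1
  flat <- summ
  flat$epr <- 0.1
  cf <- epr_fold_change(flat)
  expect_equal(cf$log2_fc, c(0, 0))
  expect_equal(cf$p_value, c(1, 1))
  expect_equal(cf$call, c("ns", "ns"))
})

test_that("halved EPR across replicates gives log2 fold change near -1", {
  summ <- tidyr::expand_grid(gene_id = "g", condition = c("control",
                                                          "treated"),
                             replicate = 1:3)
  summ$epr <- c(0.2, 0.201, 0.199, 0.1, 0.101, 0.099)
  cmp <- epr_fold_change(summ)
  expect_equal(cmp$log2_fc, -1, tolerance = 0.01)
})

test_that("group contrast matches the two-sample formula and flags direction", {
  cmp <- tibble::tibble(gene_id = paste0("g", 1:20),
                        log2_fc = c(rep(-2, 10) + rnorm(10, 0, 0.01),
                                    rep(0, 10) + rnorm(10, 0, 0.01)))
  gc <- group_contrast(cmp, paste0("g", 1:10))
  expect_equal(gc$t, oracle_welch_t(cmp$log2_fc[1:10], cmp$log2_fc[11:20]),
               tolerance = 1e-10)
  expect_gt(gc$t_decrease, 0)   # the group decreases more
  expect_lt(gc$p_value, 1e-6)
  set.seed(77)
  same <- tibble::tibble(gene_id = paste0("g", 1:10),
                         log2_fc = rnorm(10, -0.5, 0.05))
  gs <- group_contrast(same, paste0("g", c(1, 3, 5, 7, 9)))
  expect_lt(abs(gs$t), 3)
  expect_error(group_contrast(cmp, "absent"),
               class = "stamper_input_error")
  expect_error(group_contrast(cmp, paste0("g", 1:20)),
               class = "stamper_input_error")
})

test_that("region EPR ratio reports ratio of means and per-gene ratios", {
  summ <- tibble::tibble(
    gene_id = paste0("g", 1:5), condition = "control", replicate = 1L,
    epr_cds = c(0.2, 0.4, 0.3, 0.1, 0.5),
    epr_utr3 = c(0.1, 0.2, 0.15, 0.05, 0.25))
  rr <- region_epr_ratio(summ)
  expect_equal(rr$ratio_of_means, mean(summ$epr_cds) / mean(summ$epr_utr3))
  expect_equal(rr$per_gene$ratio, rep(2, 5))
  eq <- dplyr::mutate(summ, epr_cds = epr_utr3)
  expect_equal(region_epr_ratio(eq)$ratio_of_means, 1)
  zero <- dplyr::mutate(summ, epr_utr3 = 0)
  expect_error(region_epr_ratio(zero), class = "stamper_input_error")
})

test_that("null translation condition shows no systematic EPR shift", {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = 25, target_fraction = 0, seed = 35))
  loads <- stats::setNames(rep(1, 25), tx$models$gene_id)
  sim <- simulate_translation(tx, loads_control = loads,
                              loads_treated = loads, depth = 20,
                              n_reps = 2, seed = 36)
  summ <- epr_summaries(sim)
  cmp <- epr_fold_change(summ)
  expect_lt(abs(mean(cmp$log2_fc)), 0.1)
})
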