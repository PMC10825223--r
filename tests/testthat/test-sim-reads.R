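test_that("with no enzymes and no errors, reads are reference substrings", {
  ref <- c(chr = random_dna_str(400, seed = 1))
  sr <- simulate_reads(ref, enzymes = list(), n_reads = 25,
                       read_length = 80, seed = 2, error_rate = 0)
  expect_equal(nrow(sr$reads), 25)
  expect_identical(sr$reads$seq,
                   unname(substr(rep(ref, 25), sr$reads$start + 1,
                                 sr$reads$start + 80)))
  expect_equal(nrow(sr$truth$read_edits), 0)
  expect_equal(nrow(sr$truth$errors), 0)
})

test_that("edited-read fraction at the kernel peak matches the peak rate", {
  # one bound site, uniform contexts, no background/errors: the substrate
  # base at the site midpoint is edited on each read with prob peak_rate
  ref <- c(chr = paste0(random_dna_str(60, seed = 3), "C",
                        random_dna_str(60, seed = 4)))
  bound <- tibble::tibble(ref = "chr", start = 55L, end = 66L,
                          enzyme = "enz")
  enz <- enzyme_model("enz", "C2U", peak_rate = 0.3, kernel_halfwidth = 30,
                      background_rate = 0)
  sr <- simulate_reads(ref, bound, list(enz), n_reads = 10000,
                       read_length = 100, seed = 5, error_rate = 0)
  mat <- pileup_counts(sr, ref)
  at_peak <- mat[mat$pos == 60, ]
  frac <- at_peak$T / at_peak$coverage
  sd3 <- 3 * sqrt(0.3 * 0.7 / at_peak$coverage)
  expect_lt(abs(frac - 0.3), sd3)
})

test_that("edits in emitted reads and truth records agree one-to-one", {
  tx <- simulate_transcriptome(transcriptome_spec(n_genes = 5, seed = 7))
  enz <- enzyme_model("enz", "DUAL", peak_rate = 0.3, kernel_halfwidth = 20,
                      background_rate = 0.01)
  bound <- dplyr::mutate(tx$truth$motif_sites[, c("ref", "start", "end")],
                         enzyme = "enz")
  sr <- simulate_reads(tx$sequences, bound, list(enz), n_reads = 600,
                       seed = 8, error_rate = 0)
  # dual enzymes carry both channels
  expect_setequal(unique(sr$truth$read_edits$edit_type), c("C2U", "A2I"))
  # conservation: every truth record corresponds to a changed base in the
  # emitted read, and every changed base has a truth record
  reads <- sr$reads
  changed <- 0L
  for (i in seq_len(nrow(reads))) {
    refseq <- substr(tx$sequences[[reads$ref[i]]], reads$start[i] + 1,
                     reads$start[i] + 100)
    diffs <- which(strsplit(reads$seq[i], "")[[1]] !=
                     strsplit(refseq, "")[[1]])
    changed <- changed + length(diffs)
    te <- sr$truth$read_edits[sr$truth$read_edits$qname == reads$qname[i], ]
    expect_setequal(te$pos, reads$start[i] + diffs - 1L)
  }
  expect_equal(changed, nrow(sr$truth$read_edits))
})

test_that("context weights shape where edits land", {
  # A/U-favoured enzyme at 10:1 should edit A/T-flanked substrates roughly
  # tenfold more often than G/C-flanked ones, per favourable position
  ref <- c(chr = random_dna_str(4000, seed = 10))
  enz <- enzyme_model("enz", "C2U", peak_rate = 0,
                      background_rate = 0.2,
                      context_weights = context_weights_biased("AT", 10))
  sr <- simulate_reads(ref, NULL, list(enz), n_reads = 4000,
                       read_length = 100, seed = 11, error_rate = 0)
  chars <- strsplit(ref[[1]], "")[[1]]
  ed <- sr$truth$read_edits
  flank <- function(p) paste0(chars[p], chars[p + 2])  # pos is 0-based
  ctx <- flank(ed$pos)
  at_pair <- function(x) x %in% c("AA", "AT", "TA", "TT")
  gc_pair <- function(x) x %in% c("GG", "GC", "CG", "CC")
  # normalise by the number of available C positions in each context class
  cpos <- which(chars == "C")
  cpos <- cpos[cpos > 1 & cpos < length(chars)]
  avail <- flank(cpos - 1L)
  rate_at <- sum(at_pair(ctx)) / sum(at_pair(avail))
  rate_gc <- sum(gc_pair(ctx)) / sum(gc_pair(avail))
  expect_gt(rate_at / rate_gc, 6)
  expect_lt(rate_at / rate_gc, 16)
})

test_that("binned edit fraction decays monotonically with site distance", {
  ref <- c(chr = random_dna_str(1200, seed = 12))
  bound <- tibble::tibble(ref = "chr", start = 595L, end = 605L,
                          enzyme = "enz")
  enz <- enzyme_model("enz", "C2U", peak_rate = 0.5, kernel_halfwidth = 60,
                      background_rate = 0)
  sr <- simulate_reads(ref, bound, list(enz), n_reads = 20000,
                       read_length = 100, seed = 13, error_rate = 0)
  ed <- sr$truth$read_edits
  d <- abs(ed$pos - 599.5)
  bins <- cut(d, breaks = c(0, 40, 80, 120, 160, 200), right = FALSE)
  counts <- as.numeric(table(bins))
  expect_true(all(diff(counts) < 0))
})

test_that("simulation is deterministic and writers are stable", {
  ref <- c(chr = random_dna_str(300, seed = 14))
  enz <- enzyme_model("enz", "C2U", background_rate = 0.02)
  a <- simulate_reads(ref, NULL, list(enz), n_reads = 50, read_length = 60,
                      seed = 15)
  b <- simulate_reads(ref, NULL, list(enz), n_reads = 50, read_length = 60,
                      seed = 15)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth$read_edits, b$truth$read_edits)
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  sa <- tempfile(fileext = ".sam"); sb <- tempfile(fileext = ".sam")
  write_fastq(a, fa); write_fastq(b, fb)
  write_sam(a, sa); write_sam(b, sb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(readLines(sa), readLines(sb))
  # FASTQ structure: 4 lines per read, sequence length as requested
  expect_equal(length(readLines(fa)), 200)
})

test_that("invalid simulation parameters raise configuration errors", {
  ref <- c(chr = random_dna_str(50, seed = 16))
  expect_error(simulate_reads(ref, n_reads = 5, read_length = 100, seed = 1),
               class = "stamper_config_error")
  expect_error(enzyme_model("x", "C2U", peak_rate = 1.5))
  expect_error(simulate_reads(ref, NULL, list(), n_reads = 5,
                              read_length = 20, seed = 1, error_rate = 2),
               class = "stamper_config_error")
})
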