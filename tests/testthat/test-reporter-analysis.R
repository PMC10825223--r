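test_that("per-position profile fractions follow the base counts", {
  sp <- build_reporter("MS2x12", seed = 2)
  len <- nchar(sp$full_seq)
  chars <- strsplit(sp$full_seq, "")[[1]]
  # synthetic counts: position i covered by 10 reads; C positions carry
  # 2 T reads, A positions 5 G reads
  m <- tibble::tibble(
    ref = sp$name, pos = 0:(len - 1L), ref_base = chars,
    A = ifelse(chars == "A", 5L, 0L),
    C = ifelse(chars == "C", 8L, 0L),
    G = ifelse(chars == "A", 5L, ifelse(chars == "G", 10L, 0L)),
    T = ifelse(chars == "C", 2L, ifelse(chars == "T", 10L, 0L)),
    coverage = 10L)
  prof <- profile_reporter(m, sp)
  expect_equal(nrow(prof), len)
  expect_equal(unique(prof$c2u_fraction[prof$ref_base == "C"]), 0.2)
  expect_equal(unique(prof$a2i_fraction[prof$ref_base == "A"]), 0.5)
  # non-substrate positions carry zero fractions
  expect_true(all(prof$c2u_fraction[prof$ref_base != "C"] == 0))
  expect_true(all(prof$a2i_fraction[prof$ref_base != "A"] == 0))
  # region and loop annotation line up with the construct
  expect_equal(prof$region[1], "CDS")
  expect_equal(sum(!is.na(prof$loop)), sum(sp$loop_intervals$end -
                                             sp$loop_intervals$start))
})

test_that("low-coverage positions are masked, not zeroed", {
  sp <- build_reporter("ALT4", seed = 2)
  cpos <- as.integer(regexpr("C", sp$full_seq)) - 1L  # first reference C
  m <- tibble::tibble(ref = sp$name, pos = cpos, ref_base = "C",
                      A = 0L, C = 2L, G = 0L, T = 1L, coverage = 3L)
  prof <- profile_reporter(m, sp, min_coverage = 5)
  row <- which(prof$pos == cpos)
  expect_true(is.na(prof$c2u_fraction[row]))
  expect_equal(prof$c2u_count[row], 1L)  # counts are still reported
})

test_that("profile rejects a matrix longer than the construct", {
  sp <- build_reporter("ALT4", seed = 2)
  m <- tibble::tibble(ref = sp$name, pos = nchar(sp$full_seq) + 5L,
                      ref_base = "C", A = 0L, C = 2L, G = 0L, T = 1L,
                      coverage = 3L)
  expect_error(profile_reporter(m, sp), class = "stamper_input_error")
})

test_that("spillover index is the CDS share of edited observations", {
  sp <- build_reporter("MS2x12", seed = 3)
  cds_len <- nchar(sp$cds_seq)
  chars <- strsplit(sp$full_seq, "")[[1]]
  cds_c <- which(chars[1:cds_len] == "C")[1:2] - 1L
  utr_c <- cds_len + which(chars[(cds_len + 1):length(chars)] == "C")[1] - 1L
  base <- tibble::tibble(ref = sp$name, pos = c(cds_c, utr_c),
                         ref_base = "C", A = 0L, C = 6L, G = 0L,
                         T = c(2L, 1L, 3L), coverage = 8L)
  prof <- profile_reporter(base, sp)
  expect_equal(spillover_index(prof), (2 + 1) / (2 + 1 + 3))
  # all edits in the UTR -> 0; all in CDS -> 1
  utr_only <- profile_reporter(base[3, ], sp)
  expect_equal(spillover_index(utr_only), 0)
  cds_only <- profile_reporter(base[1:2, ], sp)
  expect_equal(spillover_index(cds_only), 1)
  # no edits at all -> undefined, with a warning
  none <- profile_reporter(dplyr::mutate(base, T = 0L), sp)
  expect_warning(val <- spillover_index(none), "undefined")
  expect_true(is.na(val))
})

test_that("on/off ratio handles replicates, zeros and pooling", {
  r <- on_off_ratio(c(100, 0, 5), c(50, 10, 0))
  expect_equal(r$ratio[1:2], c(2, 0))
  expect_true(is.na(r$ratio[3]) && r$undefined[3])
  # pooled-counts mode equals ratio of summed counts
  pooled <- on_off_ratio(sum(c(100, 5)), sum(c(50, 10)))
  expect_equal(pooled$ratio, 105 / 60)
})

test_that("on/off ratio falls as off-target background rises", {
  sp <- build_reporter("MS2x12", seed = 5)
  tx <- simulate_transcriptome(transcriptome_spec(n_genes = 10,
                                                  target_fraction = 0,
                                                  seed = 6))
  ref <- c(stats::setNames(sp$full_seq, sp$name), tx$sequences)
  ratio_at <- function(bg) {
    enz <- enzyme_model("enz", "C2U", peak_rate = 0.3,
                        kernel_halfwidth = 25, background_rate = bg)
    sr <- simulate_reads(ref, reporter_bound_sites(sp, MS2 = "enz"),
                         list(enz), n_reads = 6000, seed = 7,
                         error_rate = 0)
    sites <- call_edits(pileup_counts(sr, ref), "C2U")
    on <- count_edit_observations(sites[sites$ref == sp$name, ], 0.9)
    off <- count_edit_observations(sites[sites$ref != sp$name, ], 0.9)
    on / max(off, 1)
  }
  expect_gt(ratio_at(2e-4), ratio_at(5e-3))
})

test_that("spillover grows with kernel halfwidth", {
  sp <- build_reporter("MS2x12", seed = 8)
  ref <- stats::setNames(sp$full_seq, sp$name)
  spill_at <- function(hw) {
    enz <- enzyme_model("enz", "C2U", peak_rate = 0.4,
                        kernel_halfwidth = hw, background_rate = 0)
    sr <- simulate_reads(ref, reporter_bound_sites(sp, MS2 = "enz"),
                         list(enz), n_reads = 6000, seed = 9,
                         error_rate = 0)
    prof <- profile_reporter(pileup_counts(sr, ref), sp)
    spillover_index(prof)
  }
  expect_gt(spill_at(80), spill_at(15))
})

test_that("dual-editor signals concentrate near their own loops", {
  sp <- build_reporter("ALT12", seed = 10)
  ref <- stats::setNames(sp$full_seq, sp$name)
  bs <- reporter_bound_sites(sp, MS2 = "mcp_c2u", PP7 = "pp7_a2i")
  enzC <- enzyme_model("mcp_c2u", "C2U", peak_rate = 0.4,
                       kernel_halfwidth = 15, background_rate = 0)
  enzA <- enzyme_model("pp7_a2i", "A2I", peak_rate = 0.4,
                       kernel_halfwidth = 15, background_rate = 0)
  sr <- simulate_reads(ref, bs, list(enzC, enzA), n_reads = 8000,
                       seed = 11, error_rate = 0)
  prof <- profile_reporter(pileup_counts(sr, ref), sp)
  loops <- sp$loop_intervals
  mid <- (loops$start + loops$end) / 2
  dist_to <- function(pos, kind) {
    vapply(pos, function(p) min(abs(p - mid[loops$kind == kind])),
           numeric(1))
  }
  c2u_pos <- prof$pos[!is.na(prof$c2u_fraction) & prof$c2u_fraction > 0.05]
  a2i_pos <- prof$pos[!is.na(prof$a2i_fraction) & prof$a2i_fraction > 0.05]
  expect_lt(mean(dist_to(c2u_pos, "MS2")), mean(dist_to(c2u_pos, "PP7")))
  expect_lt(mean(dist_to(a2i_pos, "PP7")), mean(dist_to(a2i_pos, "MS2")))
})
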