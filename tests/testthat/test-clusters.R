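mk_site <- function(ref, pos, et = "C2U", alt = 2L) {
  tibble::tibble(ref = ref, pos = as.integer(pos), strand = "+",
                 edit_type = et, ref_base = "C", alt_base = "T",
                 coverage = 20L, alt_count = as.integer(alt),
                 fraction = alt / 20, confidence = 0.99)
}

mk_matrix <- function(ref, len, base = "C", coverage = 20L) {
  tibble::tibble(ref = ref, pos = 0:(len - 1L), ref_base = base,
                 A = 0L, C = coverage, G = 0L, T = 0L, coverage = coverage)
}

toy_models <- function(len = 500L, genes = "g1") {
  tibble::tibble(gene_id = genes, seqname = genes, strand = "+",
                 start = 0L, end = len, length = len)
}

test_that("bin window arithmetic anchors at the gene 5' end", {
  models <- toy_models()
  mat <- mk_matrix("g1", 500L)
  bins <- bin_edits(mk_site("g1", 35), models, mat)
  hit <- bins[bins$edited_count > 0, ]
  expect_equal(hit$start, 30)
  expect_equal(hit$end, 60)
  expect_equal(hit$edited_count, 1)
  # sites at 10 and 70 land in two distinct, non-spanning bins
  bins2 <- bin_edits(mk_site("g1", c(10, 70)), models, mat)
  hit2 <- bins2[bins2$edited_count > 0, ]
  expect_equal(hit2$start, c(0, 60))
  # all bins of the edited gene are tiled, zero-edit bins included
  expect_equal(nrow(bins2), ceiling(500 / 30))
  expect_equal(sum(bins2$edited_count), 2)
})

test_that("bin tallies match a brute-force per-position loop", {
  set.seed(42)
  len <- 500L
  models <- toy_models(len)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  cov <- sample(c(0L, 3L, 10L, 30L), len, replace = TRUE)
  mat <- tibble::tibble(ref = "g1", pos = 0:(len - 1L), ref_base = chars,
                        A = 0L, C = cov, G = 0L, T = 0L, coverage = cov)
  cpos <- which(chars == "C" & cov >= 10L) - 1L
  sites <- mk_site("g1", sample(cpos, 30))
  bins <- bin_edits(sites, models, mat, min_coverage = 10)
  for (i in seq_len(nrow(bins))) {
    b <- bins[i, ]
    expect_equal(b$edited_count,
                 sum(sites$pos >= b$start & sites$pos < b$end))
    span <- (b$start + 1):b$end
    expect_equal(b$editable_count,
                 max(b$edited_count,
                     sum(chars[span] == "C" & cov[span] >= 10L)))
    expect_equal(b$editing_fraction, b$edited_count / b$editable_count)
  }
})

test_that("sites outside every gene are dropped with a message", {
  models <- toy_models()
  mat <- mk_matrix("g1", 500L)
  sites <- dplyr::bind_rows(mk_site("g1", 35), mk_site("nowhere", 10))
  expect_message(bins <- bin_edits(sites, models, mat), "outside")
  expect_equal(sum(bins$edited_count), 1)
})

test_that("background rate is the unweighted mean editing fraction", {
  bins <- tibble::tibble(editable_count = c(10L, 5L),
                         edited_count = c(1L, 2L),
                         editing_fraction = c(0.1, 0.4))
  expect_equal(background_rate(bins), 0.25)
  # unweighted vs weighted differ when editable counts differ
  weighted <- sum(bins$edited_count) / sum(bins$editable_count)
  expect_false(isTRUE(all.equal(background_rate(bins), weighted)))
  # ... and agree when they are equal
  bins_eq <- dplyr::mutate(bins, editable_count = 10L,
                           editing_fraction = edited_count / 10)
  expect_equal(background_rate(bins_eq),
               sum(bins_eq$edited_count) / sum(bins_eq$editable_count))
  expect_equal(background_rate(dplyr::mutate(bins, edited_count = 0L,
                                             editing_fraction = 0)), 0)
  expect_error(background_rate(tibble::tibble(editable_count = 0L,
                                              edited_count = 0L,
                                              editing_fraction = NaN)),
               class = "stamper_input_error")
})

test_that("the Poisson bin test matches explicit pmf summation", {
  # printed example: lambda = 1 (bg 0.05 x 20 editable), 4 edits
  b <- tibble::tibble(edited_count = 4L, editable_count = 20L)
  expect_equal(poisson_bin_test(b, 0.05), 0.018988, tolerance = 1e-4)
  # zero edits always give p = 1
  expect_equal(poisson_bin_test(tibble::tibble(edited_count = 0L,
                                               editable_count = 20L),
                                0.05), 1)
  # pmf-summation oracle across the grid
  for (lambda in c(0.1, 1, 5)) {
    for (k in 0:25) {
      b <- tibble::tibble(edited_count = k, editable_count = 10L)
      expect_equal(poisson_bin_test(b, lambda / 10),
                   oracle_poisson_upper(k, lambda), tolerance = 1e-12)
    }
  }
  # zero background with edits present: floored rate, p < 1 but defined
  p0 <- poisson_bin_test(tibble::tibble(edited_count = 2L,
                                        editable_count = 10L), 0)
  expect_true(p0 > 0 && p0 < 1e-8)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03, 0.04)),
               c(0.004, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "stamper_input_error")
  # random vectors against the textbook oracle
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("filter-and-merge keeps q < fdr strictly and merges by gap", {
  mk_bins <- function(starts, q, ref = "g1") {
    tibble::tibble(ref = ref, gene_id = ref, edit_type = "C2U",
                   start = starts, end = starts + 30L,
                   editable_count = 10L, edited_count = 5L,
                   editing_fraction = 0.5, p_value = q / 2, q_value = q)
  }
  # gap 10 merges, gap 16 does not
  one <- filter_and_merge(mk_bins(c(100L, 140L), c(0.01, 0.02)))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(100, 170))
  expect_equal(one$q_value, 0.01)  # min over members
  two <- filter_and_merge(mk_bins(c(100L, 146L), c(0.01, 0.02)))
  expect_equal(nrow(two), 2)
  # strict threshold: q exactly at the fdr is dropped
  at <- filter_and_merge(mk_bins(100L, 0.1))
  expect_equal(nrow(at), 0)
})

test_that("merging equals a transitive-closure oracle on random layouts", {
  set.seed(7)
  for (trial in 1:200) {
    n <- sample(3:20, 1)
    starts <- sort(sample(seq(0, 900, by = 30), n))
    bins <- tibble::tibble(
      ref = sample(c("g1", "g2"), n, replace = TRUE), gene_id = "g",
      edit_type = "C2U", start = starts, end = starts + 30L,
      editable_count = 10L, edited_count = 5L, editing_fraction = 0.5,
      p_value = runif(n, 0, 0.05), q_value = runif(n, 0, 0.2))
    got <- filter_and_merge(bins, fdr = 0.1, merge_gap = 15)
    kept <- bins[bins$q_value < 0.1, ]
    if (nrow(kept) == 0) {
      expect_equal(nrow(got), 0)
      next
    }
    want <- oracle_merge(as.data.frame(kept), 15)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$p_value, want$p_value)
    expect_equal(got$q_value, want$q_value)
  }
})

test_that("the pipeline is invariant to input row order", {
  set.seed(11)
  models <- toy_models()
  mat <- mk_matrix("g1", 500L)
  sites <- mk_site("g1", sample(which(rep(TRUE, 450)), 40))
  run <- function(s) {
    bins <- bin_edits(s, models, mat)
    filter_and_merge(test_bins(bins), fdr = 0.5)
  }
  a <- run(sites)
  b <- suppressMessages(run(sites[sample(nrow(sites)), ]))
  expect_equal(a, b)
})

test_that("replicate intersection keeps set-1 clusters seen everywhere", {
  cl <- function(ref, start, end) {
    tibble::tibble(ref = ref, gene_id = ref, start = start, end = end,
                   n_bins = 1L, edited_count = 5L, p_value = 1e-4,
                   q_value = 1e-3)
  }
  s1 <- cl("g1", c(100L, 300L), c(160L, 360L))
  s2 <- cl("g1", 150L, 200L)   # overlaps only the first
  s3 <- cl("g1", c(110L, 290L), c(130L, 310L))
  out <- replicate_intersect(list(s1, s2, s3))
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)        # set-1 coordinates retained
  expect_equal(out$replicate_support, 3)
  # identical sets are idempotent; an empty replicate empties the result
  expect_equal(nrow(replicate_intersect(list(s1, s1, s1))), nrow(s1))
  expect_equal(nrow(replicate_intersect(list(s1, s1[0, ]))), 0)
  expect_error(replicate_intersect(list(s1)),
               class = "stamper_input_error")
  # agreement with the quadratic overlap oracle on random sets
  set.seed(3)
  for (trial in 1:20) {
    mk_rand <- function() {
      n <- sample(1:8, 1)
      st <- sample(0:500, n)
      cl(sample(c("g1", "g2"), n, TRUE), as.integer(st),
         as.integer(st + sample(20:80, n, TRUE)))
    }
    a <- mk_rand(); b <- mk_rand()
    got <- replicate_intersect(list(a, b))
    want <- a[oracle_overlaps_any(a, b), ]
    expect_equal(got$start, want$start)
  }
})

test_that("free-editor background subtraction removes overlapping clusters", {
  cl <- function(start, end) {
    tibble::tibble(ref = "g1", gene_id = "g1", start = start, end = end,
                   n_bins = 1L, edited_count = 5L, p_value = 1e-4,
                   q_value = 1e-3)
  }
  rbp <- cl(c(100L, 400L), c(150L, 450L))
  free <- cl(120L, 130L)
  out <- subtract_background(rbp, free)
  expect_equal(out$start, 400)
  expect_equal(nrow(subtract_background(rbp, cl(700L, 800L))), 2)
  expect_equal(nrow(subtract_background(rbp, rbp)), 0)
})
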