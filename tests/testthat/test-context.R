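mk_conf_site <- function(ref, pos, conf = 0.99) {
  tibble::tibble(ref = ref, pos = as.integer(pos), strand = "+",
                 edit_type = "C2U", ref_base = "C", alt_base = "T",
                 coverage = 20L, alt_count = 5L, fraction = 0.25,
                 confidence = conf)
}

test_that("flanking contexts are read off the sense strand", {
  ref <- c(chr = "TACGT")
  v <- flanking_contexts(mk_conf_site("chr", 2), ref)
  expect_equal(v$AG, 1L)       # upstream A, downstream G
  expect_equal(v$n_sites, 1L)
  # edge sites and low-confidence sites are skipped, with a tally
  edge <- flanking_contexts(mk_conf_site("chr", c(0, 4, 2)), ref)
  expect_equal(edge$n_sites, 1L)
  expect_equal(edge$skipped, 2L)
  low <- flanking_contexts(mk_conf_site("chr", 2, conf = 0.5), ref)
  expect_equal(low$n_sites, 0L)
})

test_that("context counts match a hand tally over listed sites", {
  ref <- c(chr = "AACATTGCACC")
  #         pos: 0123456789a ; C at 2,7(?),9,10...
  pos <- c(2L, 8L, 9L)
  v <- flanking_contexts(mk_conf_site("chr", pos), ref)
  chars <- strsplit(ref[[1]], "")[[1]]
  want <- table(paste0(chars[pos], chars[pos + 2]))
  for (ctx in names(want)) {
    expect_equal(v[[ctx]], as.integer(want[[ctx]]))
  }
  expect_equal(v$n_sites, 3L)
})

test_that("context PCA matches a covariance-eigendecomposition oracle", {
  set.seed(5)
  counts <- matrix(rpois(6 * 16, 40), 6, 16)
  vecs <- dplyr::bind_cols(
    tibble::tibble(sample = paste0("s", 1:6), n_sites = rowSums(counts),
                   skipped = 0L),
    tibble::as_tibble(stats::setNames(as.data.frame(counts),
                                      stamper:::context_names())))
  pca <- context_pca(vecs)
  # oracle: eigendecomposition of the covariance of proportions
  m <- counts / rowSums(counts)
  mc <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(mc))
  got <- abs(pca$scores$PC1)
  want <- abs(as.numeric(mc %*% ev$vectors[, 1]))
  expect_equal(got, want, tolerance = 1e-8)
  expect_equal(pca$variance_explained[1],
               ev$values[1] / sum(pmax(ev$values, 0)), tolerance = 1e-8)
  # identical inputs land on identical coordinates
  vecs2 <- vecs
  vecs2[2, -(1:3)] <- vecs2[1, -(1:3)]
  pca2 <- context_pca(vecs2)
  expect_equal(pca2$scores$PC1[1], pca2$scores$PC1[2], tolerance = 1e-10)
  expect_error(context_pca(vecs[1:2, ]), class = "stamper_input_error")
})

test_that("cluster composition counts bases exactly", {
  ref <- c(chr = "AAAAACGTACGTGGGG")
  cl <- tibble::tibble(ref = "chr", start = c(0L, 5L), end = c(4L, 9L))
  comp <- cluster_composition(cl, ref)
  expect_equal(comp$frac_A[1], 1)
  expect_equal(comp$frac_GC[1], 0)
  expect_equal(unlist(comp[2, c("frac_A", "frac_C", "frac_G", "frac_T")],
                      use.names = FALSE), rep(0.25, 4))
  expect_equal(comp$frac_GC[2], 0.5)
  expect_error(cluster_composition(
    tibble::tibble(ref = "chr", start = 3L, end = 3L), ref),
    class = "stamper_input_error")
  # random 50-mers against a per-character oracle
  set.seed(8)
  for (i in 1:10) {
    s <- random_dna_str(50)
    comp <- cluster_composition(tibble::tibble(ref = "chr", start = 0L,
                                               end = 50L),
                                c(chr = s))
    ch <- strsplit(s, "")[[1]]
    expect_equal(comp$frac_G + comp$frac_C, mean(ch %in% c("G", "C")))
    expect_equal(comp$frac_A, mean(ch == "A"))
  }
})

test_that("motif presence is exact substring search", {
  ref <- c(a = "AAGCATGAA", b = "AAAAAAAAA")
  cl <- tibble::tibble(ref = c("a", "b"), start = 0L, end = 9L)
  mp <- motif_presence(cl, ref)
  expect_equal(mp$fraction, 0.5)
  expect_equal(mp$per_cluster$has_motif, c(TRUE, FALSE))
  # regex-count oracle on random clusters
  set.seed(9)
  seqs <- vapply(1:20, function(i) random_dna_str(60), character(1))
  names(seqs) <- paste0("c", 1:20)
  cl20 <- tibble::tibble(ref = names(seqs), start = 0L, end = 60L)
  got <- motif_presence(cl20, seqs, motif = "ACG")$fraction
  expect_equal(got, mean(grepl("ACG", seqs, fixed = TRUE)))
})

test_that("motif distances are signed nearest-neighbour offsets", {
  cl <- tibble::tibble(ref = "chr", start = c(80L, 200L, 5000L),
                       end = c(120L, 240L, 5040L))
  ms <- tibble::tibble(ref = "chr", start = c(120L, 220L), end = c(125L,
                                                                   225L))
  d <- motif_distance_density(cl, ms, max_dist = 1000)
  expect_equal(d$distances$distance, c(20, 0))  # midpoints 100 and 220
  expect_equal(d$n_excluded, 1)
  expect_error(motif_distance_density(cl, ms[0, ]),
               class = "stamper_input_error")
  # exhaustive nearest-neighbour oracle
  set.seed(10)
  cl_r <- tibble::tibble(ref = "chr", start = sample(0:2000, 30))
  cl_r$end <- cl_r$start + 50L
  ms_r <- tibble::tibble(ref = "chr", start = sample(0:2000, 10))
  ms_r$end <- ms_r$start + 5L
  got <- motif_distance_density(cl_r, ms_r, max_dist = 5000)$distances
  mids <- floor((cl_r$start + cl_r$end) / 2)
  want <- vapply(mids, function(m) {
    dd <- ms_r$start - m
    dd[which.min(abs(dd))]
  }, numeric(1))
  expect_equal(got$distance, want)
})
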