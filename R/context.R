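#' Flanking-base context counts of confident edit sites
#'
#' For each edit site above the confidence threshold, records the pair
#' (base at `pos - 1`, base at `pos + 1`) on the transcript sense strand
#' and tallies the 16 possible (upstream, downstream) pairs. Sites at a
#' sequence edge, or with a non-ACGT neighbour, are skipped and reported
#' in the `skipped` attribute. The DNA alphabet (T) is used internally; U
#' appears only in display labels.
#'
#' @param sites Edit-site tibble from [call_edits()].
#' @param reference Named character vector, DNAStringSet or FASTA path.
#' @param min_confidence Keep sites with confidence strictly above this
#'   (default 0.9).
#' @param sample Label for the resulting vector.
#' @return A one-row tibble of class `context_vector`: `sample`, `n_sites`,
#'   `skipped`, then the 16 context counts (`AA` ... `TT`).
#' @export
flanking_contexts <- function(sites, reference, min_confidence = 0.9,
                              sample = "sample") {
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  reference <- as_reference(reference)
  s <- sites[sites$confidence > min_confidence, , drop = FALSE]
  cn <- context_names()
  counts <- setNames(integer(16), cn)
  skipped <- 0L
  if (nrow(s) > 0) {
    len <- nchar(reference)[s$ref]
    at_edge <- s$pos < 1 | s$pos > len - 2
    skipped <- sum(at_edge)
    s <- s[!at_edge, , drop = FALSE]
    if (nrow(s) > 0) {
      up <- substr(reference[s$ref], s$pos, s$pos)
      dn <- substr(reference[s$ref], s$pos + 2, s$pos + 2)
      ctx <- paste0(up, dn)
      ok <- ctx %in% cn
      skipped <- skipped + sum(!ok)
      tab <- table(factor(ctx[ok], levels = cn))
      counts <- setNames(as.integer(tab), cn)
    }
  }
  out <- bind_cols(tibble(sample = sample, n_sites = sum(counts),
                          skipped = skipped),
                   as_tibble(as.list(counts)))
  class(out) <- c("context_vector", class(out))
  out
}

#' PCA of flanking-context profiles across samples
#'
#' Normalises each sample's 16 context counts to proportions, mean-centres
#' across samples (no unit-variance scaling — the counts are compositional
#' and loadings are read per base pair), and decomposes with [prcomp()].
#'
#' @param vectors A tibble of stacked [flanking_contexts()] rows (>= 3
#'   samples), or a list of such rows.
#' @param normalize Use proportions (default TRUE) or raw counts.
#' @return An object of class `context_pca`: list with `scores` (tibble
#'   `sample`, `PC1`, ...), `loadings` (tibble `context`, `PC1`, ...),
#'   `variance_explained`, and the fitted `prcomp` object. [tidy()]
#'   extracts scores/loadings/eigenvalues.
#' @export
context_pca <- function(vectors, normalize = TRUE) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- bind_rows(vectors)
  }
  cn <- context_names()
  if (nrow(vectors) < 3) abort("need at least 3 context vectors.",
                               class = "stamper_input_error")
  m <- as.matrix(vectors[, cn])
  rownames(m) <- vectors$sample
  if (normalize) {
    rs <- rowSums(m)
    if (any(rs == 0)) abort("a context vector has zero total counts.",
                            class = "stamper_input_error")
    m <- m / rs
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- ncol(fit$x)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = bind_cols(tibble(sample = vectors$sample),
                       as_tibble(fit$x)),
    loadings = bind_cols(tibble(context = cn),
                         as_tibble(unclass(fit$rotation))),
    variance_explained = ve[seq_len(k)],
    prcomp = fit
  ), class = "context_pca")
}

#' @export
print.context_pca <- function(x, ...) {
  cat("<context_pca> ", nrow(x$scores), " samples; PC1 ",
      sprintf("%.1f%%", 100 * x$variance_explained[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * (x$variance_explained[2] %||% 0)),
      " variance\n", sep = "")
  invisible(x)
}

#' Base composition of cluster sequences
#'
#' Per-cluster A/C/G/T fractions and GC fraction over the cluster's
#' sense-strand sequence (Ns ignored in the denominator).
#'
#' @param clusters Cluster tibble (`ref`, `start`, `end`).
#' @param reference Named character vector, DNAStringSet or FASTA path.
#' @return The clusters with `frac_A`, `frac_C`, `frac_G`, `frac_T`
#'   (renamed U in reports) and `frac_GC` columns.
#' @export
cluster_composition <- function(clusters, reference) {
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  reference <- as_reference(reference)
  if (any(clusters$end <= clusters$start)) {
    abort("zero-length cluster.", class = "stamper_input_error")
  }
  seqs <- substr(reference[clusters$ref], clusters$start + 1, clusters$end)
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                        letters = c("A", "C", "G", "T"))
  tot <- rowSums(counts)
  frac <- function(b) unname(counts[, b] / tot)
  clusters %>%
    mutate(frac_A = frac("A"), frac_C = frac("C"),
           frac_G = frac("G"), frac_T = frac("T"),
           frac_GC = .data$frac_G + .data$frac_C)
}

#' Fraction of clusters containing a binding motif
#'
#' Exact substring search on the sense strand (default the RBFOX2 core
#' motif GCAUG, DNA alphabet).
#'
#' @param clusters Cluster tibble (`ref`, `start`, `end`).
#' @param reference Named character vector, DNAStringSet or FASTA path.
#' @param motif Motif string (non-empty).
#' @return List with `fraction` and `per_cluster` (clusters plus a logical
#'   `has_motif` column).
#' @export
motif_presence <- function(clusters, reference, motif = "GCATG") {
  if (!nzchar(motif)) abort("`motif` must be non-empty.")
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  reference <- as_reference(reference)
  seqs <- substr(reference[clusters$ref], clusters$start + 1, clusters$end)
  has <- stringr::str_detect(seqs, stringr::fixed(toupper(motif)))
  list(fraction = if (nrow(clusters) > 0) mean(has) else NA_real_,
       per_cluster = mutate(clusters, has_motif = has))
}

#' Signed distances from cluster midpoints to the nearest motif site
#'
#' For each cluster, the signed distance (downstream positive) from the
#' cluster midpoint to the start of the nearest motif site within
#' `max_dist` bp on the same reference; clusters with no motif in range
#' are excluded and tallied.
#'
#' @param clusters Cluster tibble (`ref`, `start`, `end`).
#' @param motif_sites Interval tibble of motif occurrences (`ref`,
#'   `start`, `end`), e.g. from a scan or the simulator truth.
#' @param max_dist Search radius in bp (default 1000).
#' @return List with `distances` (tibble `ref`, `midpoint`, `distance`)
#'   and `n_excluded`.
#' @export
motif_distance_density <- function(clusters, motif_sites, max_dist = 1000) {
  if (nrow(motif_sites) == 0) abort("`motif_sites` is empty.",
                                    class = "stamper_input_error")
  mids <- floor((clusters$start + clusters$end) / 2)
  d <- purrr::map_dbl(seq_len(nrow(clusters)), function(i) {
    ms <- motif_sites$start[motif_sites$ref == clusters$ref[i]]
    if (length(ms) == 0) return(NA_real_)
    dd <- ms - mids[i]
    dd <- dd[abs(dd) <= max_dist]
    if (length(dd) == 0) return(NA_real_)
    dd[which.min(abs(dd))]
  })
  list(distances = tibble(ref = clusters$ref, midpoint = mids,
                          distance = d)[!is.na(d), ],
       n_excluded = sum(is.na(d)))
}
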