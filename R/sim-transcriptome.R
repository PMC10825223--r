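#' Specification of a simulated toy transcriptome
#'
#' Parameters for [simulate_transcriptome()]: gene count, lognormal length
#' models for CDS and 3'UTR, base composition, the binding motif planted in
#' target genes, and the fraction of genes flagged as TOP-like (5' terminal
#' oligopyrimidine-tract genes whose translation is strongly
#' mTOR-dependent).
#'
#' Per-gene GC content is drawn around `gc_content` with spread `gc_sd`,
#' reflecting the wide compositional variation of real transcriptomes; set
#' `gc_sd = 0` for homogeneous composition. Within a gene, sequence is
#' laid down in compositional segments (mean length `segment_length`,
#' per-segment GC spread `segment_gc_sd` around the gene's GC), emulating
#' the local composition structure of real mRNAs (AU-rich elements,
#' GC-rich stretches); set `segment_gc_sd = 0` for i.i.d. bases.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param cds_meanlog,cds_sdlog,cds_min Lognormal CDS length model (bp).
#' @param utr3_meanlog,utr3_sdlog,utr3_min Lognormal 3'UTR length model (bp).
#' @param gc_content Mean GC fraction.
#' @param gc_sd Between-gene standard deviation of GC fraction.
#' @param segment_length Mean compositional segment length in bp.
#' @param segment_gc_sd Within-gene, between-segment GC spread.
#' @param motif Motif string planted in target-gene 3'UTRs (DNA alphabet;
#'   default the RBFOX2 core motif GCAUG as `"GCATG"`).
#' @param target_fraction Fraction of genes receiving planted motif sites
#'   (the simulated RBP's targets).
#' @param motifs_per_target Planted motif instances per target gene.
#' @param top_fraction Fraction of genes flagged TOP-like.
#' @param seed Integer seed.
#' @return A list of class `transcriptome_spec`.
#' @export
transcriptome_spec <- function(n_genes = 50,
                               cds_meanlog = log(600), cds_sdlog = 0.3,
                               cds_min = 150,
                               utr3_meanlog = log(400), utr3_sdlog = 0.4,
                               utr3_min = 120,
                               gc_content = 0.45, gc_sd = 0.07,
                               segment_length = 150, segment_gc_sd = 0.12,
                               motif = "GCATG",
                               target_fraction = 0.3,
                               motifs_per_target = 1,
                               top_fraction = 0.2,
                               seed = 1L) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.",
                         class = "stamper_config_error")
  for (v in c(cds_min, utr3_min, motifs_per_target)) {
    if (v < 0) abort("length parameters must be non-negative.",
                     class = "stamper_config_error")
  }
  if (top_fraction < 0 || top_fraction > 1 ||
      target_fraction < 0 || target_fraction > 1) {
    abort("fractions must lie in [0, 1].", class = "stamper_config_error")
  }
  structure(as.list(environment()), class = "transcriptome_spec")
}

#' Simulate a toy transcriptome with gene models and ground truth
#'
#' Emits one transcript per gene in transcript space (each transcript is
#' its own reference sequence), a matching gene-model table (CDS and 3'UTR
#' features, TOP flag), and a truth record of planted motif sites. Binding
#' motifs are planted at random 3'UTR positions of target genes; TOP genes
#' are a random subset of exactly `round(top_fraction * n_genes)` genes.
#'
#' @param spec A [transcriptome_spec()].
#' @return A list of class `sim_transcriptome` with elements
#'   `sequences` (named character vector), `models` (gene-model tibble:
#'   `gene_id`, `seqname`, `strand`, `length`, `cds_start`, `cds_end`,
#'   `utr3_start`, `utr3_end`, `top`; 0-based half-open), and `truth`
#'   (list with `motif_sites` tibble `ref`, `start`, `end`, `gene_id` and
#'   per-gene `gc` values).
#' @examples
#' tx <- simulate_transcriptome(transcriptome_spec(n_genes = 10, seed = 3))
#' sum(tx$models$top)
#' @export
simulate_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "transcriptome_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    ids <- sprintf("gene%03d", seq_len(n))
    cds_len <- pmax(spec$cds_min,
                    round(rlnorm(n, spec$cds_meanlog, spec$cds_sdlog)))
    utr_len <- pmax(spec$utr3_min,
                    round(rlnorm(n, spec$utr3_meanlog, spec$utr3_sdlog)))
    gc <- pmin(0.8, pmax(0.2, rnorm(n, spec$gc_content, spec$gc_sd)))
    seqs <- vapply(seq_len(n), function(i) {
      total <- cds_len[i] + utr_len[i]
      if (spec$segment_gc_sd <= 0) return(random_dna(total, gc[i]))
      pieces <- character(0)
      laid <- 0
      while (laid < total) {
        sl <- min(total - laid,
                  max(30, round(rlnorm(1, log(spec$segment_length), 0.4))))
        sgc <- min(0.9, max(0.1, rnorm(1, gc[i], spec$segment_gc_sd)))
        pieces <- c(pieces, random_dna(sl, sgc))
        laid <- laid + sl
      }
      paste(pieces, collapse = "")
    }, character(1))
    names(seqs) <- ids

    n_top <- round(spec$top_fraction * n)
    top <- ids %in% sample(ids, n_top)

    n_target <- round(spec$target_fraction * n)
    targets <- sample(ids, n_target)
    motif <- toupper(spec$motif)
    mlen <- nchar(motif)
    motif_sites <- purrr::map_dfr(targets, function(g) {
      i <- match(g, ids)
      lo <- cds_len[i] + 10
      hi <- cds_len[i] + utr_len[i] - 10 - mlen
      if (hi <= lo) return(tibble())
      # greedy non-overlapping placement so planted motifs never collide
      cand <- sample(lo:hi)
      starts <- integer(0)
      for (x in cand) {
        if (length(starts) == spec$motifs_per_target) break
        if (all(abs(x - starts) >= mlen)) starts <- c(starts, x)
      }
      starts <- sort(starts)
      tibble(ref = g, start = starts, end = starts + mlen, gene_id = g)
    })
    # plant the motifs into the sequences
    for (j in seq_len(nrow(motif_sites))) {
      g <- motif_sites$ref[j]
      s <- motif_sites$start[j]
      substr(seqs[[g]], s + 1, s + mlen) <- motif
    }
  })

  models <- tibble(
    gene_id = ids, seqname = ids, strand = "+",
    start = 0L, end = as.integer(cds_len + utr_len),
    length = cds_len + utr_len,
    cds_start = 0L, cds_end = as.integer(cds_len),
    utr3_start = as.integer(cds_len), utr3_end = as.integer(cds_len + utr_len),
    top = top)

  structure(list(
    spec = spec,
    sequences = seqs,
    models = models,
    truth = list(motif_sites = motif_sites,
                 gc = setNames(gc, ids))
  ), class = "sim_transcriptome")
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  cat("<sim_transcriptome> ", nrow(x$models), " genes, ",
      sum(nchar(x$sequences)), " bp; ", sum(x$models$top), " TOP-flagged, ",
      nrow(x$truth$motif_sites), " planted motif sites\n", sep = "")
  invisible(x)
}
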