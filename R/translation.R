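#' Per-gene read counts from alignments
#'
#' A read counts toward a gene iff its aligned span overlaps the gene's
#' exonic span (>= 1 bp); reads overlapping more than one gene are
#' discarded as ambiguous and tallied in the `ambiguous` attribute.
#'
#' @param alignments Reads tibble (`ref`, `start`, `seq`), `sim_reads`
#'   object, or SAM path.
#' @param models Gene-model tibble (`gene_id`, `seqname`, `length`).
#' @return Tibble `gene_id`, `read_count` (all genes, zero-filled), with
#'   attribute `ambiguous`.
#' @export
gene_read_counts <- function(alignments, models) {
  if (nrow(models) == 0) abort("empty gene models.",
                               class = "stamper_input_error")
  if (inherits(alignments, "sim_reads")) alignments <- alignments$reads
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- read_sam_reads(alignments)
  }
  reads_gr <- GenomicRanges::GRanges(
    alignments$ref,
    IRanges::IRanges(alignments$start + 1L,
                     alignments$start + nchar(alignments$seq)))
  gstart <- if ("start" %in% names(models)) models$start else
    rep(0L, nrow(models))
  genes_gr <- GenomicRanges::GRanges(
    models$seqname, IRanges::IRanges(gstart + 1L, gstart + models$length))
  hits <- GenomicRanges::findOverlaps(reads_gr, genes_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_genes_per_read <- tabulate(qh, nbins = length(reads_gr))
  ambiguous <- sum(n_genes_per_read > 1)
  ok <- n_genes_per_read[qh] == 1
  counts <- tabulate(sh[ok], nbins = nrow(models))
  out <- tibble(gene_id = models$gene_id, read_count = counts)
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Edits per read (EPR) per gene
#'
#' The translation proxy: edited read-base observations on a gene divided
#' by the reads assigned to it, for genes with at least `min_reads` reads.
#'
#' @param edit_counts Tibble `gene_id`, `edit_count`.
#' @param read_counts Tibble `gene_id`, `read_count`.
#' @param min_reads Minimum reads for a gene to be reported (default 10).
#' @return Tibble `gene_id`, `read_count`, `edit_count`, `epr`.
#' @export
edits_per_read <- function(edit_counts, read_counts, min_reads = 10) {
  stopifnot(min_reads >= 1)
  read_counts %>%
    left_join(edit_counts, by = "gene_id") %>%
    mutate(edit_count = tidyr::replace_na(.data$edit_count, 0)) %>%
    filter(.data$read_count >= min_reads) %>%
    mutate(epr = .data$edit_count / .data$read_count)
}

#' Per-gene, per-replicate edit summaries for a simulated experiment
#'
#' Runs the EPR pipeline on every replicate of both conditions of a
#' [simulate_translation()] experiment: pileup, edit calling, confidence
#' filtering, per-gene read and edit counting, and region-restricted EPR.
#' A read contributes to the CDS (3'UTR) denominator when its alignment
#' midpoint falls in the region — the midpoint rule avoids double counting
#' across the junction; an edit contributes by its site position.
#'
#' @param sim A `sim_translation` object.
#' @param min_confidence Site confidence filter (default 0.9, strict).
#' @param min_reads Minimum reads per gene (default 10).
#' @param min_coverage,error_rate Edit-calling parameters.
#' @return Tibble: `gene_id`, `condition`, `replicate`, `read_count`,
#'   `edit_count`, `epr`, `epr_cds`, `epr_utr3`.
#' @export
epr_summaries <- function(sim, min_confidence = 0.9, min_reads = 10,
                          min_coverage = 5, error_rate = 0.001) {
  stopifnot(inherits(sim, "sim_translation"))
  models <- sim$models
  one <- function(sr, cond, rep_i) {
    mat <- pileup_counts(sr$reads, sr$reference)
    sites <- call_edits(mat, sim$params$edit_type,
                        min_coverage = min_coverage,
                        error_rate = error_rate)
    sites <- sites[sites$confidence > min_confidence, , drop = FALSE]
    rc <- gene_read_counts(sr$reads, models)

    mid <- sr$reads$start + nchar(sr$reads$seq) %/% 2
    gi <- match(sr$reads$ref, models$seqname)
    in_cds <- mid < models$cds_end[gi]
    reads_cds <- tibble(gene_id = models$gene_id[gi], in_cds = in_cds) %>%
      group_by(.data$gene_id) %>%
      summarise(reads_cds = sum(.data$in_cds),
                reads_utr3 = sum(!.data$in_cds), .groups = "drop")

    si <- match(sites$ref, models$seqname)
    edits <- tibble(gene_id = models$gene_id[si],
                    n = sites$alt_count,
                    in_cds = sites$pos < models$cds_end[si]) %>%
      group_by(.data$gene_id) %>%
      summarise(edit_count = sum(.data$n),
                edits_cds = sum(.data$n[.data$in_cds]),
                edits_utr3 = sum(.data$n[!.data$in_cds]), .groups = "drop")

    edits_per_read(select(edits, "gene_id", "edit_count"), rc, min_reads) %>%
      left_join(reads_cds, by = "gene_id") %>%
      left_join(select(edits, "gene_id", "edits_cds", "edits_utr3"),
                by = "gene_id") %>%
      mutate(across(c("reads_cds", "reads_utr3", "edits_cds", "edits_utr3"),
                    ~ tidyr::replace_na(.x, 0)),
             epr_cds = ifelse(.data$reads_cds > 0,
                              .data$edits_cds / .data$reads_cds, NA_real_),
             epr_utr3 = ifelse(.data$reads_utr3 > 0,
                               .data$edits_utr3 / .data$reads_utr3,
                               NA_real_),
             condition = cond, replicate = rep_i) %>%
      select("gene_id", "condition", "replicate", "read_count",
             "edit_count", "epr", "epr_cds", "epr_utr3")
  }
  bind_rows(
    purrr::imap_dfr(sim$control, ~ one(.x, "control", .y)),
    purrr::imap_dfr(sim$treated, ~ one(.x, "treated", .y)))
}

#' Treated-versus-control EPR fold changes with significance
#'
#' Per-gene Welch two-sided t-test on replicate EPR values, BH-adjusted
#' across genes; `log2FC = log2(mean treated + eps) - log2(mean control +
#' eps)` with `eps = 1e-6`. Genes quantifiable (present) in every
#' replicate of both conditions are compared. Genes with zero variance in
#' both conditions and equal means get p = 1.
#'
#' @param summaries Long tibble from [epr_summaries()] (or with columns
#'   `gene_id`, `condition`, `replicate`, `epr`).
#' @param fdr Call threshold on q (default 0.05).
#' @return Tibble of class `epr_comparison`: `gene_id`, `mean_control`,
#'   `mean_treated`, `log2_fc`, `t`, `p_value`, `q_value`, `call`
#'   (`decrease` / `increase` / `ns`).
#' @export
epr_fold_change <- function(summaries, fdr = 0.05) {
  n_needed <- summaries %>%
    distinct(.data$condition, .data$replicate) %>%
    count(.data$condition)
  if (any(n_needed$n < 2)) {
    abort("need >= 2 replicates per condition.",
          class = "stamper_input_error")
  }
  eps <- 1e-6
  complete <- summaries %>%
    count(.data$gene_id) %>%
    filter(.data$n == sum(n_needed$n)) %>%
    pull(.data$gene_id)
  res <- summaries %>%
    filter(.data$gene_id %in% complete) %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, key) {
      x <- d$epr[d$condition == "treated"]
      y <- d$epr[d$condition == "control"]
      tt <- tryCatch(t.test(x, y),
                     error = function(e) list(statistic = 0, p.value = 1))
      tibble(mean_control = mean(y), mean_treated = mean(x),
             log2_fc = log2(mean(x) + eps) - log2(mean(y) + eps),
             t = unname(tt$statistic), p_value = tt$p.value)
    }) %>%
    ungroup()
  res %>%
    mutate(q_value = bh_adjust(.data$p_value),
           call = dplyr::case_when(
             .data$q_value < fdr & .data$log2_fc < 0 ~ "decrease",
             .data$q_value < fdr & .data$log2_fc > 0 ~ "increase",
             TRUE ~ "ns")) %>%
    `class<-`(c("epr_comparison", class(res)))
}

#' Group-versus-complement contrast of EPR fold changes
#'
#' Welch two-sided t-test comparing the log2 EPR fold changes of a gene
#' group (e.g. TOP-containing mRNAs) against all other genes. `t_decrease`
#' is the statistic oriented so that a group whose EPR drops more than the
#' complement scores positive.
#'
#' @param comparisons An [epr_fold_change()] table.
#' @param group_members Character vector of gene ids; must be a non-empty
#'   proper subset of the table's genes.
#' @return One-row tibble: `n_group`, `n_other`, `mean_group`,
#'   `mean_other`, `t`, `t_decrease`, `p_value`.
#' @export
group_contrast <- function(comparisons, group_members) {
  genes <- comparisons$gene_id
  if (!all(group_members %in% genes)) {
    abort("group contains genes absent from the comparison table.",
          class = "stamper_input_error")
  }
  g <- comparisons$log2_fc[genes %in% group_members]
  o <- comparisons$log2_fc[!genes %in% group_members]
  if (length(g) == 0 || length(o) == 0) {
    abort("group must be a non-empty proper subset.",
          class = "stamper_input_error")
  }
  tt <- tryCatch(t.test(g, o), error = function(e) {
    # both groups constant: t is 0 (equal means) or infinite (different)
    if (isTRUE(all.equal(mean(g), mean(o)))) {
      list(statistic = 0, p.value = 1)
    } else {
      list(statistic = sign(mean(g) - mean(o)) * Inf, p.value = 0)
    }
  })
  tibble(n_group = length(g), n_other = length(o),
         mean_group = mean(g), mean_other = mean(o),
         t = unname(tt$statistic), t_decrease = -unname(tt$statistic),
         p_value = tt$p.value)
}

#' CDS / 3'UTR editing ratio
#'
#' Reports both the ratio of means (`mean(epr_cds) / mean(epr_utr3)`) and
#' the per-gene ratio distribution, over genes with nonzero 3'UTR EPR.
#'
#' @param summaries Rows of [epr_summaries()] (filter to one condition
#'   first if desired).
#' @param group Optional gene-id subset.
#' @return List with `ratio_of_means` and `per_gene` (tibble `gene_id`,
#'   `epr_cds`, `epr_utr3`, `ratio`).
#' @export
region_epr_ratio <- function(summaries, group = NULL) {
  d <- summaries
  if (!is.null(group)) d <- d[d$gene_id %in% group, , drop = FALSE]
  d <- d %>%
    group_by(.data$gene_id) %>%
    summarise(epr_cds = mean(.data$epr_cds, na.rm = TRUE),
              epr_utr3 = mean(.data$epr_utr3, na.rm = TRUE),
              .groups = "drop") %>%
    filter(is.finite(.data$epr_utr3), .data$epr_utr3 > 0,
           is.finite(.data$epr_cds))
  if (nrow(d) == 0) abort("no genes with nonzero 3'UTR EPR.",
                          class = "stamper_input_error")
  list(ratio_of_means = mean(d$epr_cds) / mean(d$epr_utr3),
       per_gene = mutate(d, ratio = .data$epr_cds / .data$epr_utr3))
}
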