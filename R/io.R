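#' Read gene models from GTF/GFF
#'
#' Imports transcript, CDS and 3'UTR features (via [rtracklayer::import()])
#' and converts the 1-based inclusive coordinates to the package's
#' internal 0-based half-open convention. The optional `top` attribute
#' ("1"/"0") marks TOP-like genes.
#'
#' @param path GTF/GFF file.
#' @return Gene-model tibble: `gene_id`, `seqname`, `strand`, `start`,
#'   `end`, `length`, `cds_start`, `cds_end`, `utr3_start`, `utr3_end`,
#'   `top` (0-based half-open).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  d <- as_tibble(as.data.frame(gr))
  if (!all(c("type", "gene_id") %in% names(d))) {
    abort("GTF lacks mandatory type/gene_id fields.",
          class = "stamper_input_error")
  }
  d <- d %>%
    mutate(start0 = .data$start - 1L, end0 = .data$end,
           seqname = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           type = as.character(.data$type))
  tx <- d %>% filter(.data$type == "transcript")
  if (nrow(tx) == 0) abort("GTF contains no transcript features.",
                           class = "stamper_input_error")
  cds <- d %>% filter(.data$type == "CDS") %>%
    group_by(.data$gene_id) %>%
    summarise(cds_start = min(.data$start0), cds_end = max(.data$end0),
              .groups = "drop")
  utr <- d %>% filter(.data$type == "three_prime_utr") %>%
    group_by(.data$gene_id) %>%
    summarise(utr3_start = min(.data$start0), utr3_end = max(.data$end0),
              .groups = "drop")
  out <- tx %>%
    transmute(gene_id = .data$gene_id, seqname = .data$seqname,
              strand = if_else(.data$strand == "*", "+", .data$strand),
              start = .data$start0, end = .data$end0,
              length = .data$end0 - .data$start0,
              top = if ("top" %in% names(d)) .data$top == "1" else FALSE) %>%
    left_join(cds, by = "gene_id") %>%
    left_join(utr, by = "gene_id") %>%
    arrange(.data$gene_id)
  out
}

#' Write gene models as GTF
#'
#' Emits transcript, CDS and three_prime_utr features with `gene_id`,
#' `transcript_id` and `top` attributes (1-based inclusive on disk).
#'
#' @param models Gene-model tibble (see [read_gene_models()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  m <- models
  if (!"start" %in% names(m)) m$start <- 0L
  if (!"end" %in% names(m)) m$end <- m$start + m$length
  rows <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    g <- m[i, ]
    feats <- tibble(type = "transcript", start = g$start, end = g$end)
    if (!is.na(g$cds_start %||% NA)) {
      feats <- bind_rows(feats, tibble(type = "CDS", start = g$cds_start,
                                       end = g$cds_end))
    }
    if (!is.na(g$utr3_start %||% NA)) {
      feats <- bind_rows(feats,
                         tibble(type = "three_prime_utr",
                                start = g$utr3_start, end = g$utr3_end))
    }
    mutate(feats, seqname = g$seqname, strand = g$strand,
           gene_id = g$gene_id,
           top = if (isTRUE(g$top)) "1" else "0")
  })
  gr <- GenomicRanges::GRanges(
    rows$seqname, IRanges::IRanges(rows$start + 1L, rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$phase <- ifelse(rows$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$gene_id
  S4Vectors::mcols(gr)$top <- rows$top
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read/write interval sets as BED (0-based half-open)
#'
#' @param path BED file.
#' @return `read_bed()`: tibble `ref`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(ref = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         name = if (!is.null(gr$name)) gr$name else NA_character_,
         strand = as.character(GenomicRanges::strand(gr)))
}

#' @param intervals Tibble `ref`, `start`, `end`, optionally `name`,
#'   `strand`, `score`.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  has <- function(col, default) {
    if (col %in% names(intervals)) intervals[[col]] else default
  }
  d <- tibble(ref = intervals$ref,
              start = intervals$start,
              end = intervals$end,
              name = has("name", "."),
              score = has("score", 0),
              strand = has("strand", "."))
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}

#' Write/read edit-site tables as TSV
#'
#' Columns on disk: `ref`, `pos0` (0-based), `strand`, `edit_type`,
#' `ref_base`, `alt_base`, `coverage`, `alt_count`, `fraction`,
#' `confidence`.
#'
#' @param sites Edit-site tibble from [call_edits()].
#' @param path TSV file.
#' @export
write_edit_sites <- function(sites, path) {
  out <- rename(sites, pos0 = "pos")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_edit_sites
#' @export
read_edit_sites <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    rename(pos = "pos0")
}

#' Write clusters as BED6+ with p/q columns
#'
#' Columns: chrom, start, end, name (gene id), score (`-log10 q`, capped
#' at 1000), strand, p_value, q_value, edited_count; 0-based half-open.
#'
#' @param clusters Cluster tibble.
#' @param path Output file.
#' @export
write_clusters_bed <- function(clusters, path) {
  d <- tibble(
    chrom = clusters$ref, start = clusters$start, end = clusters$end,
    name = if ("gene_id" %in% names(clusters)) clusters$gene_id else ".",
    score = round(pmin(1000, -log10(pmax(clusters$q_value, 1e-300))), 3),
    strand = ".",
    p_value = signif(clusters$p_value, 6),
    q_value = signif(clusters$q_value, 6),
    edited_count = clusters$edited_count)
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}

#' Write a per-position edit-fraction track (bedGraph)
#'
#' @param matrix Base-count tibble from [pileup_counts()].
#' @param path Output file.
#' @param edit_type Channel to report.
#' @export
write_edit_fraction_bedgraph <- function(matrix, path, edit_type = "C2U") {
  sub <- substrate_base(edit_type)
  alt <- product_base(edit_type)
  d <- matrix %>%
    filter(.data$ref_base == sub, .data$coverage > 0) %>%
    transmute(.data$ref, start = .data$pos, end = .data$pos + 1L,
              value = round(.data[[alt]] /
                              pmax(1L, .data[[sub]] + .data[[alt]]), 6))
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}
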