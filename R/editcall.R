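#' Per-position base counts from alignments
#'
#' Builds the base-count matrix (per-position A/C/G/T counts and coverage)
#' that edit calling and reporter profiling consume. Two engines stand
#' behind the same contract:
#'
#' * `"rsamtools"` — for SAM/BAM files on disk; SAM input is converted,
#'   sorted and indexed via [Rsamtools::asBam()], then piled up with
#'   [Rsamtools::pileup()]. Unmapped, secondary and supplementary reads are
#'   excluded.
#' * `"native"` — for in-memory read tables from the simulator (a
#'   `sim_reads` object or a tibble with `ref`, `start`, `seq`, `qual`);
#'   tallies bases directly without a file round-trip.
#'
#' Both engines count only bases with Phred quality at least
#' `min_base_quality`. Coverage includes N bases; the A/C/G/T columns do
#' not, so `A + C + G + T <= coverage`.
#'
#' @param alignments Path to a SAM/BAM file, a `sim_reads` object, or a
#'   reads tibble.
#' @param reference Named character vector, DNAStringSet, or FASTA path.
#' @param min_base_quality Minimum base quality (Phred; default 20).
#' @param region Optional tibble `ref`, `start`, `end` (0-based half-open)
#'   restricting the output.
#' @param engine `"auto"`, `"native"` or `"rsamtools"`.
#' @return Tibble `ref`, `pos` (0-based), `ref_base`, `A`, `C`, `G`, `T`,
#'   `coverage`, sorted by reference and position; positions with zero
#'   coverage are omitted.
#' @export
pileup_counts <- function(alignments, reference, min_base_quality = 20,
                          region = NULL, engine = c("auto", "native",
                                                    "rsamtools")) {
  engine <- match.arg(engine)
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  reference <- as_reference(reference)
  if (inherits(alignments, "sim_reads")) alignments <- alignments$reads
  is_path <- is.character(alignments) && length(alignments) == 1
  if (engine == "auto") engine <- if (is_path) "rsamtools" else "native"

  mat <- if (engine == "native") {
    if (is_path) alignments <- read_sam_reads(alignments)
    pileup_native(alignments, reference, min_base_quality)
  } else {
    if (!is_path) {
      path <- tempfile(fileext = ".sam")
      on.exit(unlink(path), add = TRUE)
      write_sam(alignments, path, reference)
      alignments <- path
    }
    pileup_rsamtools(alignments, reference, min_base_quality)
  }
  if (!is.null(region)) {
    keep <- rep(FALSE, nrow(mat))
    for (i in seq_len(nrow(region))) {
      keep <- keep | (mat$ref == region$ref[i] & mat$pos >= region$start[i] &
                        mat$pos < region$end[i])
    }
    mat <- mat[keep, , drop = FALSE]
  }
  mat
}

#' @noRd
pileup_native <- function(reads, reference, min_base_quality) {
  if (nrow(reads) == 0) {
    return(tibble(ref = character(), pos = integer(), ref_base = character(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  coverage = integer()))
  }
  bad <- setdiff(unique(reads$ref), names(reference))
  if (length(bad) > 0) {
    abort(paste0("alignment reference(s) absent from FASTA: ",
                 paste(bad, collapse = ",")), class = "stamper_input_error")
  }
  lens <- nchar(reads$seq)
  rid <- rep.int(match(reads$ref, names(reference)), lens)
  pos0 <- sequence(lens) - 1L + rep.int(as.integer(reads$start), lens)
  bcode <- as.integer(charToRaw(paste(reads$seq, collapse = "")))
  q <- as.integer(charToRaw(paste(reads$qual, collapse = ""))) - 33L
  keep <- q >= min_base_quality
  maxlen <- max(nchar(reference))
  key <- (rid - 1) * maxlen + pos0 + 1
  nbins <- length(reference) * maxlen
  cnt <- function(code) tabulate(key[keep & bcode == code], nbins = nbins)
  a <- cnt(65L); c_ <- cnt(67L); g <- cnt(71L); t <- cnt(84L)
  cov <- tabulate(key[keep], nbins = nbins)
  nz <- which(cov > 0)
  refn <- names(reference)[(nz - 1) %/% maxlen + 1]
  p0 <- as.integer((nz - 1) %% maxlen)
  tibble(ref = refn, pos = p0,
         ref_base = substr(reference[refn], p0 + 1, p0 + 1),
         A = a[nz], C = c_[nz], G = g[nz], T = t[nz],
         coverage = cov[nz]) %>%
    arrange(.data$ref, .data$pos)
}

#' @noRd
pileup_rsamtools <- function(path, reference, min_base_quality) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    sorted <- Rsamtools::sortBam(path, tempfile())
    Rsamtools::indexBam(sorted)
    path <- sorted
  }
  bf <- Rsamtools::BamFile(path)
  hdr_refs <- names(Rsamtools::scanBamHeader(bf)$targets)
  bad <- setdiff(hdr_refs, names(reference))
  if (length(bad) > 0) {
    abort(paste0("alignment reference(s) absent from FASTA: ",
                 paste(bad, collapse = ",")), class = "stamper_input_error")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = as.integer(min_base_quality),
    min_mapq = 0L, min_nucleotide_depth = 1L, min_minor_allele_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE, include_deletions = FALSE,
    include_insertions = FALSE)
  res <- Rsamtools::pileup(bf, scanBamParam = Rsamtools::ScanBamParam(flag = flag),
                           pileupParam = pp)
  res <- as_tibble(res) %>%
    mutate(ref = as.character(.data$seqnames), pos = .data$pos - 1L,
           nucleotide = as.character(.data$nucleotide)) %>%
    select("ref", "pos", "nucleotide", "count")
  wide <- res %>%
    tidyr::pivot_wider(names_from = "nucleotide", values_from = "count",
                       values_fill = 0L)
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(wide)) wide[[b]] <- 0L
  }
  extra <- setdiff(names(wide), c("ref", "pos", "A", "C", "G", "T"))
  cov <- Reduce(`+`, c(wide[c("A", "C", "G", "T")], wide[extra]))
  wide %>%
    mutate(coverage = as.integer(cov),
           ref_base = substr(reference[.data$ref], .data$pos + 1,
                             .data$pos + 1)) %>%
    select("ref", "pos", "ref_base", "A", "C", "G", "T", "coverage") %>%
    arrange(.data$ref, .data$pos)
}

#' Read the alignment records of a SAM file as a reads tibble
#'
#' Minimal ingestion for the package's own ungapped single-end records;
#' general SAM/BAM should go through the `"rsamtools"` pileup engine.
#' @param path SAM file.
#' @return Tibble `qname`, `ref`, `start` (0-based), `seq`, `qual`.
#' @export
read_sam_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  flags <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flags, 0x904L) == 0L  # drop unmapped/secondary/supplementary
  f <- f[keep]
  tibble(qname = vapply(f, `[[`, character(1), 1),
         ref = vapply(f, `[[`, character(1), 3),
         start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
         seq = vapply(f, `[[`, character(1), 10),
         qual = vapply(f, `[[`, character(1), 11))
}

#' Call candidate edit sites from a base-count matrix
#'
#' Reports a site wherever the reference base matches the channel's
#' substrate, coverage reaches `min_coverage`, at least one read carries
#' the edited base, and the position is not masked as a known SNV. Each
#' site gets a confidence score: the posterior probability that the true
#' editing fraction exceeds `error_rate`, under a uniform Beta(1, 1) prior
#' and a binomial likelihood —
#' `1 - pbeta(error_rate, alt_count + 1, coverage - alt_count + 1)`.
#' The conventional confidence cutoff downstream is 0.9.
#'
#' For reverse-stranded libraries (`strand = "-"`), substrate and product
#' bases are complemented in reference coordinates (C2U reads as G-to-A).
#'
#' @param matrix Base-count tibble from [pileup_counts()].
#' @param edit_type `"C2U"` or `"A2I"` (call `"DUAL"` enzymes once per
#'   channel and combine with [combine_edit_channels()]).
#' @param min_coverage Minimum coverage (default 5).
#' @param error_rate Null editing fraction for the confidence score
#'   (default 0.001).
#' @param snv_mask Optional tibble `ref`, `start`, `end` (0-based
#'   half-open) of positions to exclude (known variants).
#' @param strand `"+"` (stranded-sense, default) or `"-"`.
#' @return Tibble of edit sites: `ref`, `pos` (0-based), `strand`,
#'   `edit_type`, `ref_base`, `alt_base`, `coverage`, `alt_count`,
#'   `fraction`, `confidence`.
#' @examples
#' m <- tibble::tibble(ref = "r", pos = 0L, ref_base = "C",
#'                     A = 0L, C = 7L, G = 0L, T = 3L, coverage = 10L)
#' call_edits(m, "C2U")
#' @export
call_edits <- function(matrix, edit_type, min_coverage = 5,
                       error_rate = 0.001, snv_mask = NULL,
                       strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (identical(edit_type, "DUAL")) {
    abort("call_edits() handles one channel; call per channel and use combine_edit_channels().")
  }
  if (min_coverage < 1) abort("`min_coverage` must be >= 1.")
  if (error_rate <= 0 || error_rate >= 1) {
    abort("`error_rate` must lie in (0, 1).")
  }
  sub <- substrate_base(edit_type)
  alt <- product_base(edit_type)
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    sub <- comp[[sub]]
    alt <- comp[[alt]]
  }
  m <- matrix %>%
    filter(.data$ref_base == sub, .data$coverage >= min_coverage)
  if (!is.null(snv_mask) && nrow(snv_mask) > 0 && nrow(m) > 0) {
    masked <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(snv_mask))) {
      masked <- masked | (m$ref == snv_mask$ref[i] &
                            m$pos >= snv_mask$start[i] &
                            m$pos < snv_mask$end[i])
    }
    m <- m[!masked, , drop = FALSE]
  }
  m %>%
    mutate(alt_count = .data[[alt]]) %>%
    filter(.data$alt_count >= 1) %>%
    transmute(
      ref = .data$ref, pos = .data$pos, strand = strand,
      edit_type = edit_type, ref_base = .data$ref_base, alt_base = alt,
      coverage = .data$coverage, alt_count = .data$alt_count,
      fraction = .data$alt_count / .data$coverage,
      confidence = 1 - pbeta(error_rate, .data$alt_count + 1,
                             .data$coverage - .data$alt_count + 1))
}

#' Combine C-to-U and A-to-I edit-site tables
#'
#' Concatenates the two channels of a dual-modality enzyme into one table
#' with a stable (reference, position) sort. Duplicate
#' (reference, position, edit_type) entries indicate the same channel was
#' called twice and raise an error.
#'
#' @param c2u_sites,a2i_sites Edit-site tibbles from [call_edits()].
#' @return A single sorted edit-site tibble.
#' @export
combine_edit_channels <- function(c2u_sites, a2i_sites) {
  out <- bind_rows(c2u_sites, a2i_sites)
  if (nrow(out) == 0) return(out)
  key <- paste(out$ref, out$pos, out$edit_type)
  if (anyDuplicated(key)) {
    abort("duplicate (ref, pos, edit_type) entries in combined channels.",
          class = "stamper_internal_error")
  }
  arrange(out, .data$ref, .data$pos)
}
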