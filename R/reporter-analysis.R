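#' Per-position editing profile of a reporter construct
#'
#' Computes, at every position of the construct, the fraction of covered
#' bases read as edited: C-to-U fraction `T / (C + T)` at reference-C
#' positions and A-to-I fraction `G / (A + G)` at reference-A positions
#' (0 at non-substrate positions), together with edited-read counts,
#' coverage, and CDS/3'UTR/loop annotation. Positions with coverage below
#' `min_coverage` are masked (`NA` fractions) rather than shown as 0.
#'
#' @param matrix Base-count tibble from [pileup_counts()] built against the
#'   construct sequence.
#' @param spec The [build_reporter()] construct.
#' @param edit_types Channels to profile (`"C2U"`, `"A2I"`, or both).
#' @param min_coverage Mask positions below this coverage.
#' @return A tibble of class `reporter_profile` with one row per construct
#'   position: `pos` (0-based), `ref_base`, `coverage`, `region`, `loop`,
#'   `c2u_fraction`, `c2u_count`, `a2i_fraction`, `a2i_count`.
#' @export
profile_reporter <- function(matrix, spec, edit_types = c("C2U", "A2I"),
                             min_coverage = 5) {
  stopifnot(inherits(spec, "reporter_spec"))
  len <- nchar(spec$full_seq)
  if (nrow(matrix) > 0 && max(matrix$pos) >= len) {
    abort("base-count matrix extends past the construct; length mismatch.",
          class = "stamper_input_error")
  }
  chars <- seq_chars(spec$full_seq)
  prof <- tibble(pos = 0:(len - 1L), ref_base = chars) %>%
    left_join(select(matrix, "pos", "A", "C", "G", "T", "coverage"),
              by = "pos") %>%
    mutate(across(c("A", "C", "G", "T", "coverage"),
                  ~ tidyr::replace_na(.x, 0L)))

  cds_len <- nchar(spec$cds_seq)
  loops <- spec$loop_intervals
  loop_of <- rep(NA_character_, len)
  for (i in seq_len(nrow(loops))) {
    loop_of[(loops$start[i] + 1):loops$end[i]] <- loops$kind[i]
  }

  covered <- prof$coverage >= min_coverage
  c2u_count <- ifelse(prof$ref_base == "C", prof$T, 0L)
  a2i_count <- ifelse(prof$ref_base == "A", prof$G, 0L)
  c2u_frac <- ifelse(prof$ref_base == "C",
                     prof$T / pmax(1L, prof$C + prof$T), 0)
  a2i_frac <- ifelse(prof$ref_base == "A",
                     prof$G / pmax(1L, prof$A + prof$G), 0)
  out <- prof %>%
    mutate(region = if_else(.data$pos < cds_len, "CDS", "UTR3"),
           loop = loop_of,
           c2u_fraction = ifelse(covered, c2u_frac, NA_real_),
           c2u_count = if ("C2U" %in% edit_types) c2u_count else 0L,
           a2i_fraction = ifelse(covered, a2i_frac, NA_real_),
           a2i_count = if ("A2I" %in% edit_types) a2i_count else 0L) %>%
    select("pos", "ref_base", "coverage", "region", "loop",
           "c2u_fraction", "c2u_count", "a2i_fraction", "a2i_count")
  if (!"C2U" %in% edit_types) out$c2u_fraction <- NA_real_
  if (!"A2I" %in% edit_types) out$a2i_fraction <- NA_real_
  class(out) <- c("reporter_profile", class(out))
  attr(out, "construct") <- spec$name
  attr(out, "cds_length") <- cds_len
  out
}

#' Edit spillover onto the coding sequence
#'
#' Fraction of all edited-read observations on the construct that fall in
#' the CDS rather than the stem-loop 3'UTR — a proxy for how far an
#' enzyme's activity spreads beyond its tether.
#'
#' @param profile A [profile_reporter()] result.
#' @return A single fraction in `[0, 1]`; `NA` (with a warning) when the
#'   construct carries no edits at all.
#' @export
spillover_index <- function(profile) {
  stopifnot(inherits(profile, "reporter_profile"))
  edited <- profile$c2u_count + profile$a2i_count
  total <- sum(edited)
  if (total == 0) {
    warn("no edits on the construct; spillover index undefined.")
    return(NA_real_)
  }
  sum(edited[profile$region == "CDS"]) / total
}

#' On/off-target editing ratio
#'
#' The reporter screen's signal-to-noise metric: the number of edited
#' read-base observations on reads mapped to the reporter construct
#' (on-target), divided by the number on reads mapped to the rest of the
#' transcriptome (off-target). Replicates are kept as separate rows;
#' sum the counts first for a pooled ratio.
#'
#' @param construct_edit_count,genome_edit_count Non-negative counts
#'   (vectors for replicates); see [count_edit_observations()].
#' @param sample Optional sample labels.
#' @return Tibble `sample`, `on_target_edits`, `off_target_edits`, `ratio`,
#'   `undefined` (TRUE where the off-target count is 0 and the ratio is NA).
#' @examples
#' on_off_ratio(c(100, 120), c(50, 40), sample = c("rep1", "rep2"))
#' @export
on_off_ratio <- function(construct_edit_count, genome_edit_count,
                         sample = NULL) {
  stopifnot(all(construct_edit_count >= 0), all(genome_edit_count >= 0),
            length(construct_edit_count) == length(genome_edit_count))
  if (is.null(sample)) {
    sample <- paste0("rep", seq_along(construct_edit_count))
  }
  tibble(sample = sample,
         on_target_edits = construct_edit_count,
         off_target_edits = genome_edit_count,
         ratio = ifelse(genome_edit_count > 0,
                        construct_edit_count / genome_edit_count, NA_real_),
         undefined = genome_edit_count == 0)
}

#' Total edited read-base observations in an edit-site table
#'
#' @param sites Edit-site tibble from [call_edits()].
#' @param min_confidence Keep sites at or above this confidence (default 0,
#'   i.e. all).
#' @return Sum of `alt_count` over retained sites.
#' @export
count_edit_observations <- function(sites, min_confidence = 0) {
  if (nrow(sites) == 0) return(0L)
  sum(sites$alt_count[sites$confidence >= min_confidence])
}
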