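#' Per-position editing probabilities implied by enzyme models
#'
#' For every reference sequence and every editing channel of every enzyme,
#' computes the expected per-read probability that each substrate base
#' (reference C for C2U, reference A for A2I; sense strand) is edited:
#' `min(1, peak_rate * kernel(d) * context_weight) + background_rate`,
#' capped at 1, with `d` the distance to the midpoint of the nearest bound
#' site assigned to the enzyme. Positions whose reference base is not the
#' channel's substrate have probability 0. Flank context uses the bases at
#' `pos - 1` and `pos + 1`; sequence-edge positions take context weight 1.
#'
#' @param reference Named character vector (or DNAStringSet) of sequences.
#' @param bound_sites Tibble `ref`, `start`, `end`, `enzyme` (0-based
#'   half-open), or `NULL` for untethered (background-only) enzymes.
#' @param enzymes List of [enzyme_model()] objects.
#' @param interference Multiplicative factor in `[0, 1]` applied to the
#'   targeted (kernel) component when two or more enzymes are co-simulated;
#'   models mutual interference of co-recruited editors. Default 1 (off).
#' @return A list with one element per (enzyme, channel): each a list with
#'   `enzyme`, `edit_type`, and `p`, a named list of per-reference numeric
#'   probability vectors (one entry per base, 0-based position `i` at
#'   element `i + 1`).
#' @export
edit_probability <- function(reference, bound_sites = NULL, enzymes = list(),
                             interference = 1) {
  reference <- as_reference(reference)
  if (inherits(enzymes, "enzyme_model")) enzymes <- list(enzymes)
  if (interference < 0 || interference > 1) {
    abort("`interference` must lie in [0, 1].",
          class = "stamper_config_error")
  }
  interf <- if (length(enzymes) >= 2) interference else 1
  ctx_names <- context_names()

  out <- list()
  for (enz in enzymes) {
    stopifnot(inherits(enz, "enzyme_model"))
    sites <- if (!is.null(bound_sites)) {
      bound_sites[bound_sites$enzyme == enz$name, , drop = FALSE]
    }
    for (ch in enz$channels) {
      sub <- substrate_base(ch$edit_type)
      p_ref <- lapply(names(reference), function(rn) {
        chars <- seq_chars(reference[[rn]])
        len <- length(chars)
        p <- numeric(len)
        is_sub <- chars == sub
        if (!any(is_sub)) return(p)
        pos0 <- which(is_sub) - 1L  # 0-based
        # flanking-context weight applies everywhere the enzyme acts,
        # tethered or free: it is an intrinsic property of the deaminase
        up <- ifelse(pos0 >= 1, chars[pos0], "A")
        dn <- ifelse(pos0 + 2 <= len, chars[pos0 + 2], "A")
        ctx <- paste0(up, dn)
        w <- numeric(length(pos0))
        known <- ctx %in% ctx_names
        w[known] <- ch$context_weights[ctx[known]]
        targeted <- numeric(length(pos0))
        if (!is.null(sites)) {
          s <- sites[sites$ref == rn, , drop = FALSE]
          if (nrow(s) > 0) {
            mids <- (s$start + s$end - 1) / 2
            d <- vapply(pos0, function(x) min(abs(x - mids)), numeric(1))
            targeted <- pmin(1, ch$peak_rate *
                               recruitment_kernel(d, ch$kernel_halfwidth) * w)
          }
        }
        p[pos0 + 1L] <- pmin(1, targeted * interf + ch$background_rate * w)
        p
      })
      names(p_ref) <- names(reference)
      out[[length(out) + 1]] <- list(enzyme = enz$name,
                                     edit_type = ch$edit_type, p = p_ref)
    }
  }
  out
}

#' Simulate edited sequencing reads with full ground truth
#'
#' Samples single-end reads from the reference (uniformly over eligible
#' start positions, or by per-reference weights), deposits enzyme edits on
#' each read according to [edit_probability()], then applies an independent
#' substitution-only sequencing-error process. Reads are emitted with an
#' ungapped placement so alignments are known without an external aligner.
#'
#' @inheritParams edit_probability
#' @param n_reads Total number of reads.
#' @param read_length Read length in bp (default 100, single-end).
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param error_rate Per-base substitution sequencing-error probability
#'   (default `1e-3`); applied after editing.
#' @param ref_weights Optional named non-negative weights per reference;
#'   default weights each reference by its number of eligible start
#'   positions (uniform coverage).
#' @param reads_per_ref Optional named integer vector fixing the exact read
#'   count per reference (overrides `n_reads`/`ref_weights`).
#' @param channels Advanced: a precomputed [edit_probability()]-style
#'   channel list to use instead of deriving one from `bound_sites` and
#'   `enzymes` (used e.g. by [simulate_translation()], whose per-base
#'   editing probabilities follow ribosome load rather than a recruitment
#'   kernel).
#' @return An object of class `sim_reads`: list with `reads` (tibble
#'   `qname`, `ref`, `start` 0-based, `seq`, `qual`), `reference`, `truth`
#'   (list: `site_prob` per-position expected edit probability per enzyme
#'   channel; `read_edits` per-read introduced edits; `errors` per-read
#'   sequencing errors), and `read_length`.
#' @examples
#' ref <- c(chr = strrep("ACGT", 50))
#' sr <- simulate_reads(ref, enzymes = list(), n_reads = 10,
#'                      read_length = 50, seed = 1, error_rate = 0)
#' sr$reads$seq[1]
#' @export
simulate_reads <- function(reference, bound_sites = NULL, enzymes = list(),
                           n_reads = 1000, read_length = 100, seed = 1L,
                           error_rate = 1e-3, ref_weights = NULL,
                           reads_per_ref = NULL, interference = 1,
                           channels = NULL) {
  reference <- as_reference(reference)
  if (inherits(enzymes, "enzyme_model")) enzymes <- list(enzymes)
  if (error_rate < 0 || error_rate > 1) {
    abort("`error_rate` must lie in [0, 1].", class = "stamper_config_error")
  }
  len <- nchar(reference)
  if (read_length > max(len)) {
    abort("`read_length` exceeds every reference length.",
          class = "stamper_config_error")
  }
  eligible <- setNames(pmax(0L, len - read_length + 1L), names(reference))
  if (is.null(channels)) {
    channels <- edit_probability(reference, bound_sites, enzymes, interference)
  }

  with_seed(seed, {
    if (is.null(reads_per_ref)) {
      w <- if (is.null(ref_weights)) {
        eligible
      } else {
        stopifnot(all(names(reference) %in% names(ref_weights)))
        ref_weights[names(reference)] * (eligible > 0)
      }
      if (sum(w) <= 0) abort("no reference admits a read of this length.")
      ref_of_read <- sample(names(reference), n_reads, replace = TRUE,
                            prob = w / sum(w))
      reads_per_ref <- table(factor(ref_of_read, levels = names(reference)))
    } else {
      stopifnot(all(names(reads_per_ref) %in% names(reference)))
      reads_per_ref <- reads_per_ref[intersect(names(reference),
                                               names(reads_per_ref))]
    }

    all_reads <- list()
    all_edits <- list()
    all_errs <- list()
    qoff <- 0L
    for (rn in names(reference)) {
      nr <- as.integer(reads_per_ref[rn] %||% 0L)
      if (is.na(nr) || nr == 0) next
      if (eligible[[rn]] <= 0) {
        abort(paste0("reference ", rn, " shorter than read_length."),
              class = "stamper_config_error")
      }
      chars <- seq_chars(reference[[rn]])
      starts <- sample.int(eligible[[rn]], nr, replace = TRUE) - 1L
      off <- 0:(read_length - 1L)
      idx1 <- rep(starts, each = read_length) + off + 1L  # 1-based ref index
      read_id <- rep(seq_len(nr), each = read_length)
      mat <- chars[idx1]
      qnames <- sprintf("read%06d", qoff + seq_len(nr))

      for (chn in channels) {
        p <- chn$p[[rn]][idx1]
        hit <- runif(length(idx1)) < p
        if (any(hit)) {
          mat[hit] <- product_base(chn$edit_type)
          all_edits[[length(all_edits) + 1]] <- tibble(
            qname = qnames[read_id[hit]], ref = rn, pos = idx1[hit] - 1L,
            edit_type = chn$edit_type, enzyme = chn$enzyme)
        }
      }

      if (error_rate > 0) {
        err <- which(runif(length(idx1)) < error_rate)
        if (length(err) > 0) {
          cur <- match(mat[err], DNA_BASES)
          shift <- sample.int(3L, length(err), replace = TRUE)
          newb <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
          all_errs[[length(all_errs) + 1]] <- tibble(
            qname = qnames[read_id[err]], ref = rn, pos = idx1[err] - 1L,
            from = mat[err], to = newb)
          mat[err] <- newb
        }
      }

      dim(mat) <- c(read_length, nr)
      seqs <- do.call(paste0, asplit(mat, 1))
      all_reads[[length(all_reads) + 1]] <- tibble(
        qname = qnames, ref = rn, start = starts, seq = seqs,
        qual = strrep("I", read_length))
      qoff <- qoff + nr
    }
  })

  site_prob <- purrr::map_dfr(channels, function(chn) {
    purrr::map_dfr(names(chn$p), function(rn) {
      p <- chn$p[[rn]]
      nz <- which(p > 0)
      if (length(nz) == 0) return(tibble())
      tibble(enzyme = chn$enzyme, edit_type = chn$edit_type, ref = rn,
             pos = nz - 1L, prob = p[nz])
    })
  })

  empty_edits <- tibble(qname = character(), ref = character(),
                        pos = integer(), edit_type = character(),
                        enzyme = character())
  structure(list(
    reads = bind_rows(all_reads),
    reference = reference,
    read_length = read_length,
    truth = list(
      site_prob = site_prob,
      read_edits = if (length(all_edits)) bind_rows(all_edits) else empty_edits,
      errors = if (length(all_errs)) bind_rows(all_errs) else
        tibble(qname = character(), ref = character(), pos = integer(),
               from = character(), to = character()),
      bound_sites = bound_sites)
  ), class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("<sim_reads> ", nrow(x$reads), " reads x ", x$read_length, " bp on ",
      length(x$reference), " reference(s); ", nrow(x$truth$read_edits),
      " true edits, ", nrow(x$truth$errors), " sequencing errors\n", sep = "")
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param x A `sim_reads` object or a reads tibble (`qname`, `seq`, `qual`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  reads <- if (inherits(x, "sim_reads")) x$reads else x
  lines <- as.vector(rbind(paste0("@", reads$qname), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulated reads as an ungapped SAM file
#'
#' Records are emitted pre-aligned (flag 0, MAPQ 60, full-match CIGAR) so
#' downstream pileup can run without an external aligner.
#'
#' @param x A `sim_reads` object, or a reads tibble (then `reference` must
#'   be given).
#' @param path Output SAM file.
#' @param reference Named character vector of reference sequences (for the
#'   `@SQ` header lines).
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path, reference = NULL) {
  if (inherits(x, "sim_reads")) {
    reference <- x$reference
    reads <- x$reads
  } else {
    reads <- x
    if (is.null(reference)) abort("`reference` required for a reads tibble.")
    reference <- as_reference(reference)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  cigar <- paste0(nchar(reads$seq), "M")
  rec <- paste(reads$qname, 0L, reads$ref, reads$start + 1L, 60L, cigar,
               "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}
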