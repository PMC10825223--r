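#' @noRd
DNA_BASES <- c("A", "C", "G", "T")

#' Sample a random DNA string
#'
#' Bases are drawn independently; `gc` sets the total probability of G or C
#' (split evenly between the two, as between A and T).
#'
#' @param n Length in bases.
#' @param gc GC fraction in `[0, 1]`.
#' @return A single character string of length `n`.
#' @noRd
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Split a DNA string into a character vector of single bases
#' @noRd
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Reverse complement (DNA alphabet; non-ACGT untouched except N)
#' @noRd
revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", vapply(seq, function(s) {
    paste(rev(seq_chars(s)), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Coerce reference sequences to a named character vector
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], or a
#' single-column named list.
#' @noRd
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (is.list(reference)) reference <- unlist(reference)
  if (!is.character(reference) || is.null(names(reference)) ||
      any(!nzchar(names(reference)))) {
    abort("`reference` must be a named character vector or DNAStringSet.")
  }
  toupper(reference)
}

#' Write reference sequences as FASTA
#'
#' @param reference Named character vector or DNAStringSet.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  reference <- as_reference(reference)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), filepath = path)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), names(x))
}

#' Run code with a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a stream-specific child seed from a scalar seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1103L + as.numeric(k) * 7919) %% 2147483647
}
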