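#' @noRd
interval_key <- function(x, strand_aware = FALSE) {
  if (strand_aware && "strand" %in% names(x)) {
    paste(x$ref, x$strand)
  } else {
    x$ref
  }
}

#' Which query intervals overlap any subject interval (>= 1 bp)
#' @noRd
interval_overlaps_any <- function(query, subject, strand_aware = FALSE) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  qk <- interval_key(query, strand_aware)
  sk <- interval_key(subject, strand_aware)
  out <- rep(FALSE, nrow(query))
  for (k in unique(qk)) {
    qi <- which(qk == k)
    si <- which(sk == k)
    if (length(si) == 0) next
    out[qi] <- IRanges::overlapsAny(
      IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
      IRanges::IRanges(subject$start[si] + 1L, subject$end[si]))
  }
  out
}

#' Fraction of query intervals overlapping a subject set
#'
#' The fraction of query intervals that overlap (by at least 1 bp) at
#' least one subject interval — e.g. the fraction of edit clusters
#' coinciding with eCLIP peaks. Overlap is strand-aware when both tables
#' carry a `strand` column (set `strand_aware = FALSE` to ignore it).
#'
#' @param query,subject Interval tibbles `ref`, `start`, `end` (0-based
#'   half-open), optionally `strand`.
#' @param strand_aware Respect strand when present (default TRUE).
#' @return A single fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(query, subject, strand_aware = TRUE) {
  if (nrow(query) == 0) abort("`query` is empty.",
                              class = "stamper_input_error")
  mean(interval_overlaps_any(query, subject, strand_aware = strand_aware))
}

#' Permutation test of interval-set overlap enrichment
#'
#' Compares the observed [overlap_fraction()] of a query set against the
#' subject set with an empirical null in which each query interval is
#' re-placed, length-preserved, uniformly at random within the allowed
#' placement domain (e.g. the transcribed regions of the annotation). A
#' domain region is chosen with probability proportional to the number of
#' start positions that fit the interval, so placement is uniform over all
#' admissible positions. The empirical p-value uses the add-one rule
#' `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param query Interval tibble to test.
#' @param subject Reference interval set (e.g. eCLIP peaks).
#' @param domain Interval tibble of allowed placement regions; every query
#'   interval must fit inside at least one region.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `permutation_result` with `observed`, `null`
#'   (length `n_perm`), `p_value`, `enrichment`
#'   (`observed / mean(null)`), `n_perm`, `n_query`, and `seed`.
#'   [tidy()] returns the null draws, [glance()] the summary row.
#' @export
permute_intervals <- function(query, subject, domain, n_perm = 200,
                              seed = 1L) {
  if (nrow(query) == 0) abort("`query` is empty.",
                              class = "stamper_input_error")
  qw <- query$end - query$start
  dw <- domain$end - domain$start
  if (any(qw > max(dw))) {
    abort("a query interval is longer than every domain region.",
          class = "stamper_input_error")
  }
  observed <- overlap_fraction(query, subject, strand_aware = FALSE)

  nq <- nrow(query)
  starts <- matrix(0L, nq, n_perm)
  refs <- matrix("", nq, n_perm)
  with_seed(seed, {
    for (w in unique(qw)) {
      rows <- which(qw == w)
      elig <- which(dw >= w)
      slots <- dw[elig] - w + 1
      ndraw <- length(rows) * n_perm
      pick <- elig[sample.int(length(elig), ndraw, replace = TRUE,
                              prob = slots)]
      off <- floor(runif(ndraw) * (dw[pick] - w + 1))
      starts[rows, ] <- domain$start[pick] + off
      refs[rows, ] <- domain$ref[pick]
    }
  })

  placed <- tibble(ref = as.vector(refs), start = as.vector(starts),
                   end = as.vector(starts) + rep(qw, times = n_perm),
                   perm = rep(seq_len(n_perm), each = nq))
  hit <- interval_overlaps_any(placed, subject)
  null <- as.numeric(tapply(hit, placed$perm, mean))

  structure(list(
    observed = observed,
    null = null,
    p_value = (1 + sum(null >= observed)) / (1 + n_perm),
    enrichment = if (mean(null) > 0) observed / mean(null) else NA_real_,
    n_perm = n_perm, n_query = nq, seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed=%.4f null mean=%.4f p=%.4g enrichment=%.2f (n_perm=%d, n_query=%d)\n",
    x$observed, mean(x$null), x$p_value, x$enrichment, x$n_perm, x$n_query))
  invisible(x)
}

#' Combine cluster sets into one flattened interval set
#'
#' Unions two or more interval sets, merging overlapping intervals into
#' maximal runs; each merged region keeps the labels of the input sets
#' that contributed to it.
#'
#' @param cluster_sets Named (or unnamed) list of >= 2 interval tibbles.
#' @return Tibble `ref`, `start`, `end`, `sets` (comma-separated source
#'   labels).
#' @export
combined_set <- function(cluster_sets) {
  if (!is.list(cluster_sets) || length(cluster_sets) < 2) {
    abort("need at least two cluster sets.", class = "stamper_input_error")
  }
  labels <- names(cluster_sets) %||% paste0("set", seq_along(cluster_sets))
  if (is.null(names(cluster_sets))) names(cluster_sets) <- labels
  all <- purrr::imap_dfr(cluster_sets, function(x, nm) {
    if (nrow(x) == 0) return(tibble())
    tibble(ref = x$ref, start = x$start, end = x$end, set = nm)
  })
  if (nrow(all) == 0) {
    return(tibble(ref = character(), start = integer(), end = integer(),
                  sets = character()))
  }
  flat <- purrr::map_dfr(split(all, all$ref), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    tibble(ref = d$ref[1], start = IRanges::start(r) - 1L,
           end = IRanges::end(r))
  })
  flat$sets <- vapply(seq_len(nrow(flat)), function(i) {
    reg <- flat[i, , drop = FALSE]
    members <- labels[vapply(labels, function(nm) {
      any(interval_overlaps_any(reg, cluster_sets[[nm]]))
    }, logical(1))]
    paste(members, collapse = ",")
  }, character(1))
  arrange(flat, .data$ref, .data$start)
}

#' Intersection-pattern (upset) counts of cluster sets
#'
#' Flattens the union of all sets into maximal regions and counts, for
#' every non-empty subset pattern of the inputs, the regions supported by
#' exactly the sets in that pattern (membership by >= 1 bp overlap).
#'
#' @param cluster_sets Named (or unnamed) list of >= 2 interval tibbles.
#' @return Tibble `pattern` (labels joined by `&`), `degree`, `n`.
#' @export
upset_counts <- function(cluster_sets) {
  flat <- combined_set(cluster_sets)
  if (nrow(flat) == 0) {
    return(tibble(pattern = character(), degree = integer(), n = integer()))
  }
  flat %>%
    mutate(pattern = gsub(",", "&", .data$sets, fixed = TRUE),
           degree = stringr::str_count(.data$sets, ",") + 1L) %>%
    count(.data$pattern, .data$degree, name = "n") %>%
    arrange(dplyr::desc(.data$n))
}
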