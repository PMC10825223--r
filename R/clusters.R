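#' Bin confident edit sites into fixed 30-bp windows
#'
#' Tiles the span of every gene exhibiting edits (at least one site) with
#' fixed-width bins anchored at the gene 5' end, and tallies confident
#' edit sites (or, optionally, edited-read counts) per bin. All bins of an
#' edited gene are returned — including zero-edit bins, which anchor the
#' background editing rate; genes without any edit contribute no bins.
#' `editable_count` is the number of substrate positions (reference C for
#' C2U, A for A2I) in the bin with coverage at least `min_coverage`,
#' computed from the base-count matrix; bins with no editable position are
#' dropped as uninformative.
#'
#' @param sites Edit-site tibble (already confidence-filtered upstream).
#' @param models Gene-model tibble (`gene_id`, `seqname`, `length`).
#' @param matrix Base-count tibble from [pileup_counts()] (for editable
#'   positions).
#' @param bin_size Bin width in bp (default 30); terminal partial bins are
#'   retained.
#' @param min_coverage Coverage floor for a position to count as editable.
#' @param count_mode `"sites"` (default: confident edit sites per bin) or
#'   `"reads"` (edited-read observations, `alt_count` summed).
#' @return Tibble of bins: `ref`, `gene_id`, `edit_type`, `start`, `end`,
#'   `editable_count`, `edited_count`, `editing_fraction`. Sites outside
#'   every gene are dropped with a message.
#' @export
bin_edits <- function(sites, models, matrix, bin_size = 30,
                      min_coverage = 5, count_mode = c("sites", "reads")) {
  count_mode <- match.arg(count_mode)
  stopifnot(bin_size >= 1)
  bin_size <- as.integer(bin_size)
  empty <- tibble(ref = character(), gene_id = character(),
                  edit_type = character(), start = integer(),
                  end = integer(), editable_count = integer(),
                  edited_count = integer(), editing_fraction = numeric())
  if (nrow(sites) == 0) return(empty)

  gidx <- match(sites$ref, models$seqname)
  if (anyNA(gidx)) {
    message(sum(is.na(gidx)), " edit site(s) outside any gene; dropped.")
    sites <- sites[!is.na(gidx), , drop = FALSE]
    gidx <- gidx[!is.na(gidx)]
  }
  if (nrow(sites) == 0) return(empty)

  mstart <- if ("start" %in% names(models)) models$start else
    rep(0L, nrow(models))
  goff <- setNames(as.integer(mstart), models$gene_id)
  glen <- setNames(as.integer(models$length), models$gene_id)

  sites <- mutate(sites, gene_id = models$gene_id[gidx],
                  weight = if (count_mode == "reads") .data$alt_count else 1L)

  purrr::map_dfr(unique(sites$edit_type), function(et) {
    s <- sites[sites$edit_type == et, , drop = FALSE]
    genes <- sort(unique(s$gene_id))
    # tile every edited gene from its 5' end
    grid <- purrr::map_dfr(genes, function(g) {
      nb <- ceiling(glen[[g]] / bin_size)
      start <- goff[[g]] + (seq_len(nb) - 1L) * bin_size
      tibble(ref = models$seqname[match(g, models$gene_id)], gene_id = g,
             bin = seq_len(nb) - 1L, start = start,
             end = pmin(start + bin_size, goff[[g]] + glen[[g]]))
    })
    edited <- s %>%
      mutate(bin = (.data$pos - goff[.data$gene_id]) %/% bin_size) %>%
      group_by(.data$gene_id, .data$bin) %>%
      summarise(edited_count = sum(.data$weight), .groups = "drop")
    sub <- substrate_base(et)
    m <- matrix[matrix$ref_base == sub & matrix$coverage >= min_coverage &
                  matrix$ref %in% unique(grid$ref), , drop = FALSE]
    editable <- m %>%
      mutate(gene_id = models$gene_id[match(.data$ref, models$seqname)],
             bin = (.data$pos - goff[.data$gene_id]) %/% bin_size) %>%
      filter(.data$gene_id %in% genes) %>%
      count(.data$gene_id, .data$bin, name = "editable_count")
    grid %>%
      left_join(edited, by = c("gene_id", "bin")) %>%
      left_join(editable, by = c("gene_id", "bin")) %>%
      mutate(edit_type = et,
             edited_count = tidyr::replace_na(.data$edited_count, 0L),
             editable_count = tidyr::replace_na(.data$editable_count, 0L),
             # a called site implies an editable position even if the bin
             # coverage filter missed it; only meaningful in sites mode
             editable_count = if (count_mode == "sites") {
               pmax(.data$editable_count, .data$edited_count)
             } else {
               pmax(.data$editable_count,
                    as.integer(.data$edited_count > 0))
             }) %>%
      filter(.data$editable_count > 0) %>%
      mutate(editing_fraction = .data$edited_count / .data$editable_count) %>%
      select("ref", "gene_id", "edit_type", "start", "end",
             "editable_count", "edited_count", "editing_fraction")
  }) %>%
    arrange(.data$ref, .data$start)
}

#' Background editing rate across bins
#'
#' The unweighted mean editing fraction (edited substrate positions over
#' editable substrate positions) across all bins of one editing channel.
#'
#' @param bins Bin tibble from [bin_edits()] (one edit type).
#' @return A single fraction.
#' @export
background_rate <- function(bins) {
  ok <- bins$editable_count > 0
  if (!any(ok)) abort("no bins with editable positions.",
                      class = "stamper_input_error")
  mean(bins$editing_fraction[ok])
}

#' One-sided Poisson test for elevated editing in a bin
#'
#' Tests whether a bin's edit count significantly exceeds what the
#' background editing rate predicts: with `lambda = bg * editable_count`,
#' the p-value is the upper tail `P(X >= edited_count)` for
#' `X ~ Poisson(lambda)`. When `bg = 0` the rate is floored at
#' `1e-6 * editable_count` to avoid degenerate zero p-values.
#'
#' @param bins Bin tibble (or any data frame with `edited_count` and
#'   `editable_count`).
#' @param bg Background editing fraction from [background_rate()].
#' @return Numeric vector of p-values, one per bin.
#' @examples
#' poisson_bin_test(tibble::tibble(edited_count = 4, editable_count = 20),
#'                  bg = 0.05)  # ~0.019
#' @export
poisson_bin_test <- function(bins, bg) {
  stopifnot(bg >= 0)
  lambda <- bg * bins$editable_count
  lambda[lambda <= 0] <- 1e-6 * pmax(1, bins$editable_count[lambda <= 0])
  ppois(bins$edited_count - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate control:
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1, returned in input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "stamper_input_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Add Poisson p-values and BH q-values to a bin table
#'
#' Convenience wrapper running [background_rate()], [poisson_bin_test()]
#' and [bh_adjust()] separately within each editing channel.
#'
#' @param bins Bin tibble from [bin_edits()].
#' @return The bins with `p_value` and `q_value` columns.
#' @export
test_bins <- function(bins) {
  bins %>%
    group_by(.data$edit_type) %>%
    dplyr::group_modify(function(b, key) {
      b$p_value <- poisson_bin_test(b, background_rate(b))
      b$q_value <- bh_adjust(b$p_value)
      b
    }) %>%
    ungroup() %>%
    select(names(bins), "p_value", "q_value")
}

#' Retain significant bins and merge them into clusters
#'
#' Keeps bins with `q_value` strictly below `fdr`, then merges consecutive
#' kept bins on the same reference whenever the gap between them
#' (`next start - previous end`) is at most `merge_gap`. A cluster's
#' p/q-values are the minima over its member bins; its coordinates are the
#' union span.
#'
#' @param bins Bin tibble with `p_value` and `q_value` (see [test_bins()]).
#' @param fdr FDR threshold (default 0.1, strict `<`).
#' @param merge_gap Maximum inter-bin gap in bp to merge (default 15).
#' @return Cluster tibble: `ref`, `gene_id`, `start`, `end`, `n_bins`,
#'   `edited_count`, `p_value`, `q_value`.
#' @export
filter_and_merge <- function(bins, fdr = 0.1, merge_gap = 15) {
  empty <- tibble(ref = character(), gene_id = character(),
                  start = integer(), end = integer(), n_bins = integer(),
                  edited_count = integer(), p_value = numeric(),
                  q_value = numeric())
  kept <- bins[bins$q_value < fdr, , drop = FALSE]
  if (nrow(kept) == 0) return(empty)
  if (is.unsorted(order(kept$ref, kept$start))) {
    message("bins unsorted; sorting by (ref, start).")
  }
  kept <- arrange(kept, .data$ref, .data$start)
  new_run <- c(TRUE, kept$ref[-1] != kept$ref[-nrow(kept)] |
                 kept$start[-1] - kept$end[-nrow(kept)] > merge_gap)
  kept$cluster <- cumsum(new_run)
  kept %>%
    group_by(.data$cluster) %>%
    summarise(ref = first(.data$ref), gene_id = first(.data$gene_id),
              start = min(.data$start), end = max(.data$end),
              n_bins = n(), edited_count = sum(.data$edited_count),
              p_value = min(.data$p_value), q_value = min(.data$q_value),
              .groups = "drop") %>%
    select(-"cluster") %>%
    arrange(.data$ref, .data$start)
}

#' Intersect cluster sets across replicates
#'
#' A cluster from the first set is retained iff it overlaps (by at least
#' 1 bp) at least one cluster in every other set; retained coordinates are
#' the first set's, and `replicate_support` records the number of
#' supporting replicates.
#'
#' @param cluster_sets List (length >= 2) of cluster tibbles.
#' @return The supported clusters of the first set.
#' @export
replicate_intersect <- function(cluster_sets) {
  if (!is.list(cluster_sets) || length(cluster_sets) < 2) {
    abort("need at least two cluster sets.", class = "stamper_input_error")
  }
  base <- cluster_sets[[1]]
  if (nrow(base) == 0) return(mutate(base, replicate_support = integer(0)))
  supported <- rep(TRUE, nrow(base))
  for (other in cluster_sets[-1]) {
    supported <- supported & interval_overlaps_any(base, other)
  }
  base %>%
    filter(supported) %>%
    mutate(replicate_support = length(cluster_sets))
}

#' Remove clusters explained by free-editor background
#'
#' Drops every cluster that overlaps (>= 1 bp) a cluster from the
#' untethered free-editor control — the background-noise set.
#'
#' @param rbp_clusters Fusion-experiment clusters.
#' @param free_rbe_clusters Replicate-intersected free-editor clusters.
#' @return The fusion clusters not overlapping any free-editor cluster.
#' @export
subtract_background <- function(rbp_clusters, free_rbe_clusters) {
  if (nrow(rbp_clusters) == 0 || nrow(free_rbe_clusters) == 0) {
    return(rbp_clusters)
  }
  rbp_clusters[!interval_overlaps_any(rbp_clusters, free_rbe_clusters), ,
               drop = FALSE]
}

#' Full cluster-calling pipeline over replicates
#'
#' For each replicate: confidence-filter the edit sites (strictly above
#' `min_confidence`), bin per editing channel, estimate the per-channel
#' background rate, Poisson-test each bin, BH-adjust, and filter/merge into
#' clusters. Replicate cluster sets are then intersected, and (optionally)
#' clusters replicating in a free-editor control are subtracted.
#'
#' @param site_sets List of edit-site tibbles, one per replicate.
#' @param models Gene-model tibble.
#' @param matrices List of base-count tibbles matching `site_sets`.
#' @param free_site_sets,free_matrices Optional free-editor replicates for
#'   background subtraction.
#' @param min_confidence Site confidence threshold (default 0.9).
#' @param fdr,bin_size,merge_gap,min_coverage,count_mode Passed through to
#'   the stage functions.
#' @return Cluster tibble with `replicate_support`.
#' @export
call_clusters <- function(site_sets, models, matrices,
                          free_site_sets = NULL, free_matrices = NULL,
                          min_confidence = 0.9, fdr = 0.1, bin_size = 30,
                          merge_gap = 15, min_coverage = 5,
                          count_mode = "sites") {
  one_rep <- function(sites, matrix) {
    sites <- sites[sites$confidence > min_confidence, , drop = FALSE]
    bins <- bin_edits(sites, models, matrix, bin_size = bin_size,
                      min_coverage = min_coverage, count_mode = count_mode)
    if (nrow(bins) == 0) {
      return(filter_and_merge(mutate(bins, p_value = numeric(0),
                                     q_value = numeric(0)), fdr, merge_gap))
    }
    filter_and_merge(test_bins(bins), fdr = fdr, merge_gap = merge_gap)
  }
  sets <- purrr::map2(site_sets, matrices, one_rep)
  clusters <- if (length(sets) >= 2) replicate_intersect(sets) else
    mutate(sets[[1]], replicate_support = 1L)
  if (!is.null(free_site_sets)) {
    free_sets <- purrr::map2(free_site_sets, free_matrices, one_rep)
    free <- if (length(free_sets) >= 2) replicate_intersect(free_sets) else
      mutate(free_sets[[1]], replicate_support = 1L)
    clusters <- subtract_background(clusters, free)
  }
  clusters
}
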