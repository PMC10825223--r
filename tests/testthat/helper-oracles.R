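# Independent reference implementations used to cross-check the package.
# These deliberately use the slowest, most transparent algorithm available
# (per-read loops, O(n^2) scans, explicit summations) and never call the
# package code paths they verify.

# per-read, per-base pileup tally
oracle_pileup <- function(reads, reference, min_baseq = 0) {
  counts <- list()
  for (i in seq_len(nrow(reads))) {
    bases <- strsplit(reads$seq[i], "")[[1]]
    quals <- utf8ToInt(reads$qual[i]) - 33L
    for (j in seq_along(bases)) {
      if (quals[j] < min_baseq) next
      key <- paste(reads$ref[i], reads$start[i] + j - 1L)
      if (is.null(counts[[key]])) {
        counts[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
      }
      b <- bases[j]
      if (!b %in% names(counts[[key]])) b <- "N"
      counts[[key]][b] <- counts[[key]][b] + 1L
    }
  }
  out <- do.call(rbind, lapply(names(counts), function(key) {
    parts <- strsplit(key, " ")[[1]]
    k <- counts[[key]]
    data.frame(ref = parts[1], pos = as.integer(parts[2]),
               A = k[["A"]], C = k[["C"]], G = k[["G"]], T = k[["T"]],
               coverage = sum(k))
  }))
  out$ref_base <- substr(reference[out$ref], out$pos + 1, out$pos + 1)
  out[order(out$ref, out$pos), c("ref", "pos", "ref_base", "A", "C", "G",
                                 "T", "coverage")]
}

# upper-tail Poisson probability by explicit pmf summation (summed from k
# upward so tiny tails are not lost to cancellation)
oracle_poisson_upper <- function(k, lambda, kmax = 400) {
  if (k <= 0) return(1)
  j <- k:(k + kmax)
  sum(exp(j * log(lambda) - lambda - lgamma(j + 1)))
}

# BH step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# transitive-closure merge of kept bins (repeated-pass label propagation)
oracle_merge <- function(bins, merge_gap) {
  n <- nrow(bins)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (bins$ref[i] == bins$ref[j] &&
          max(bins$start[i], bins$start[j]) -
            min(bins$end[i], bins$end[j]) <= merge_gap &&
          comp[j] != comp[i]) {
        lab <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    b <- bins[comp == cc, , drop = FALSE]
    data.frame(ref = b$ref[1], start = min(b$start), end = max(b$end),
               n_bins = nrow(b), p_value = min(b$p_value),
               q_value = min(b$q_value))
  }))
  out[order(out$ref, out$start), ]
}

# O(n*m) interval overlap
oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$ref == query$ref[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# trapezoidal ROC integration
oracle_auc_trapezoid <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels == 1] >= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[labels == 0] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Welch two-sample t statistic from the closed form
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
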