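#' Benchmark scenarios
#'
#' Self-contained simulation studies that exercise the package end to end
#' under fixed, documented conditions. Each scenario generates its own
#' data with the package's simulators, runs the corresponding analysis
#' stage, and returns the summary quantities a reader would check first
#' (recall, false-positive rates, detection power, separation statistics,
#' AUCs, contrast statistics, calibration diagnostics). They power the
#' package's validation suite and the reproduction script, and double as
#' worked examples of full analyses.
#'
#' @param seed Integer seed; every random stream derives from it.
#' @name scenarios
NULL

#' Edit-caller fidelity on error-free reads
#'
#' Simulates a tethered C-to-U editor (peak rate 0.3, 25-bp kernel,
#' background 0.002) on a 20-gene transcriptome at 50x depth with the
#' sequencing-error process disabled, then calls edit sites and compares
#' them with the simulator truth: confident calls (confidence > 0.9) at
#' positions never edited in any read are false positives; recall is
#' measured over truth positions with expected per-read editing rate at
#' least 0.1 and coverage at least 5.
#'
#' @inheritParams scenarios
#' @return List: `recall`, `false_positives`, `n_eligible`, `n_confident`.
#' @export
scenario_edit_recall <- function(seed = 1) {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = 20, target_fraction = 0.4, motifs_per_target = 2,
    seed = child_seed(seed, 1)))
  enz <- enzyme_model("rBE", "C2U", peak_rate = 0.3, kernel_halfwidth = 25,
                      background_rate = 0.002)
  bound <- dplyr::mutate(tx$truth$motif_sites[, c("ref", "start", "end")],
                         enzyme = enz$name)
  n_reads <- round(50 * sum(nchar(tx$sequences)) / 100)
  sr <- simulate_reads(tx$sequences, bound, list(enz), n_reads = n_reads,
                       error_rate = 0, seed = child_seed(seed, 2))
  mat <- pileup_counts(sr, tx$sequences)
  sites <- call_edits(mat, "C2U")
  conf <- sites[sites$confidence > 0.9, , drop = FALSE]

  edited <- distinct(sr$truth$read_edits, .data$ref, .data$pos)
  fp <- anti_join(conf, edited, by = c("ref", "pos"))

  eligible <- sr$truth$site_prob %>%
    filter(.data$prob >= 0.1) %>%
    inner_join(select(mat, "ref", "pos", "coverage"),
               by = c("ref", "pos")) %>%
    filter(.data$coverage >= 5)
  hit <- semi_join(eligible, conf, by = c("ref", "pos"))
  list(recall = nrow(hit) / nrow(eligible),
       false_positives = nrow(fp),
       n_eligible = nrow(eligible),
       n_confident = nrow(conf))
}

#' Cluster-caller calibration on background-only editing
#'
#' Simulates three replicates of a free (untethered) editor with uniform
#' context preference (background 0.005 per read per substrate base; no
#' bound sites) on a compositionally homogeneous 30-gene transcriptome at
#' 50x depth, and measures the per-bin Poisson false-positive fraction at
#' nominal levels 0.01 and 0.05, plus the replicate-intersected cluster
#' count (expected ~0).
#'
#' @inheritParams scenarios
#' @return List: `fpr_01`, `fpr_05` (pooled over replicates), `n_bins`,
#'   `intersected_clusters`.
#' @export
scenario_cluster_calibration <- function(seed = 1) {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = 30, target_fraction = 0, gc_sd = 0, segment_gc_sd = 0,
    seed = child_seed(seed, 11)))
  enz <- enzyme_model("free", "C2U", peak_rate = 0, background_rate = 0.005)
  n_reads <- round(50 * sum(nchar(tx$sequences)) / 100)
  reps <- lapply(1:3, function(r) {
    sr <- simulate_reads(tx$sequences, NULL, list(enz), n_reads = n_reads,
                         seed = child_seed(seed, 20 + r))
    mat <- pileup_counts(sr, tx$sequences)
    sites <- call_edits(mat, "C2U")
    sites <- sites[sites$confidence > 0.9, , drop = FALSE]
    bins <- bin_edits(sites, tx$models, mat)
    list(mat = mat, sites = sites,
         p = poisson_bin_test(bins, background_rate(bins)))
  })
  p <- unlist(lapply(reps, `[[`, "p"))
  cl <- call_clusters(lapply(reps, `[[`, "sites"), tx$models,
                      lapply(reps, `[[`, "mat"))
  list(fpr_01 = mean(p < 0.01), fpr_05 = mean(p < 0.05),
       n_bins = length(p), intersected_clusters = nrow(cl))
}

#' Detection power for a planted bound site
#'
#' Repeatedly simulates a single bound site edited at 20x the background
#' rate (background 0.005 per read per substrate base, peak 0.1, 25-bp
#' kernel) on a 10-gene transcriptome at 50x depth, runs the
#' bin/test/adjust/filter pipeline in read-count mode, and reports the
#' fraction of simulations in which a bin passing q < 0.1 overlaps the
#' planted site (within the kernel span).
#'
#' @inheritParams scenarios
#' @param n_sims Number of simulation replicates (default 100).
#' @return List: `power`, `n_sims`.
#' @export
scenario_cluster_power <- function(seed = 1, n_sims = 100) {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = 10, target_fraction = 0.1, motifs_per_target = 1,
    gc_sd = 0, segment_gc_sd = 0, seed = child_seed(seed, 31)))
  site <- tx$truth$motif_sites[1, c("ref", "start", "end")]
  wide <- mutate(site, start = .data$start - 30L, end = .data$end + 30L)
  enz <- enzyme_model("planted", "C2U", peak_rate = 0.1,
                      kernel_halfwidth = 25, background_rate = 0.005)
  bound <- mutate(site, enzyme = enz$name)
  n_reads <- round(50 * sum(nchar(tx$sequences)) / 100)
  hits <- vapply(seq_len(n_sims), function(i) {
    sr <- simulate_reads(tx$sequences, bound, list(enz), n_reads = n_reads,
                         seed = child_seed(seed, 1000 + i))
    mat <- pileup_counts(sr, tx$sequences)
    sites <- call_edits(mat, "C2U")
    sites <- sites[sites$confidence > 0.9, , drop = FALSE]
    bins <- bin_edits(sites, tx$models, mat, count_mode = "reads")
    if (nrow(bins) == 0) return(FALSE)
    tb <- test_bins(bins)
    keep <- tb[tb$q_value < 0.1, , drop = FALSE]
    nrow(keep) > 0 && any(interval_overlaps_any(wide, keep))
  }, logical(1))
  list(power = mean(hits), n_sims = n_sims)
}

#' Two context-divergent enzymes: bias recovery and attribution
#'
#' Simulates two free editors with opposite flanking-context preferences
#' (A/U-favouring versus G/C-favouring, 100:1 pair ratio, editing rate 0.1
#' per read at favoured substrate bases) in three replicates each on a
#' 120-gene transcriptome with realistic compositional heterogeneity at
#' 40x depth. Returns the flanking-context PCA separation statistics
#' (between-enzyme PC1 gap versus within-enzyme replicate spread, loading
#' signs), the per-enzyme replicated cluster sets (read-count mode), and
#' balanced 200-bp windows for the sequence classifier.
#'
#' @inheritParams scenarios
#' @return List: `pca`, `pc1_gap`, `pc1_spread`, `loadings_split`,
#'   `clusters_au`, `clusters_gc`, `windows`, `transcriptome`.
#' @export
scenario_enzyme_divergence <- function(seed = 1) {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = 120, target_fraction = 0, gc_content = 0.5, gc_sd = 0.12,
    seed = child_seed(seed, 41)))
  mk <- function(nm, fav) {
    enzyme_model(nm, "C2U", peak_rate = 0, background_rate = 0.1,
                 context_weights = context_weights_biased(fav, 100))
  }
  n_reads <- round(40 * sum(nchar(tx$sequences)) / 100)
  one <- function(enz, k) {
    sr <- simulate_reads(tx$sequences, NULL, list(enz), n_reads = n_reads,
                         seed = child_seed(seed, k))
    mat <- pileup_counts(sr, tx$sequences)
    list(mat = mat, sites = call_edits(mat, "C2U"))
  }
  au <- lapply(1:3, function(r) one(mk("eAU", "AT"), 50 + r))
  gc <- lapply(1:3, function(r) one(mk("eGC", "GC"), 60 + r))

  vectors <- bind_rows(
    purrr::imap_dfr(au, function(x, i) {
      flanking_contexts(x$sites, tx$sequences, sample = paste0("AU_rep", i))
    }),
    purrr::imap_dfr(gc, function(x, i) {
      flanking_contexts(x$sites, tx$sequences, sample = paste0("GC_rep", i))
    }))
  pca <- context_pca(vectors)
  s <- pca$scores
  is_au <- grepl("^AU", s$sample)
  pc1_gap <- abs(mean(s$PC1[is_au]) - mean(s$PC1[!is_au]))
  pc1_spread <- max(sd(s$PC1[is_au]), sd(s$PC1[!is_au]))
  ld <- pca$loadings
  ctx_class <- function(ctx, letters) {
    vapply(strsplit(ctx, ""), function(b) all(b %in% letters), logical(1))
  }
  au_ld <- ld$PC1[ctx_class(ld$context, c("A", "T"))]
  gc_ld <- ld$PC1[ctx_class(ld$context, c("G", "C"))]
  loadings_split <- (all(au_ld > 0) && all(gc_ld < 0)) ||
    (all(au_ld < 0) && all(gc_ld > 0))

  cl_au <- call_clusters(lapply(au, `[[`, "sites"), tx$models,
                         lapply(au, `[[`, "mat"), count_mode = "reads")
  cl_gc <- call_clusters(lapply(gc, `[[`, "sites"), tx$models,
                         lapply(gc, `[[`, "mat"), count_mode = "reads")
  windows <- make_windows(cl_au, cl_gc, tx$sequences, width = 200,
                          seed = child_seed(seed, 71))
  list(pca = pca, pc1_gap = pc1_gap, pc1_spread = pc1_spread,
       loadings_split = loadings_split, clusters_au = cl_au,
       clusters_gc = cl_gc, windows = windows, transcriptome = tx)
}

#' Classifier performance on divergent and label-permuted windows
#'
#' Trains the convolutional classifier on the
#' [scenario_enzyme_divergence()] windows and reports the held-out AUC,
#' plus the held-out AUC after randomly permuting the labels (the null
#' control, expected near 0.5).
#'
#' @inheritParams scenarios
#' @param divergence Optionally a precomputed
#'   [scenario_enzyme_divergence()] result (to share the simulation).
#' @return List: `auc_holdout`, `auc_null`, `n_windows`, `model`.
#' @export
scenario_classifier <- function(seed = 1, divergence = NULL) {
  if (is.null(divergence)) divergence <- scenario_enzyme_divergence(seed)
  w <- divergence$windows
  model <- train_classifier(w, seed = child_seed(seed, 81))
  wnull <- w
  wnull$label <- with_seed(child_seed(seed, 82), sample(w$label))
  mnull <- train_classifier(wnull, seed = child_seed(seed, 83))
  list(auc_holdout = model$auc_test, auc_null = mnull$auc_test,
       n_windows = nrow(w), model = model)
}

#' Translation contrast recovery and null calibration
#'
#' Simulates a ribosome-fusion EPR experiment (3 + 3 replicates, 30x
#' depth) on `n_genes` genes with the default treated condition (TOP genes
#' reduced 4-fold, others 1.25-fold), runs the EPR pipeline, and returns
#' the TOP-versus-rest contrast. With `null = TRUE` the treated loads
#' equal the control loads and the fraction of q < 0.05 calls is the
#' quantity of interest.
#'
#' @inheritParams scenarios
#' @param n_genes Transcriptome size (default 200).
#' @param null Simulate the no-effect condition instead.
#' @return List: `contrast` (tibble from [group_contrast()], `NULL` under
#'   the null), `frac_significant`, `comparisons`, `summaries`,
#'   `region_ratio`.
#' @export
scenario_translation <- function(seed = 1, n_genes = 200, null = FALSE) {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = n_genes, target_fraction = 0, top_fraction = 0.2,
    seed = child_seed(seed, 91)))
  loads <- setNames(rep(1, n_genes), tx$models$gene_id)
  sim <- simulate_translation(
    tx, loads_control = loads,
    loads_treated = if (null) loads else treated_loads(tx$models, loads),
    depth = 30, n_reps = 3, seed = child_seed(seed, 92))
  summaries <- epr_summaries(sim)
  comparisons <- epr_fold_change(summaries)
  top <- intersect(tx$models$gene_id[tx$models$top], comparisons$gene_id)
  contrast <- if (!null && length(top) > 0 &&
                  length(top) < nrow(comparisons)) {
    group_contrast(comparisons, top)
  }
  ratio <- region_epr_ratio(
    summaries[summaries$condition == "control", , drop = FALSE])
  list(contrast = contrast,
       frac_significant = mean(comparisons$q_value < 0.05),
       comparisons = comparisons, summaries = summaries,
       region_ratio = ratio, models = tx$models)
}

#' Permutation-test calibration and planted enrichment
#'
#' Draws `n_trials` query sets from the null placement process itself
#' (150 intervals of 80 bp over a 20-transcript domain) and tests each
#' against a fixed subject set, recording the empirical p-values; under
#' the null they should be approximately uniform (Kolmogorov-Smirnov D).
#' A planted query set sitting on the subject intervals provides the
#' positive control.
#'
#' @inheritParams scenarios
#' @param n_trials Null trials (default 100).
#' @param n_perm Permutations per test (default 200).
#' @return List: `ks_D`, `p_values`, `planted_p`.
#' @export
scenario_permutation_calibration <- function(seed = 1, n_trials = 100,
                                             n_perm = 200) {
  domain <- tibble(ref = sprintf("tx%02d", 1:20), start = 0L, end = 1000L)
  subject <- with_seed(child_seed(seed, 101), {
    tibble(ref = sample(domain$ref, 30, replace = TRUE),
           start = sample(0:900, 30, replace = TRUE)) %>%
      mutate(end = .data$start + 60L)
  })
  ps <- vapply(seq_len(n_trials), function(i) {
    q <- with_seed(child_seed(seed, 200 + i), {
      w <- rep(80L, 150)
      pick <- sample.int(nrow(domain), length(w), replace = TRUE)
      off <- floor(runif(length(w)) * (domain$end[pick] - w + 1))
      tibble(ref = domain$ref[pick], start = domain$start[pick] + off,
             end = domain$start[pick] + off + w)
    })
    permute_intervals(q, subject, domain, n_perm = n_perm,
                      seed = child_seed(seed, 400 + i))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  planted <- subject %>%
    mutate(start = pmax(0L, .data$start - 10L), end = .data$end + 10L)
  pr <- permute_intervals(planted, subject, domain, n_perm = n_perm,
                          seed = child_seed(seed, 102))
  list(ks_D = unname(ks$statistic), p_values = ps,
       planted_p = pr$p_value)
}
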