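#' Default configuration of a pipeline preset
#'
#' @param preset `"reporter"`, `"fusion"` or `"translation"`.
#' @return Named list of stage parameters (all overridable via the
#'   `config` argument of [run_pipeline()]).
#' @export
default_config <- function(preset = c("reporter", "fusion", "translation")) {
  preset <- match.arg(preset)
  common <- list(seed = 1, read_length = 100, error_rate = 1e-3,
                 min_coverage = 5, min_confidence = 0.9)
  extra <- switch(preset,
    reporter = list(layout = "MS2x12", edit_type = "C2U", peak_rate = 0.3,
                    kernel_halfwidth = 25, background_rate = 5e-4,
                    context_ratio = 10, n_reads = 8000,
                    off_target_genes = 20, replicates = 2),
    fusion = list(n_genes = 40, depth = 40, replicates = 3,
                  edit_type = "C2U", peak_rate = 0.3,
                  kernel_halfwidth = 20, background_rate = 5e-4,
                  context_ratio = 10, target_fraction = 0.3,
                  fdr = 0.1, bin_size = 30, merge_gap = 15, n_perm = 200),
    translation = list(n_genes = 60, depth = 30, replicates = 3,
                       epr_scale = 0.005, cds_bias = 3,
                       top_fraction = 0.2, fdr = 0.05, min_reads = 10))
  c(common, extra)
}

#' @noRd
resolve_config <- function(preset, config) {
  base <- default_config(preset)
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "stamper_config_error")
  }
  utils::modifyList(base, config)
}

#' Run a pipeline preset end to end
#'
#' Chains the package's stages into the three canonical workflows and
#' writes a TSV/BED/JSON report bundle plus a resolved-config copy to
#' `outdir`. Reruns with an identical config produce byte-identical
#' outputs.
#'
#' * `reporter` — build a stem-loop reporter and a small off-target
#'   transcriptome, simulate tethered editing in replicate, call edits,
#'   and report the per-position profile, spillover index and
#'   on/off-target ratios.
#' * `fusion` — simulate an RBP-rBE fusion (edits at planted motif sites)
#'   and a free-editor control in triplicate, call replicated clusters
#'   with background subtraction, and report flanking-context PCA, motif
#'   presence and permutation overlap enrichment.
#' * `translation` — simulate a ribosome-fusion experiment with a treated
#'   condition, compute per-gene EPR, fold changes and the TOP-gene
#'   contrast.
#'
#' @param preset `"reporter"`, `"fusion"` or `"translation"`.
#' @param config Named list (or YAML file path) overriding
#'   [default_config()] values; unknown keys are rejected.
#' @param outdir Output directory (created if needed).
#' @return The report bundle (a named list of tibbles/values), invisibly;
#'   file paths in its `files` element.
#' @export
run_pipeline <- function(preset = c("reporter", "fusion", "translation"),
                         config = list(), outdir = tempfile("stamper_")) {
  preset <- match.arg(preset)
  cfg <- resolve_config(preset, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- switch(preset,
    reporter = pipeline_reporter(cfg, outdir),
    fusion = pipeline_fusion(cfg, outdir),
    translation = pipeline_translation(cfg, outdir))
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(c(list(preset = preset), cfg), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$config <- cfg
  bundle$files <- c(bundle$files, config = cfg_path)
  invisible(bundle)
}

#' @noRd
pipeline_reporter <- function(cfg, outdir) {
  spec <- build_reporter(cfg$layout, seed = cfg$seed)
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = cfg$off_target_genes, target_fraction = 0,
    seed = child_seed(cfg$seed, 11)))
  reference <- c(setNames(spec$full_seq, spec$name), tx$sequences)
  enz <- enzyme_model("tethered-rBE", cfg$edit_type,
                      peak_rate = cfg$peak_rate,
                      kernel_halfwidth = cfg$kernel_halfwidth,
                      background_rate = cfg$background_rate,
                      context_weights = context_weights_biased(
                        "AT", cfg$context_ratio))
  bound <- reporter_bound_sites(spec, MS2 = enz$name)

  reps <- lapply(seq_len(cfg$replicates), function(r) {
    sr <- simulate_reads(reference, bound, list(enz),
                         n_reads = cfg$n_reads,
                         read_length = cfg$read_length,
                         error_rate = cfg$error_rate,
                         ref_weights = setNames(
                           c(10 * sum(nchar(tx$sequences)) /
                               nchar(spec$full_seq), rep(1, length(tx$sequences))),
                           names(reference)),
                         seed = child_seed(cfg$seed, r))
    mat <- pileup_counts(sr, reference)
    sites <- call_edits(mat, cfg$edit_type, min_coverage = cfg$min_coverage)
    list(matrix = mat, sites = sites)
  })

  prof <- profile_reporter(
    filter(reps[[1]]$matrix, .data$ref == spec$name), spec,
    min_coverage = cfg$min_coverage)
  on <- vapply(reps, function(r) {
    count_edit_observations(filter(r$sites, .data$ref == spec$name),
                            cfg$min_confidence)
  }, numeric(1))
  off <- vapply(reps, function(r) {
    count_edit_observations(filter(r$sites, .data$ref != spec$name),
                            cfg$min_confidence)
  }, numeric(1))
  onoff <- on_off_ratio(on, off)
  spill <- spillover_index(prof)

  files <- c(
    profile = file.path(outdir, "reporter_profile.tsv"),
    onoff = file.path(outdir, "on_off_ratio.tsv"),
    sites = file.path(outdir, "edit_sites_rep1.tsv"),
    loops = file.path(outdir, "loops.bed"))
  readr::write_tsv(as_tibble(prof), files["profile"])
  readr::write_tsv(mutate(onoff, spillover_index = spill), files["onoff"])
  write_edit_sites(reps[[1]]$sites, files["sites"])
  write_bed(tibble(ref = spec$name, start = spec$loop_intervals$start,
                   end = spec$loop_intervals$end,
                   name = spec$loop_intervals$kind), files["loops"])
  list(profile = prof, on_off = onoff, spillover = spill,
       spec = spec, files = files)
}

#' @noRd
pipeline_fusion <- function(cfg, outdir) {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = cfg$n_genes, target_fraction = cfg$target_fraction,
    seed = child_seed(cfg$seed, 21)))
  n_reads <- round(cfg$depth * sum(nchar(tx$sequences)) / cfg$read_length)
  enz <- enzyme_model("RBP-rBE", cfg$edit_type, peak_rate = cfg$peak_rate,
                      kernel_halfwidth = cfg$kernel_halfwidth,
                      background_rate = cfg$background_rate,
                      context_weights = context_weights_biased(
                        "AT", cfg$context_ratio))
  bound <- mutate(tx$truth$motif_sites[, c("ref", "start", "end")],
                  enzyme = enz$name)

  sim_rep <- function(bound_sites, k) {
    sr <- simulate_reads(tx$sequences, bound_sites, list(enz),
                         n_reads = n_reads, read_length = cfg$read_length,
                         error_rate = cfg$error_rate,
                         seed = child_seed(cfg$seed, k))
    mat <- pileup_counts(sr, tx$sequences)
    list(matrix = mat,
         sites = call_edits(mat, cfg$edit_type,
                            min_coverage = cfg$min_coverage))
  }
  fusion <- lapply(seq_len(cfg$replicates), function(r) sim_rep(bound, r))
  free <- lapply(seq_len(cfg$replicates), function(r) {
    sim_rep(NULL, 100 + r)
  })

  clusters <- call_clusters(
    lapply(fusion, `[[`, "sites"), tx$models,
    lapply(fusion, `[[`, "matrix"),
    free_site_sets = lapply(free, `[[`, "sites"),
    free_matrices = lapply(free, `[[`, "matrix"),
    min_confidence = cfg$min_confidence, fdr = cfg$fdr,
    bin_size = cfg$bin_size, merge_gap = cfg$merge_gap,
    min_coverage = cfg$min_coverage)

  vectors <- bind_rows(
    purrr::imap_dfr(fusion, function(x, i) {
      flanking_contexts(x$sites, tx$sequences, cfg$min_confidence,
                        sample = paste0("fusion_rep", i))
    }),
    purrr::imap_dfr(free, function(x, i) {
      flanking_contexts(x$sites, tx$sequences, cfg$min_confidence,
                        sample = paste0("free_rep", i))
    }))
  pca <- context_pca(vectors)
  motif <- motif_presence(clusters, tx$sequences)

  perm <- NULL
  if (nrow(clusters) > 0) {
    subject <- mutate(tx$truth$motif_sites[, c("ref", "start", "end")],
                      start = pmax(0L, .data$start - 20L),
                      end = .data$end + 20L)
    domain <- transmute(tx$models, ref = .data$seqname, start = 0L,
                        end = .data$length)
    perm <- permute_intervals(clusters, subject, domain,
                              n_perm = cfg$n_perm,
                              seed = child_seed(cfg$seed, 31))
  }

  files <- c(
    clusters_bed = file.path(outdir, "clusters.bed"),
    clusters = file.path(outdir, "clusters.tsv"),
    contexts = file.path(outdir, "context_counts.tsv"),
    pca_scores = file.path(outdir, "pca_scores.tsv"),
    pca_loadings = file.path(outdir, "pca_loadings.tsv"),
    overlap = file.path(outdir, "overlap.json"))
  write_clusters_bed(clusters, files["clusters_bed"])
  readr::write_tsv(clusters, files["clusters"])
  readr::write_tsv(vectors, files["contexts"])
  readr::write_tsv(pca$scores, files["pca_scores"])
  readr::write_tsv(pca$loadings, files["pca_loadings"])
  jsonlite::write_json(
    list(motif_fraction = motif$fraction,
         n_clusters = nrow(clusters),
         overlap = if (!is.null(perm)) {
           list(observed = perm$observed, p_value = perm$p_value,
                enrichment = perm$enrichment, n_perm = perm$n_perm)
         }),
    files["overlap"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(clusters = clusters, contexts = vectors, pca = pca,
       motif = motif, permutation = perm, transcriptome = tx,
       files = files)
}

#' @noRd
pipeline_translation <- function(cfg, outdir) {
  tx <- simulate_transcriptome(transcriptome_spec(
    n_genes = cfg$n_genes, top_fraction = cfg$top_fraction,
    target_fraction = 0, seed = child_seed(cfg$seed, 41)))
  sim <- simulate_translation(tx, epr_scale = cfg$epr_scale,
                              cds_bias = cfg$cds_bias, depth = cfg$depth,
                              read_length = cfg$read_length,
                              n_reps = cfg$replicates,
                              error_rate = cfg$error_rate,
                              seed = child_seed(cfg$seed, 42))
  summaries <- epr_summaries(sim, min_confidence = cfg$min_confidence,
                             min_reads = cfg$min_reads,
                             min_coverage = cfg$min_coverage)
  comparisons <- epr_fold_change(summaries, fdr = cfg$fdr)
  top_genes <- intersect(tx$models$gene_id[tx$models$top],
                         comparisons$gene_id)
  contrast <- if (length(top_genes) > 0 &&
                  length(top_genes) < nrow(comparisons)) {
    group_contrast(comparisons, top_genes)
  }
  ratio <- region_epr_ratio(filter(summaries,
                                   .data$condition == "control"))

  files <- c(
    summaries = file.path(outdir, "epr_summaries.tsv"),
    comparisons = file.path(outdir, "epr_comparisons.tsv"),
    contrast = file.path(outdir, "top_contrast.tsv"),
    region = file.path(outdir, "region_ratio.tsv"))
  readr::write_tsv(summaries, files["summaries"])
  readr::write_tsv(as_tibble(comparisons), files["comparisons"])
  readr::write_tsv(contrast %||% tibble(), files["contrast"])
  readr::write_tsv(ratio$per_gene, files["region"])
  list(summaries = summaries, comparisons = comparisons,
       contrast = contrast, region_ratio = ratio, sim = sim, files = files)
}
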