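#' Default treated-condition ribosome loads
#'
#' The generator's default translation-inhibition condition: TOP-flagged
#' genes (whose translation is strongly mTOR-dependent) have their ribosome
#' load reduced 4-fold, all other genes 1.25-fold.
#'
#' @param models Gene-model tibble with `gene_id` and `top`.
#' @param loads_control Named per-gene control loads (default all 1).
#' @param top_factor,other_factor Fold-reduction applied to TOP and
#'   non-TOP genes.
#' @return Named numeric vector of treated loads.
#' @export
treated_loads <- function(models, loads_control = NULL,
                          top_factor = 4, other_factor = 1.25) {
  if (is.null(loads_control)) {
    loads_control <- setNames(rep(1, nrow(models)), models$gene_id)
  }
  f <- ifelse(models$top[match(names(loads_control), models$gene_id)],
              top_factor, other_factor)
  loads_control / f
}

#' Simulate a translation-profiling (RiboSTAMP-style) experiment
#'
#' Emits replicate read sets for a control and a treated condition in which
#' a ribosome-fused rBE deposits edits on translated mRNAs. Each gene's
#' per-read expected edits-per-read (EPR) is proportional to its ribosome
#' load times `epr_scale`; CDS positions are edited `cds_bias`-fold more
#' readily than 3'UTR positions. The default treated loads follow
#' [treated_loads()] (TOP genes reduced 4-fold, others 1.25-fold),
#' emulating mTOR inhibition.
#'
#' @param transcriptome A [simulate_transcriptome()] object, or a list with
#'   `sequences` and `models`.
#' @param loads_control,loads_treated Named per-gene positive loads; the
#'   gene sets must match the gene models exactly.
#' @param epr_scale Per-substrate-base editing probability per unit load.
#' @param cds_bias Multiplier (>= 1) for CDS relative to 3'UTR positions.
#' @param depth Expected per-base coverage per replicate.
#' @param read_length Read length in bp.
#' @param n_reps Replicates per condition.
#' @param error_rate Sequencing substitution-error rate.
#' @param edit_type Editing channel of the fused enzyme.
#' @param seed Integer seed.
#' @return An object of class `sim_translation`: lists `control` and
#'   `treated` of `sim_reads` objects (one per replicate), `models`, and
#'   `truth` (loads and per-gene expected EPR per condition).
#' @export
simulate_translation <- function(transcriptome,
                                 loads_control = NULL, loads_treated = NULL,
                                 epr_scale = 0.005, cds_bias = 3,
                                 depth = 30, read_length = 100, n_reps = 3,
                                 error_rate = 1e-3, edit_type = "C2U",
                                 seed = 1L) {
  models <- transcriptome$models
  sequences <- as_reference(transcriptome$sequences)
  if (cds_bias < 1) abort("`cds_bias` must be >= 1.",
                          class = "stamper_config_error")
  if (is.null(loads_control)) {
    loads_control <- setNames(rep(1, nrow(models)), models$gene_id)
  }
  if (is.null(loads_treated)) {
    loads_treated <- treated_loads(models, loads_control)
  }
  for (ld in list(loads_control, loads_treated)) {
    if (!setequal(names(ld), models$gene_id)) {
      abort("load gene set does not match the gene models.",
            class = "stamper_config_error")
    }
    if (any(ld <= 0)) abort("loads must be strictly positive.",
                            class = "stamper_config_error")
  }

  sub <- substrate_base(edit_type)
  base_p <- lapply(models$gene_id, function(g) {
    m <- models[models$gene_id == g, ]
    chars <- seq_chars(sequences[[g]])
    w <- ifelse(seq_along(chars) - 1L < m$cds_end, cds_bias, 1)
    w[chars != sub] <- 0
    w * epr_scale
  })
  names(base_p) <- models$gene_id

  channel_for <- function(loads) {
    p <- lapply(models$gene_id, function(g) pmin(1, base_p[[g]] * loads[[g]]))
    names(p) <- models$gene_id
    list(list(enzyme = "RPS2-rBE", edit_type = edit_type, p = p))
  }

  # expected EPR: mean over eligible starts of the read-window probability sum
  expected_epr <- function(loads) {
    vapply(models$gene_id, function(g) {
      p <- pmin(1, base_p[[g]] * loads[[g]])
      n <- length(p)
      if (n < read_length) return(NA_real_)
      cs <- c(0, cumsum(p))
      wins <- cs[(read_length + 1):(n + 1)] - cs[1:(n - read_length + 1)]
      mean(wins)
    }, numeric(1))
  }

  lens <- setNames(models$length, models$gene_id)
  sim_condition <- function(loads, cond, k0) {
    lapply(seq_len(n_reps), function(r) {
      ks <- child_seed(seed, k0 + r)
      nper <- with_seed(ks, {
        setNames(rpois(nrow(models), depth * lens / read_length),
                 models$gene_id)
      })
      simulate_reads(sequences, channels = channel_for(loads),
                     reads_per_ref = pmax(nper, 1L),
                     read_length = read_length, error_rate = error_rate,
                     seed = child_seed(seed, k0 + 100 + r))
    })
  }

  structure(list(
    control = sim_condition(loads_control, "control", 0),
    treated = sim_condition(loads_treated, "treated", 1000),
    models = models,
    truth = list(
      loads_control = loads_control, loads_treated = loads_treated,
      expected_epr = tibble(
        gene_id = rep(models$gene_id, 2),
        condition = rep(c("control", "treated"), each = nrow(models)),
        expected_epr = c(expected_epr(loads_control),
                         expected_epr(loads_treated)))),
    params = list(epr_scale = epr_scale, cds_bias = cds_bias, depth = depth,
                  read_length = read_length, n_reps = n_reps,
                  edit_type = edit_type, seed = seed)
  ), class = "sim_translation")
}

#' @export
print.sim_translation <- function(x, ...) {
  cat("<sim_translation> ", nrow(x$models), " genes, ",
      length(x$control), " + ", length(x$treated),
      " replicates (control + treated)\n", sep = "")
  invisible(x)
}
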