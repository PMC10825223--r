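#' Tidy a context PCA
#'
#' @param x A [context_pca()] object.
#' @param matrix `"scores"` (per-sample coordinates), `"loadings"`
#'   (per-context contributions), or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.context_pca <- function(x, matrix = c("scores", "loadings",
                                           "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble(PC = seq_along(x$variance_explained),
                         variance_explained = x$variance_explained))
}

#' @rdname tidy.context_pca
#' @export
glance.context_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         pc1_variance = x$variance_explained[1],
         pc2_variance = x$variance_explained[2] %||% NA_real_)
}

#' Tidy a permutation test
#'
#' @param x A [permute_intervals()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per permutation (`perm`, `null_fraction`);
#'   `glance()`: one row with observed fraction, p-value and enrichment.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(perm = seq_along(x$null), null_fraction = x$null)
}

#' @rdname tidy.permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null),
         p_value = x$p_value, enrichment = x$enrichment,
         n_perm = x$n_perm, n_query = x$n_query)
}

#' Tidy a trained sequence classifier
#'
#' @param x A [train_classifier()] model.
#' @param ... Unused.
#' @return `tidy()`: the training curve (`epoch`, `train_loss`,
#'   `val_loss`); `glance()`: one row with test AUC, best epoch and
#'   validation loss.
#' @export
tidy.stamper_cnn <- function(x, ...) x$history

#' @rdname tidy.stamper_cnn
#' @export
glance.stamper_cnn <- function(x, ...) {
  tibble(auc_test = x$auc_test, best_epoch = x$best_epoch,
         val_loss = x$val_loss, epochs_run = max(x$history$epoch),
         width = x$width, filters = x$filters,
         filter_width = x$filter_width, seed = x$seed)
}

#' Summarise an EPR comparison table
#'
#' @param x An [epr_fold_change()] table.
#' @param ... Unused.
#' @return One row with gene counts per call class.
#' @export
glance.epr_comparison <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_decrease = sum(x$call == "decrease"),
         n_increase = sum(x$call == "increase"),
         n_ns = sum(x$call == "ns"),
         median_log2_fc = median(x$log2_fc))
}
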