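#' Plot a reporter editing profile
#'
#' Per-position edited fractions along the construct, with loop intervals
#' shaded and the CDS/3'UTR boundary marked; C-to-U in green, A-to-I in
#' orange, the field's conventional colours.
#'
#' @param profile A [profile_reporter()] result.
#' @return A ggplot object.
#' @export
plot_reporter_profile <- function(profile) {
  loops <- profile %>%
    filter(!is.na(.data$loop)) %>%
    mutate(grp = cumsum(c(TRUE, diff(.data$pos) > 1))) %>%
    group_by(.data$grp, .data$loop) %>%
    summarise(start = min(.data$pos), end = max(.data$pos) + 1,
              .groups = "drop")
  long <- profile %>%
    select("pos", "region", c2u = "c2u_fraction", a2i = "a2i_fraction") %>%
    tidyr::pivot_longer(c("c2u", "a2i"), names_to = "channel",
                        values_to = "fraction") %>%
    filter(!is.na(.data$fraction))
  cds_end <- attr(profile, "cds_length")
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(data = loops,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$loop),
                       alpha = 0.2, inherit.aes = FALSE) +
    ggplot2::geom_col(ggplot2::aes(x = .data$pos, y = .data$fraction,
                                   colour = .data$channel), width = 1) +
    ggplot2::geom_vline(xintercept = cds_end, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(c2u = "#2e7d32", a2i = "#ef6c00"),
      labels = c(c2u = "C-to-U", a2i = "A-to-I")) +
    ggplot2::scale_fill_manual(values = c(MS2 = "#fdd835",
                                          PP7 = "#e53935")) +
    ggplot2::labs(x = "construct position (bp)",
                  y = "edited fraction of covered bases",
                  colour = "channel", fill = "loop") +
    ggplot2::theme_minimal()
}

#' Plot context-PCA sample coordinates
#'
#' @param object A [context_pca()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.context_pca <- function(object, ...) {
  ve <- object$variance_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               label = .data$sample)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * (ve[2] %||% 0))) +
    ggplot2::theme_minimal()
}

#' Volcano plot of EPR fold changes
#'
#' @param object An [epr_fold_change()] table.
#' @param highlight Optional gene ids to highlight (e.g. TOP genes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epr_comparison <- function(object, highlight = NULL, ...) {
  d <- mutate(as_tibble(object),
              highlighted = .data$gene_id %in% (highlight %||% character(0)))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call), alpha = 0.7) +
    ggplot2::geom_point(data = filter(d, .data$highlighted),
                        colour = "deeppink", size = 2) +
    ggplot2::scale_colour_manual(values = c(decrease = "#c62828",
                                            increase = "#1565c0",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 EPR fold change (treated / control)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Null-versus-observed plot for a permutation test
#'
#' @param object A [permute_intervals()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$null_fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#c62828") +
    ggplot2::labs(x = "null overlap fraction", y = "permutations",
                  subtitle = sprintf("observed = %.3f, p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
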