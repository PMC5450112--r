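#' Kaplan-Meier step plot
#'
#' @param object A `linc_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot of the survival step functions, one line per group,
#'   with censoring marks.
#' @method autoplot linc_km
#' @export
autoplot.linc_km <- function(object, ...) {
  start <- object %>%
    group_by(.data$group) %>%
    summarise(time = 0, survival = 1, n_censor = 0, .groups = "drop")
  df <- bind_rows(start, select(object, "group", "time", "survival", "n_censor")) %>%
    arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(df, .data$n_censor > 0), shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Overall survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of per-marker differential expression
#'
#' @param results DEResult tibble with `log2fc`, `p` (and optionally the
#'   filter outcome).
#' @param p_max,min_abs_log2fc Thresholds drawn as guide lines; defaults
#'   match [select_candidates()].
#' @return A ggplot.
#' @export
plot_volcano <- function(results, p_max = 0.005, min_abs_log2fc = 1) {
  ggplot2::ggplot(results, ggplot2::aes(.data$log2fc, -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * min_abs_log2fc,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Concordance scatter of overlapping knockdown hits
#'
#' @param stats_a,stats_b GeneStat tibbles.
#' @param genes Gene identifiers to plot (e.g. the `overlap_genes` of a
#'   [concordance_report()]).
#' @return A ggplot of log2FC under treatment A vs treatment B.
#' @export
plot_concordance <- function(stats_a, stats_b, genes) {
  df <- tibble(
    gene_id = genes,
    log2fc_a = stats_a$log2fc[match(genes, stats_a$gene_id)],
    log2fc_b = stats_b$log2fc[match(genes, stats_b$gene_id)])
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc_a, .data$log2fc_b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::labs(x = "log2FC, treatment A", y = "log2FC, treatment B") +
    ggplot2::theme_minimal()
}
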