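#' Ro/e heatmap
#'
#' Clusters x tissues tile plot of the observed/expected ratio, with
#' enriched (> 1) entries outlined.
#'
#' @param object a `roe_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.roe_table <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$cluster,
                                     fill = .data$roe)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$roe)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  name = "Ro/e") +
    ggplot2::labs(x = "tissue", y = "cluster") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves
#'
#' Step curves per group with the log-rank p-value in the subtitle.
#'
#' @param km a `km_fit`.
#' @return a ggplot object.
#' @export
plot_km <- function(km) {
  curves <- bind_rows(
    tibble(group = unique(km$curves$group), time = 0, surv = 1),
    km$curves[, c("group", "time", "surv")]
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", km$p_value)) +
    ggplot2::theme_classic()
}

#' Signature scores by group
#'
#' Violin + box plot of per-cell signature scores split by a grouping.
#'
#' @param scores tibble from [module_score()] (cell_id, score).
#' @param grouping per-cell labels aligned with the scores.
#' @return a ggplot object.
#' @export
plot_score_groups <- function(scores, grouping) {
  df <- tibble(score = scores$score, group = as.character(grouping))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4,
                          show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = attr(scores, "signature") %||% "score") +
    ggplot2::theme_classic()
}

#' Ligand-receptor dot plot
#'
#' Dot plot of retained interactions: dot size encodes -log10 p, color
#' the interaction score.
#'
#' @param lr results of [lr_interaction_test()].
#' @param retained_only show retained (p <= 0.05, testable) rows only.
#' @return a ggplot object.
#' @export
plot_lr_dotplot <- function(lr, retained_only = TRUE) {
  df <- if (retained_only) lr[lr$retained %in% TRUE, ] else lr[lr$testable %in% TRUE, ]
  df$pair <- paste(df$ligand, df$receptor, sep = " - ")
  df$groups <- paste(df$source, df$target, sep = " > ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$groups, y = .data$pair,
                                   size = -log10(.data$p_value),
                                   color = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_viridis_c(name = "score") +
    ggplot2::scale_size_continuous(name = "-log10 p") +
    ggplot2::labs(x = "source > target", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' CNV profile heatmap
#'
#' Raster heatmap of smoothed CNV scores (cells x genome positions),
#' faceted by chromosome; cells are optionally subsampled for display.
#'
#' @param profile a `cnv_profile`.
#' @param max_cells subsample limit for display.
#' @param seed subsampling seed.
#' @return a ggplot object.
#' @export
plot_cnv_profile <- function(profile, max_cells = 200, seed = 1L) {
  cells <- profile$interrogated_cells
  if (length(cells) > max_cells) {
    cells <- with_seed_(seed, sample(cells, max_cells))
  }
  S <- profile$scores[cells, , drop = FALSE]
  df <- tibble(cell = rep(rownames(S), times = ncol(S)),
               pos = rep(seq_len(ncol(S)), each = nrow(S)),
               chromosome = rep(profile$gene_order$chromosome, each = nrow(S)),
               score = as.vector(S))
  df$chromosome <- factor(df$chromosome,
                          levels = unique(profile$gene_order$chromosome))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$cell,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "CNV score") +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 6))
}
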