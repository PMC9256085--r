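#' Bar plot of region-class methylation means
#'
#' @param x A [region_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_summary <- function(x, ...) {
  ggplot2::ggplot(x$per_class,
                  ggplot2::aes(x = stats::reorder(.data$region_class,
                                                  -.data$mean_level),
                               y = 100 * .data$mean_level)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$mean_level - .data$se),
      ymax = 100 * (.data$mean_level + .data$se)), width = 0.2) +
    ggplot2::labs(x = "genomic region", y = "mean methylation (%)") +
    ggplot2::theme_minimal()
}

#' Meta-gene methylation profile plot
#'
#' Flank bins left and right of the gene body, exon/intron ranks in between,
#' one line per sample.
#'
#' @param profile [metagene_profile()] output.
#' @return A ggplot.
#' @export
plot_metagene <- function(profile) {
  dat <- profile %>%
    mutate(panel = dplyr::case_when(
      .data$element == "flank5" ~ "5'-flank",
      .data$element == "flank3" ~ "3'-flank",
      TRUE ~ .data$element))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position,
                                    y = 100 * .data$mean_level,
                                    group = .data$sample_id,
                                    colour = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_grid(. ~ factor(.data$panel,
                                   levels = c("5'-flank", "exon", "intron",
                                              "3'-flank")),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "flank bin (1 kb) / element rank",
                  y = "mean methylation (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' PCA scatter of samples
#'
#' @param x A [pca_top_variable()] result.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2, coloured by phenotype and shaped by
#'   colony when those columns are present.
#' @export
autoplot.meth_pca <- function(x, ...) {
  aes <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if ("phenotype" %in% names(x$scores)) {
    aes$colour <- rlang::quo(.data$phenotype)
  }
  if ("colony" %in% names(x$scores)) {
    aes$shape <- rlang::quo(.data$colony)
  }
  ggplot2::ggplot(x$scores, aes) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", x$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", x$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Heatmap of the pairwise DMS count matrix
#'
#' Hyper-phenotype columns, hypo-phenotype rows, as in a pairwise DMS
#' summary panel.
#'
#' @param dms A [classify_dms()] result.
#' @return A ggplot.
#' @export
plot_dms_matrix <- function(dms) {
  stopifnot(inherits(dms, "dms_summary"))
  m <- as_tibble(as.data.frame.table(dms$pair_matrix,
                                     responseName = "n_dms"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$hyper, y = .data$hypo,
                                  fill = .data$n_dms)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_dms)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "hypermethylated in", y = "hypomethylated in") +
    ggplot2::theme_minimal()
}

#' Effect-display plot for a methylation GLM
#'
#' Predicted methylation against expression percentile, one line per
#' variable level, faceted by region.
#'
#' @param x A `meth_glm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_glm <- function(x, ...) {
  grid <- predict_methylation_grid(x)
  aes <- ggplot2::aes(x = 100 * .data$percentile,
                      y = 100 * .data$predicted)
  if (!x$degenerate) {
    aes$colour <- rlang::quo(factor(.data$var))
    aes$group <- rlang::quo(factor(.data$var))
  }
  ggplot2::ggplot(grid, aes) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$region, scales = "free_y") +
    ggplot2::labs(x = "expression percentile",
                  y = "predicted methylation (%)",
                  colour = x$variable) +
    ggplot2::theme_minimal()
}
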