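# ggplot2 views of the main result types.

#' Plot fuzzy cluster centers over the time course
#' @param fit an `angio_fcm`.
#' @return A ggplot.
#' @export
plot_cluster_centers <- function(fit) {
  ctr <- as_tibble(fit$centers, rownames = "cluster")
  stages <- colnames(fit$centers)
  long <- tidyr::pivot_longer(ctr, -"cluster", names_to = "stage",
                              values_to = "center")
  long$stage <- factor(long$stage, levels = stages)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$center,
                                     group = .data$cluster,
                                     colour = .data$cluster)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stage", y = "standardised expression",
                  title = "Cluster centers over the stimulation time course")
}

#' PCA scatter plot
#' @param x an `angio_pca` (expression or genotype PCA).
#' @param colour optional vector to colour points by (defaults to
#'   `phenotype` when present).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot angio_pca
#' @export
autoplot.angio_pca <- function(x, colour = NULL, ...) {
  df <- x$coords
  if (is.null(colour) && "phenotype" %in% names(df)) colour <- df$phenotype
  df$colour <- if (is.null(colour)) "sample" else colour
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$colour)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * x$var_explained[min(2, length(x$var_explained))]),
      colour = NULL)
}

#' Manhattan plot of an association scan
#' @param assoc an `angio_assoc` tibble.
#' @param th thresholds (draws the exome-wide line at `assoc_p`).
#' @return A ggplot.
#' @export
plot_manhattan <- function(assoc, th = angio_thresholds()) {
  df <- arrange(as_tibble(assoc), .data$chrom, .data$pos)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = -log10(.data$p),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(th$assoc_p), linetype = 2) +
    ggplot2::labs(x = "variant index", y = expression(-log[10](p)),
                  colour = NULL)
}

#' TSS-distance histogram of an annotated element bank
#' @param bank an annotated `cre_bank`.
#' @return A ggplot.
#' @export
plot_tss_profile <- function(bank) {
  stopifnot("tss_distance" %in% names(bank))
  df <- as_tibble(bank)[!is.na(bank$tss_distance), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tss_distance / 1000)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::labs(x = "distance to nearest TSS (kb)", y = "elements")
}
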