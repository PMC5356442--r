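# ggplot2 visualisations for the main result types.

#' Histogram of clone log2(E/M) ratios per time point
#'
#' @param metrics Output of [phenotype_metrics()].
#' @param binwidth Histogram bin width on the log2 scale.
#' @return A ggplot.
#' @export
plot_ratio_distribution <- function(metrics, binwidth = 1) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$log2_em)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::facet_wrap(~timepoint, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(log[2](E/M)), y = "clones") +
    ggplot2::theme_minimal()
}

#' Clone stability scatter between two time points
#'
#' @param metrics Output of [phenotype_metrics()].
#' @param timepoints Length-2 vector of time points to compare.
#' @return A ggplot of per-clone log2(E/M) at one time point against the
#'   other, with the identity line.
#' @export
plot_stability <- function(metrics, timepoints = NULL) {
  tps <- sort(unique(metrics$timepoint))
  timepoints <- timepoints %||% tps[1:2]
  wide <- metrics %>%
    filter(.data$timepoint %in% timepoints) %>%
    select("clone", "timepoint", "log2_em") %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "log2_em",
                       names_prefix = "t")
  cols <- paste0("t", timepoints)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[cols[1]]], y = .data[[cols[2]]])) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = sprintf("log2(E/M), time point %s", timepoints[1]),
                  y = sprintf("log2(E/M), time point %s", timepoints[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.permutation_cor <- function(object, ...) {
  ggplot2::ggplot(tibble(rho = object$perm_rho), ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$rho, colour = "blue") +
    ggplot2::labs(x = "permuted Pearson correlation", y = "permutations",
                  subtitle = sprintf("observed rho = %.3f, p = %.3g",
                                     object$rho, object$p)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.heritability <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pooled_log2_em,
                               y = .data$subclone_log2_em)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black") +
    ggplot2::labs(x = "pooled population log2(E/M)",
                  y = "single-cell clone log2(E/M)",
                  subtitle = sprintf("rho = %.3f (n = %d)", object$rho, object$n)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.treatment_sim <- function(object, ...) {
  ggplot2::ggplot(object$fold_change,
                  ggplot2::aes(x = .data$bin_mid, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone fraction epithelial (bin midpoint)",
                  y = "median clone fold change") +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized CNV profiles
#'
#' @param cnv_norm Matrix from [normalize_to_baseline()].
#' @param windows Window map from [cnv_profiles()] (`$windows`).
#' @param clusters Optional `clone_clusters` to order cells by clone.
#' @return A ggplot tile heatmap (windows on x, cells on y).
#' @export
plot_cnv_heatmap <- function(cnv_norm, windows, clusters = NULL) {
  cells <- colnames(cnv_norm) %||% as.character(seq_len(ncol(cnv_norm)))
  ord <- if (!is.null(clusters)) clusters$hclust$order else seq_along(cells)
  df <- tibble(
    window = rep(windows$window, times = length(cells)),
    chrom = rep(windows$chrom, times = length(cells)),
    cell = rep(cells, each = nrow(windows)),
    value = as.vector(cnv_norm)
  )
  df$cell <- factor(df$cell, levels = cells[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$cell,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "genomic window", y = "cell", fill = "log2 CNV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
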