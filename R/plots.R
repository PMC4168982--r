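#' Genotype heatmap of a bloc, with similar individuals adjacent
#'
#' The visual-inspection plot for a bloc: one row per individual (ordered
#' by [order_individuals_for_plot()] within each phenotype group), one
#' column per bloc SNP. Dark blue marks a homozygote for the alternate
#' (non-pattern) allele, light blue a heterozygote, red a homozygote for
#' the pattern allele, and white a missing genotype. All individuals are
#' shown, including those excluded from the association tables for
#' missingness.
#'
#' @inheritParams order_individuals_for_plot
#' @return A ggplot object.
#' @export
plot_bloc_genotypes <- function(gm, bloc, k_clusters = 1L) {
  ord <- order_individuals_for_plot(gm, bloc, k_clusters = k_clusters)
  codes <- ord$codes
  df <- tibble(
    row = rep(seq_len(nrow(codes)), times = ncol(codes)),
    snp = factor(rep(colnames(codes), each = nrow(codes)),
                 levels = colnames(codes)),
    group = rep(ord$group, times = ncol(codes)),
    code = factor(as.vector(codes), levels = c(0, 1, 2, 9))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp, y = .data$row,
                                   fill = .data$code)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "#08306B", `1` = "#6BAED6", `2` = "#CB181D",
                 `9` = "white"),
      labels = c("alternate hom.", "heterozygote", "pattern hom.",
                 "missing"),
      name = NULL, drop = FALSE
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "individuals (similarity-ordered)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Null-distribution plot for a permutation object
#'
#' Histogram of per-trial maxima with the empirical threshold and/or the
#' comparison cutoff marked.
#'
#' @param object A `permutation_null` from [permute_phenotype_null()] or
#'   [null_max_ccc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_null
#' @export
autoplot.permutation_null <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$maximum)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey65", colour = "grey30") +
    ggplot2::labs(
      x = if (object$kind == "phenotype_labels") {
        "per-trial maximum G"
      } else "per-trial maximum CCC facet",
      y = "trials",
      title = sprintf("%s null (%d trials)", object$kind, object$n_trials)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                 linetype = "dashed", colour = "red")
  }
  if (!is.null(object$cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = object$cutoff,
                                 linetype = "dotted", colour = "blue")
  }
  p
}

#' Bloc-size overview of an allele network
#'
#' Bar chart of bloc sizes (node counts) with singletons shown as size 1.
#'
#' @param object An `allele_network`.
#' @param blocs Optional precomputed [extract_blocs()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allele_network
#' @export
autoplot.allele_network <- function(object, blocs = NULL, ...) {
  if (is.null(blocs)) blocs <- suppressWarnings(extract_blocs(object))
  sizes <- c(blocs$n_nodes,
             rep(1L, object$n_nodes - sum(blocs$n_nodes)))
  df <- dplyr::count(tibble(size = sizes), .data$size)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$size), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "component size (nodes; 1 = singleton)",
                  y = "count",
                  title = sprintf("%d nodes, %d edges, cutoff %.3f",
                                  object$n_nodes, nrow(object$edges),
                                  object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Density-sweep trajectory plot
#'
#' @param sweep Output of [density_sweep()].
#' @return A ggplot of tracked-bloc size against network density, coloured
#'   by whether the reference bloc is still matched (Jaccard >= 0.5).
#' @export
plot_density_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$n_edges,
                                      y = .data$bloc_n_nodes)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$same_bloc), size = 2) +
    ggplot2::labs(x = "network edges", y = "tracked bloc size (nodes)",
                  colour = "same bloc") +
    ggplot2::theme_minimal()
}
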