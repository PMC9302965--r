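#' Plot the fragment insert-size distribution
#'
#' The classic ATAC-seq downward-ladder profile, with the nucleosomal size
#' classes shaded.
#'
#' @param fragments Fragment tibble.
#' @param scheme A [size_class_scheme()].
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(fragments, scheme = size_class_scheme()) {
  len <- fragment_lengths(fragments)
  df <- tibble(length = len,
               class = classify_fragment_length(len, scheme))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0) +
    ggplot2::labs(x = "insert size (bp)", y = "fragments", fill = "size class") +
    ggplot2::theme_minimal()
}

#' Plot the TSS enrichment profile
#'
#' @param profile Output of [tss_profile()].
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin_start, y = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "mean fragment coverage") +
    ggplot2::theme_minimal()
}

#' @rdname qc_report
#' @param object An `atac_qc` object.
#' @method autoplot atac_qc
#' @export
autoplot.atac_qc <- function(object, ...) {
  frip_df <- mutate(object$frip, what = "FRiP")
  ggplot2::ggplot(frip_df, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of fragments",
                  title = sprintf("FRiP partition (FROT = %.3f)", object$frot)) +
    ggplot2::theme_minimal()
}

#' @rdname classify_peaks
#' @param object An `atac_comparison` object.
#' @method autoplot atac_comparison
#' @export
autoplot.atac_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$pct)), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "% of merged peaks",
                  title = sprintf("%s vs %s", object$set_labels[1], object$set_labels[2])) +
    ggplot2::theme_minimal()
}

#' Expression scatter of enriched TFs
#'
#' Target-condition versus background-condition log2CPM of the TFs behind the
#' top enriched motifs, with the nominated factors highlighted — the standard
#' visual for motif-expression integration.
#'
#' @param ranking An `atac_tf_ranking` from [rank_tfs_by_expression()].
#' @return A ggplot object.
#' @export
plot_tf_expression <- function(ranking) {
  df <- as_tibble(ranking)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expr_background, y = .data$expr_target,
                                   colour = .data$nominated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(data = df[df$nominated, , drop = FALSE],
                       ggplot2::aes(label = .data$tf_gene),
                       vjust = -0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey30")) +
    ggplot2::labs(
      x = sprintf("log2CPM (%s)", attr(ranking, "background")),
      y = sprintf("log2CPM (%s)", attr(ranking, "target")),
      colour = "nominated"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname rank_tfs_by_expression
#' @param object An `atac_tf_ranking` object.
#' @method autoplot atac_tf_ranking
#' @export
autoplot.atac_tf_ranking <- function(object, ...) {
  plot_tf_expression(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
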