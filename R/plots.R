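#' Scatter plot of contig vs gene log2 fold changes
#'
#' The diagnostic scatter for one contig set: each point is a contig (or an
#' uncovered gene) with the gold-standard gene fold change on the x axis and
#' the contig fold change on the y axis.  Points on x = 0 are contigs with no
#' corresponding gene (erroneous contigs); points on y = 0 are genes no
#' contig covered.  A tight diagonal indicates a faithful, non-redundant
#' reference.
#'
#' @param paired Output of [pair_fold_changes()].
#' @return A ggplot object.
#' @export
plot_fold_change_scatter <- function(paired) {
  ggplot2::ggplot(
    paired,
    ggplot2::aes(
      x = .data$gene_log2fc, y = .data$contig_log2fc,
      colour = .data$pairing_status
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "gene log2 fold change",
      y = "contig log2 fold change",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of per-term annotation counts for DEGs vs DECs
#'
#' @param go_comparison A `go_comparison` from [compare_go_distributions()].
#' @return A ggplot object.
#' @export
plot_go_counts <- function(go_comparison) {
  long <- tidy(go_comparison) %>%
    select("term", "deg_count", "dec_count") %>%
    tidyr::pivot_longer(
      c("deg_count", "dec_count"),
      names_to = "set", values_to = "count"
    ) %>%
    mutate(set = ifelse(.data$set == "deg_count", "DEG", "DEC"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$term, y = .data$count, fill = .data$set)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "annotation count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Quantile-quantile plot of GO term count distributions
#'
#' Sorted per-term DEG counts against sorted per-term DEC counts; points on
#' the diagonal mean the two distributions agree.
#'
#' @param go_comparison A `go_comparison`.
#' @return A ggplot object.
#' @export
plot_go_qq <- function(go_comparison) {
  tbl <- tidy(go_comparison)
  qq <- tibble(
    deg_quantile = sort(tbl$deg_count),
    dec_quantile = sort(tbl$dec_count)
  )
  ggplot2::ggplot(
    qq, ggplot2::aes(x = .data$deg_quantile, y = .data$dec_quantile)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "DEG count quantiles", y = "DEC count quantiles") +
    ggplot2::theme_minimal()
}

#' @rdname plot_go_counts
#' @param object A `go_comparison`.
#' @param ... Unused.
#' @export
autoplot.go_comparison <- function(object, ...) plot_go_counts(object)

#' Panel of evaluation metrics across contig sets
#'
#' One bar panel per headline metric (fold-change correlation, nonidentical
#' DEC count, KS statistic, significant GO terms) comparing the raw set and
#' each deduplication method.
#'
#' @param object A `redundancy_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.redundancy_benchmark <- function(object, ...) {
  long <- object$evaluation_summary %>%
    select(
      "contig_set", "correlation_all", "n_dec_nonidentical",
      "ks_statistic", "n_significant_terms"
    ) %>%
    tidyr::pivot_longer(-"contig_set", names_to = "metric") %>%
    mutate(contig_set = factor(.data$contig_set, levels = unique(.data$contig_set)))
  ggplot2::ggplot(
    long, ggplot2::aes(x = .data$contig_set, y = .data$value)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
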