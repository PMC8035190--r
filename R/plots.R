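# ggplot2 views of the two result types: outcome-category fractions and the
# deletion-span chart (bars spanning the deleted sequence, nick positions as
# dotted lines).

#' Plot outcome-category fractions
#'
#' @param summary An `amplicon_summary` or `uditas_summary`.
#' @return A ggplot.
#' @export
plot_outcome_fractions <- function(summary) {
  td <- tidy(summary)
  val <- if ("rate" %in% names(td)) "rate" else "ratio"
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$category, -.data[[val]]),
                                   y = .data[[val]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of reads / UMIs",
                  title = td$sample[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot deletion spans
#'
#' Each cluster is a horizontal bar spanning the deleted interval, annotated
#' with its size and supporting-UMI count; nick positions are dotted lines.
#'
#' @param clusters Result of [deletion_significance()] (or
#'   [cluster_deletions()]).
#' @param amplicon Optional [amplicon_spec()] supplying nick positions.
#' @param significant_only Show only BH-significant clusters.
#' @return A ggplot.
#' @export
plot_deletion_spans <- function(clusters, amplicon = NULL, significant_only = FALSE) {
  cl <- clusters
  if (significant_only && "significant" %in% names(cl))
    cl <- cl[cl$significant, , drop = FALSE]
  cl <- arrange(cl, .data$start)
  cl$y <- seq_len(nrow(cl))
  p <- ggplot2::ggplot(cl) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y),
                          linewidth = 2, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(x = .data$end, y = .data$y,
                                    label = sprintf("%d bp, %d UMIs",
                                                    .data$size, .data$umi_count)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "reference position (0-based)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(amplicon)) {
    nk <- c(amplicon$peg_nick, amplicon$nick_sgrna_nick)
    p <- p + ggplot2::geom_vline(xintercept = nk, linetype = "dotted")
  }
  p
}

#' @rdname plot_outcome_fractions
#' @param object An `amplicon_summary` or `uditas_summary`.
#' @param ... Unused.
#' @export
autoplot.amplicon_summary <- function(object, ...) plot_outcome_fractions(object)

#' @rdname plot_outcome_fractions
#' @export
autoplot.uditas_summary <- function(object, ...) plot_outcome_fractions(object)
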