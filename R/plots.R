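# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kmer model's level means
#'
#' Distribution of modeled level means, split by whether the kmer contains
#' an XNA letter; a quick visual check that XNA kmers occupy the same
#' normalized-level scale as canonical ones while shifting individual
#' contexts.
#'
#' @param object An `xna_kmer_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xna_kmer_model
#' @export
autoplot.xna_kmer_model <- function(object, ...) {
  d <- tidy(object)
  d$class <- ifelse(d$n_xna > 0, "XNA kmer", "canonical kmer")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mu, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "modeled kmer level mean (normalized)", y = "kmers",
                  fill = NULL,
                  title = sprintf("kmer model (k = %d, %d kmers)",
                                  object$k, nrow(object$entries))) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' Recall (true-positive rate) against the false-positive rate among
#' XNA-free observations ("FDR" in this benchmark's usage), swept over the
#' statistic threshold.
#'
#' @param object An `xna_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xna_roc
#' @export
autoplot.xna_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fdr, y = .data$recall)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "FDR (false-positive rate)", y = "recall",
                  title = sprintf("ROC, AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Truth-by-called heatmap of call counts, the standard display for
#' per-read or consensus basecalling benchmarks.
#'
#' @param object An `xna_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xna_confusion
#' @export
autoplot.xna_confusion <- function(object, ...) {
  d <- object$table |>
    dplyr::group_by(.data$truth) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  coll <- xna_collation()
  d$truth <- factor(d$truth, levels = intersect(coll, unique(d$truth)))
  d$called <- factor(d$called, levels = intersect(coll, unique(d$called)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$called, y = .data$truth,
                                  fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$frac)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4c2a85",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "called base", y = "truth base", fill = "fraction") +
    ggplot2::theme_minimal()
}
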