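# Benchmarking of call sets: confusion matrices, recall, specificity, ROC
# and AUC.

#' Confusion matrix for XNA calls
#'
#' Cross-tabulates truth bases against called bases and derives TP / FN /
#' FP / TN relative to the positive (XNA) class: a true positive is an XNA
#' truth called as that XNA; a false positive is a non-XNA truth called as
#' any XNA.
#'
#' @param data A data frame of scored calls.
#' @param truth,called Column names (tidy-select style strings) holding the
#'   truth base and the called base. Defaults fit the output of
#'   [call_positions()] joined to a truth table.
#' @param positive Character vector of letters forming the positive class;
#'   default: every non-ACGT letter seen in `truth`.
#' @return An object of class `xna_confusion`: list with `table` (tibble
#'   truth x called x n), `tp`, `fn`, `fp`, `tn`, `positive`.
#' @export
confusion_matrix <- function(data, truth = "truth_base", called = "called_base",
                             positive = NULL) {
  tr <- data[[truth]]
  cl <- data[[called]]
  stopifnot(!is.null(tr), !is.null(cl))
  keep <- !is.na(tr) & !is.na(cl)
  tr <- tr[keep]; cl <- cl[keep]
  if (is.null(positive)) positive <- setdiff(unique(tr), STANDARD_BASES)
  tab <- dplyr::count(tibble::tibble(truth = tr, called = cl),
                      .data$truth, .data$called, name = "n")
  pos <- tr %in% positive
  structure(list(
    table = tab,
    tp = sum(pos & cl == tr),
    fn = sum(pos & cl != tr),
    fp = sum(!pos & cl %in% positive),
    tn = sum(!pos & !(cl %in% positive)),
    positive = positive,
    n = length(tr)
  ), class = "xna_confusion")
}

#' @export
print.xna_confusion <- function(x, ...) {
  cat("<xna_confusion> n =", x$n, "| positive class:",
      paste(x$positive, collapse = ","), "\n")
  cat(sprintf("  TP=%d FN=%d FP=%d TN=%d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Recall of a call set
#'
#' `TP / (TP + FN)`: the fraction of XNA-containing observations called
#' correctly.
#'
#' @param cm An `xna_confusion` object.
#' @return Recall in `[0, 1]`; `NA` with a warning when there are no
#'   positive-class observations.
#' @export
recall <- function(cm) {
  stopifnot(inherits(cm, "xna_confusion"))
  if (cm$tp + cm$fn == 0) {
    warning("no positive-class observations: recall undefined", call. = FALSE)
    return(NA_real_)
  }
  cm$tp / (cm$tp + cm$fn)
}

#' Specificity of a call set
#'
#' Implemented exactly as `1 - FP / (FP + TN)`, the complement of the
#' false-positive rate among XNA-free observations (the rate is reported
#' as "FDR" in the ROC sweep, matching its usage in this pipeline's
#' benchmarking; a precision-based false discovery rate
#' `FP / (FP + TP)` is available via `precision_fdr`).
#'
#' @param cm An `xna_confusion` object.
#' @return Specificity in `[0, 1]`; `NA` with a warning when there are no
#'   negative-class observations.
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "xna_confusion"))
  if (cm$fp + cm$tn == 0) {
    warning("no negative-class observations: specificity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - cm$fp / (cm$fp + cm$tn)
}

#' @rdname specificity
#' @export
precision_fdr <- function(cm) {
  stopifnot(inherits(cm, "xna_confusion"))
  if (cm$fp + cm$tp == 0) return(NA_real_)
  cm$fp / (cm$fp + cm$tp)
}

#' ROC curve over classification thresholds
#'
#' Sweeps a decision threshold over the statistic values and computes, at
#' each threshold, the recall (true-positive rate) and the false-positive
#' rate among negatives (reported as `fdr`, matching the recall-vs-FDR
#' framing of the benchmark). Observations with `score >= threshold` are
#' called positive. The area under the curve is computed by trapezoidal
#' integration.
#'
#' @param data A data frame of scored observations.
#' @param score,truth Column names: numeric statistic (larger = more
#'   XNA-like) and logical/0-1 truth label (TRUE = contains the XNA).
#' @return An object of class `xna_roc`: list with `points` (tibble:
#'   threshold, recall, fdr) and `auc`.
#' @export
roc_curve <- function(data, score = "score", truth = "truth") {
  s <- data[[score]]
  y <- as.logical(data[[truth]])
  stopifnot(all(is.finite(s)), !anyNA(y))
  if (!any(y) || all(y)) {
    stop("ROC needs both positive and negative observations", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pts <- vapply(thr, function(t) {
    pred <- s >= t
    c(recall = sum(pred & y) / sum(y),
      fdr = sum(pred & !y) / sum(!y))
  }, numeric(2))
  points <- tibble::tibble(threshold = thr,
                           recall = pts["recall", ],
                           fdr = pts["fdr", ])
  o <- order(points$fdr, points$recall)
  auc <- sum(diff(points$fdr[o]) *
               (utils::head(points$recall[o], -1) +
                  utils::tail(points$recall[o], -1)) / 2)
  structure(list(points = points, auc = auc), class = "xna_roc")
}

#' @export
print.xna_roc <- function(x, ...) {
  cat("<xna_roc>", nrow(x$points), "thresholds | AUC =",
      sprintf("%.4f\n", x$auc))
  invisible(x)
}
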