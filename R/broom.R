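# tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kmer model
#'
#' @param x An `xna_kmer_model`.
#' @param ... Unused.
#' @return The per-kmer entries as a tibble, with an `n_xna` column
#'   counting non-canonical letters per kmer.
#' @method tidy xna_kmer_model
#' @export
tidy.xna_kmer_model <- function(x, ...) {
  dplyr::mutate(
    x$entries,
    n_xna = nchar(gsub("[ACGT]", "", .data$kmer))
  )
}

#' @rdname tidy.xna_kmer_model
#' @return For `glance`: a one-row tibble with `k`, `n_kmers`, `n_xna_kmers`,
#'   `global_sigma`, `sigma_policy`, `estimator`, `total_coverage`.
#' @method glance xna_kmer_model
#' @export
glance.xna_kmer_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_kmers = nrow(x$entries),
    n_xna_kmers = sum(grepl("[^ACGT]", x$entries$kmer)),
    global_sigma = x$global_sigma,
    sigma_policy = x$sigma_policy,
    estimator = x$estimator,
    total_coverage = sum(x$entries$coverage)
  )
}

#' Tidy a confusion matrix
#'
#' @param x An `xna_confusion`.
#' @param ... Unused.
#' @return `tidy`: the truth-by-called counts as a tibble; `glance`: a
#'   one-row tibble with tp, fn, fp, tn, recall and specificity.
#' @method tidy xna_confusion
#' @export
tidy.xna_confusion <- function(x, ...) x$table

#' @rdname tidy.xna_confusion
#' @method glance xna_confusion
#' @export
glance.xna_confusion <- function(x, ...) {
  tibble::tibble(
    n = x$n, tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
    recall = if (x$tp + x$fn > 0) x$tp / (x$tp + x$fn) else NA_real_,
    specificity = if (x$fp + x$tn > 0) 1 - x$fp / (x$fp + x$tn) else NA_real_
  )
}

#' Tidy an ROC curve
#'
#' @param x An `xna_roc`.
#' @param ... Unused.
#' @return `tidy`: the threshold sweep (threshold, recall, fdr); `glance`:
#'   a one-row tibble with `auc` and the number of thresholds.
#' @method tidy xna_roc
#' @export
tidy.xna_roc <- function(x, ...) x$points

#' @rdname tidy.xna_roc
#' @method glance xna_roc
#' @export
glance.xna_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_thresholds = nrow(x$points))
}
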