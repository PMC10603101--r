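# Per-read normalized current-level tables: the downstream product of
# basecalling + signal-to-sequence mapping, and the main input to the
# basecaller. One row per read; one level per reference base.

LEVELS_COLUMNS <- c("read_id", "reference_name", "reference_seq",
                    "levels", "q_score", "match_score")

#' Read / write a per-read level table
#'
#' The level CSV has one row per read with columns `read_id`,
#' `reference_name`, `reference_seq`, `levels` (semicolon-joined normalized
#' current levels, one per reference base), `q_score` and `match_score`
#' (signal match score, lower is better). In memory, `levels` is a list
#' column of numeric vectors. Rows whose level count does not match the
#' sequence length, or with non-finite levels, are rejected with their file
#' line numbers.
#'
#' @param path File path.
#' @return `read_levels` returns a tibble of class `xna_levels`;
#'   `write_levels` returns `path` invisibly.
#' @export
read_levels <- function(path) {
  hdr <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE, n_max = 0)
  missing_cols <- setdiff(LEVELS_COLUMNS, names(hdr))
  if (length(missing_cols) > 0) {
    stop("level table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           levels = readr::col_character(),
                           reference_seq = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  if (nrow(raw) == 0) {
    out <- raw
    out$levels <- list()
    return(as_xna_levels(out))
  }
  lvl <- lapply(strsplit(raw$levels, ";", fixed = TRUE), as.numeric)
  n_lvl <- lengths(lvl)
  ok <- n_lvl == nchar(raw$reference_seq) &
    vapply(lvl, function(v) all(is.finite(v)), logical(1))
  if (!all(ok)) {
    # +1 for the header; comment lines above the header would shift further
    stop("malformed level rows (level count != sequence length or ",
         "non-finite levels) at file line(s): ",
         paste(which(!ok) + 1L, collapse = ", "), call. = FALSE)
  }
  out <- raw
  out$levels <- lvl
  as_xna_levels(out)
}

#' @param x A level table (tibble with the columns above; `levels` may be a
#'   list column or already semicolon-joined strings).
#' @rdname read_levels
#' @export
write_levels <- function(x, path) {
  stopifnot(all(LEVELS_COLUMNS %in% names(x)))
  out <- tibble::as_tibble(x)
  if (is.list(out$levels)) {
    out$levels <- vapply(out$levels, function(v) {
      paste(sprintf("%.17g", v), collapse = ";")
    }, character(1))
  }
  readr::write_csv(out[LEVELS_COLUMNS], path, progress = FALSE)
  invisible(path)
}

as_xna_levels <- function(x) {
  x <- tibble::as_tibble(x)
  if (anyDuplicated(x$read_id)) {
    stop("duplicate read_id in level table", call. = FALSE)
  }
  class(x) <- unique(c("xna_levels", class(x)))
  x
}

#' Quality-filter a level table
#'
#' Drops reads with a q-score below `min_q` or a signal match score above
#' `max_match_score` (lower match score = better signal fit). The defaults
#' reproduce the standard read-filtering rule: q-score < 9 or match score
#' > 3 are discarded, boundary values kept.
#'
#' @param x A level table.
#' @param min_q Minimum q-score retained (default 9).
#' @param max_match_score Maximum signal match score retained (default 3).
#' @return The filtered table; the number of removed reads is reported via
#'   `message()`.
#' @export
filter_reads <- function(x, min_q = 9, max_match_score = 3) {
  stopifnot(all(c("q_score", "match_score") %in% names(x)))
  keep <- x$q_score >= min_q & x$match_score <= max_match_score
  message("filter_reads: removed ", sum(!keep), " of ", nrow(x), " reads")
  dplyr::filter(x, keep)
}

#' Average reads mapping to the same reference
#'
#' Per-sequence aggregation: all reads mapping to one reference are
#' collapsed to a single record whose levels are the position-wise
#' arithmetic means. Used for per-sequence (rather than per-read)
#' hypothesis testing.
#'
#' @param x A level table with a `levels` list column.
#' @return A level table with one row per `reference_name`; `n_reads`
#'   records how many reads were averaged; `q_score` and `match_score` are
#'   averaged alongside.
#' @export
aggregate_per_sequence <- function(x) {
  stopifnot(is.list(x$levels))
  x |>
    dplyr::group_by(.data$reference_name) |>
    dplyr::group_modify(function(g, key) {
      lens <- unique(lengths(g$levels))
      if (length(lens) != 1) {
        stop("reads mapping to '", key$reference_name,
             "' have inconsistent level lengths", call. = FALSE)
      }
      if (length(unique(g$reference_seq)) != 1) {
        stop("reads mapping to '", key$reference_name,
             "' carry different reference sequences", call. = FALSE)
      }
      tibble::tibble(
        read_id = paste0("consensus:", key$reference_name),
        reference_seq = g$reference_seq[1],
        levels = list(rowMeans(do.call(cbind, g$levels))),
        q_score = mean(g$q_score),
        match_score = mean(g$match_score),
        n_reads = nrow(g)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("read_id") |>
    as_xna_levels()
}

#' Median/MAD-normalize a raw signal vector
#'
#' Helper mirroring per-read median normalization of raw current values:
#' subtract the read median and divide by the median absolute deviation
#' (scaled to be consistent with the standard deviation for Gaussian
#' signal). Provided for constructing level tables from unnormalized
#' values; the simulator emits normalized levels directly.
#'
#' @param x Numeric vector of raw per-base signal values for one read.
#' @return Normalized levels, same length as `x`.
#' @export
median_normalize <- function(x) {
  s <- stats::mad(x)
  if (s == 0) stop("cannot normalize a constant signal", call. = FALSE)
  (x - stats::median(x)) / s
}
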