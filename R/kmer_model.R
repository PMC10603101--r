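# 4-nt kmer current-level model: heptamer decomposition, parameter fitting
# (mean / median / KDE), global sigma policy, the level density, and the
# model CSV format.

#' Decompose a heptamer context into its covering kmers
#'
#' Every base in a sequence is covered by `k` kmers; for a focal base with a
#' full heptamer context (k = 4) these are the kmers starting at positions
#' `focal_pos - 3 .. focal_pos`, labelled by the focal base's offset within
#' the kmer: +2 (focal last, `NNNX`), +1 (`NNXN`), 0 (`NXNN`) and -1 (focal
#' first, `XNNN`).
#'
#' @param seq A single sequence over the expanded alphabet.
#' @param focal_pos 1-based position of the focal base; needs at least
#'   `k - 1` flanking bases on each side.
#' @param k Kmer length (default 4).
#' @return A tibble with columns `offset` (integer label, +2 down to -1 for
#'   k = 4), `start` (1-based start of the kmer in `seq`) and `kmer`.
#' @examples
#' decompose_heptamer("AGTBCCT", 4)
#' @export
decompose_heptamer <- function(seq, focal_pos, k = 4) {
  stopifnot(length(seq) == 1, k >= 2)
  n <- nchar(seq)
  if (focal_pos - (k - 1) < 1 || focal_pos + (k - 1) > n) {
    stop("position ", focal_pos, " lacks the ", k - 1,
         "-base flanking context needed on each side", call. = FALSE)
  }
  starts <- seq(focal_pos - (k - 1), focal_pos)
  tibble::tibble(
    # focal base's 1-based index within the kmer, shifted so that the
    # "0 position" kmer is the one with the focal base second (NXNN)
    offset = (focal_pos - starts + 1L) - (k - 2L),
    start  = starts,
    kmer   = substring(seq, starts, starts + k - 1)
  )
}

#' Silverman-style KDE bandwidth for kmer levels
#'
#' Bandwidth for the kernel density estimate of one kmer's level
#' distribution: `A = 0.9 * min(IQR / 1.34, sd)` and `BW = A * n^(-1/5)`.
#' Constant data (IQR = sd = 0) falls back to a small positive bandwidth
#' and is flagged with a warning.
#'
#' @param levels Numeric vector of observed normalized levels for one kmer.
#' @param fallback Bandwidth used when the data are constant.
#' @return A positive bandwidth (double).
#' @export
kde_bandwidth <- function(levels, fallback = 1e-3) {
  stopifnot(length(levels) >= 1, all(is.finite(levels)))
  n <- length(levels)
  s <- if (n > 1) stats::sd(levels) else 0
  a <- 0.9 * min(stats::IQR(levels) / 1.34, s)
  if (a <= 0) {
    warning("constant levels: falling back to bandwidth ", fallback,
            call. = FALSE)
    a <- fallback
  }
  a * n^(-1 / 5)
}

# KDE grid shared by the mode and mean summaries: 512 points spanning the
# data range extended by 3 bandwidths.
kde_grid <- function(levels, bw) {
  stats::density(levels, bw = bw, n = 512,
                 from = min(levels) - 3 * bw, to = max(levels) + 3 * bw)
}

# KDE mode: grid argmax refined by a log-quadratic fit over the connected
# half-height region around the peak. The refinement averages out kernel
# wiggle, which dominates the raw grid argmax's variance.
kde_mode <- function(levels, bw = kde_bandwidth(levels)) {
  d <- kde_grid(levels, bw)
  imax <- which.max(d$y)
  high <- d$y >= 0.5 * d$y[imax]
  lo <- imax; while (lo > 1 && high[lo - 1]) lo <- lo - 1
  hi <- imax; while (hi < length(high) && high[hi + 1]) hi <- hi + 1
  idx <- lo:hi
  if (length(idx) < 3) return(d$x[imax])
  b <- stats::coef(stats::lm(log(d$y[idx]) ~ stats::poly(d$x[idx], 2,
                                                         raw = TRUE)))
  vertex <- -b[[2]] / (2 * b[[3]])
  # fall back to the grid argmax if the fit is not concave or runs away
  if (!is.finite(vertex) || b[[3]] >= 0 ||
      vertex < d$x[lo] || vertex > d$x[hi]) return(d$x[imax])
  vertex
}

kde_mean <- function(levels, bw = kde_bandwidth(levels)) {
  d <- kde_grid(levels, bw)
  sum(d$x * d$y) / sum(d$y)
}

#' Fit a kmer current-level model
#'
#' Estimates per-kmer level statistics from observed normalized levels.
#' Level distributions are modeled as Gaussians with mean `mu` and standard
#' deviation `std`; the location estimate `mu` can be the sample mean, the
#' sample median, the mode of a kernel density estimate (`"kde"`), or the
#' KDE grid mean (`"kde_mean"`, close to the sample mean by construction).
#' The model's global sigma is the arithmetic mean of the per-kmer standard
#' deviations; the `sigma_policy` decides which sigma likelihood
#' evaluations use.
#'
#' @param data A data frame with columns `kmer` and `level`, one row per
#'   observation.
#' @param estimator Location estimator for `mu`: `"mean"` (default),
#'   `"median"`, `"kde"` or `"kde_mean"`.
#' @param sigma_policy `"global"` (default: one sigma, the mean of per-kmer
#'   standard deviations), `"per_kmer"`, or `"manual"`.
#' @param manual_sigma Sigma used when `sigma_policy = "manual"`.
#' @return An object of class `xna_kmer_model`: a list with `k`, `entries`
#'   (tibble: kmer, mu, mean, median, std, min, max, iqr, coverage),
#'   `global_sigma`, `sigma_policy`, `estimator`.
#' @seealso [read_kmer_model()], [write_kmer_model()], [synthetic_model()]
#' @export
fit_kmer_model <- function(data, estimator = c("mean", "median", "kde", "kde_mean"),
                           sigma_policy = c("global", "per_kmer", "manual"),
                           manual_sigma = NULL) {
  estimator <- match.arg(estimator)
  sigma_policy <- match.arg(sigma_policy)
  stopifnot(is.data.frame(data), all(c("kmer", "level") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$level))
  if (nrow(data) == 0) stop("no level observations to fit", call. = FALSE)
  k <- unique(nchar(data$kmer))
  if (length(k) != 1) stop("kmers of mixed lengths", call. = FALSE)

  loc <- switch(estimator,
    mean     = function(x) mean(x),
    median   = function(x) stats::median(x),
    kde      = function(x) if (length(x) > 1) kde_mode(x) else x,
    kde_mean = function(x) if (length(x) > 1) kde_mean(x) else x
  )
  entries <- data |>
    dplyr::group_by(.data$kmer) |>
    dplyr::summarise(
      mu       = loc(.data$level),
      mean     = mean(.data$level),
      median   = stats::median(.data$level),
      std      = ifelse(dplyr::n() > 1, stats::sd(.data$level), 0),
      min      = min(.data$level),
      max      = max(.data$level),
      iqr      = stats::IQR(.data$level),
      coverage = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(substr(.data$kmer, 1, 1), xna_collation()), .data$kmer)

  new_kmer_model(k = k, entries = entries, sigma_policy = sigma_policy,
                 manual_sigma = manual_sigma, estimator = estimator)
}

new_kmer_model <- function(k, entries, sigma_policy = "global",
                           manual_sigma = NULL, estimator = "mean") {
  stopifnot(all(nchar(entries$kmer) == k), !anyDuplicated(entries$kmer))
  if (sigma_policy == "manual" && is.null(manual_sigma)) {
    stop("sigma_policy = 'manual' requires manual_sigma", call. = FALSE)
  }
  structure(
    list(
      k = as.integer(k),
      entries = tibble::as_tibble(entries),
      global_sigma = mean(entries$std),
      sigma_policy = sigma_policy,
      manual_sigma = manual_sigma,
      estimator = estimator
    ),
    class = "xna_kmer_model"
  )
}

#' @export
print.xna_kmer_model <- function(x, ...) {
  cat("<xna_kmer_model> k =", x$k, "|", nrow(x$entries), "kmers |",
      "sigma_policy =", x$sigma_policy,
      sprintf("| global_sigma = %.4f\n", x$global_sigma))
  print(x$entries, n = 5)
  invisible(x)
}

# Look up model means for a set of kmers; missing kmers are a coverage
# error naming the offenders.
model_mu <- function(model, kmers) {
  idx <- match(kmers, model$entries$kmer)
  if (anyNA(idx)) {
    stop("kmer(s) not covered by the model: ",
         paste(unique(kmers[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  model$entries$mu[idx]
}

# Sigma per the model's policy, recycled to the kmers queried.
model_sigma <- function(model, kmers) {
  switch(model$sigma_policy,
    manual   = rep(model$manual_sigma, length(kmers)),
    global   = rep(model$global_sigma, length(kmers)),
    per_kmer = {
      idx <- match(kmers, model$entries$kmer)
      if (anyNA(idx)) {
        stop("kmer(s) not covered by the model: ",
             paste(unique(kmers[is.na(idx)]), collapse = ", "), call. = FALSE)
      }
      model$entries$std[idx]
    }
  )
}

#' Log10 density of an observed level under a kmer's Gaussian
#'
#' The probability density that a normalized level `I` was emitted by a
#' kmer with level mean `mu` and standard deviation `sigma`, on the log10
#' scale. This is the building block of the likelihood-ratio tests: per-kmer
#' log10 densities are summed over the kmers covering a position.
#'
#' @param level Observed normalized level(s) `I`.
#' @param mu Kmer level mean.
#' @param sigma Level standard deviation (> 0).
#' @return log10 density, vectorized over the inputs.
#' @export
level_log10_pdf <- function(level, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  stats::dnorm(level, mean = mu, sd = sigma, log = TRUE) / log(10)
}

#' Write / read a kmer model CSV
#'
#' The model file is a CSV with columns `kmer`, `mu`, `mean`, `median`,
#' `std`, `min`, `max`, `iqr`, `coverage`, preceded by `#` comment lines
#' recording `k`, the sigma policy, the global sigma and the estimator.
#' Round-trips are lossless; extra columns are preserved; duplicate kmer
#' rows are rejected.
#'
#' @param model An `xna_kmer_model`.
#' @param path File path.
#' @return `write_kmer_model` returns `path` invisibly; `read_kmer_model`
#'   returns an `xna_kmer_model`.
#' @export
write_kmer_model <- function(model, path) {
  stopifnot(inherits(model, "xna_kmer_model"))
  hdr <- c(
    paste0("# xenocall kmer model v", as.character(utils::packageVersion("xenocall"))),
    paste0("# k=", model$k),
    paste0("# sigma_policy=", model$sigma_policy),
    paste0("# global_sigma=", format(model$global_sigma, digits = 17)),
    if (!is.null(model$manual_sigma))
      paste0("# manual_sigma=", format(model$manual_sigma, digits = 17)),
    paste0("# estimator=", model$estimator)
  )
  readr::write_lines(hdr, path)
  readr::write_csv(model$entries, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_kmer_model
#' @export
read_kmer_model <- function(path) {
  lines <- readr::read_lines(path, n_max = 20)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NA_character_) {
    m <- grep(paste0("^# ?", key, "="), meta_lines, value = TRUE)
    if (length(m) == 0) return(default)
    sub(paste0("^# ?", key, "="), "", m[1])
  }
  entries <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                             progress = FALSE)
  required <- c("kmer", "mu", "std", "coverage")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("model file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(entries$kmer)) {
    stop("duplicate kmer rows in model file: ",
         paste(unique(entries$kmer[duplicated(entries$kmer)]), collapse = ", "),
         call. = FALSE)
  }
  k <- as.integer(get_meta("k", as.character(unique(nchar(entries$kmer)))))
  manual_sigma <- get_meta("manual_sigma")
  model <- new_kmer_model(
    k = k, entries = entries,
    sigma_policy = get_meta("sigma_policy", "global"),
    manual_sigma = if (!is.na(manual_sigma)) as.numeric(manual_sigma),
    estimator = get_meta("estimator", "mean")
  )
  gs <- get_meta("global_sigma")
  if (!is.na(gs)) model$global_sigma <- as.numeric(gs)
  model
}
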