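# Monte-Carlo simulation of level data from a kmer model, plus synthetic
# model generation for dependency-free testing, and the closed-form
# Gaussian discrimination oracle.

# Independent child seed per sequence so any subset of sequences is
# reproducible regardless of iteration order. Kept below 2^31 - 1.
child_seed <- function(root_seed, index) {
  (as.numeric(root_seed) * 48271 + index * 7919) %% 2147483587 + 1
}

#' Generate a synthetic kmer model
#'
#' Builds a fully covered kmer model over the standard bases plus any XNA
#' letters, with per-kmer level means drawn uniformly at random and a fixed
#' standard deviation. Synthetic models stand in for measured ones in tests
#' and simulations: the canonical kmers get entries as well as every kmer
#' containing exactly one XNA letter.
#'
#' @param k Kmer length (default 4).
#' @param xna_letters XNA letters to cover (default none: canonical-only
#'   model).
#' @param seed Integer seed for reproducibility.
#' @param mu_range Range the kmer means are drawn from; the default
#'   `c(-2.5, 2.5)` spans the scale of median-normalized levels.
#' @param sigma Per-kmer (and hence global) standard deviation; 0.4 matches
#'   the typical spread of measured normalized kmer levels.
#' @return An `xna_kmer_model` with `coverage = 0` marking entries as
#'   synthetic rather than observed.
#' @export
synthetic_model <- function(k = 4, xna_letters = character(0), seed = 1,
                            mu_range = c(-2.5, 2.5), sigma = 0.4) {
  stopifnot(all(is.finite(mu_range)), length(mu_range) == 2, sigma > 0)
  canon <- sort_kmers(do.call(paste0, expand.grid(
    rep(list(STANDARD_BASES), k), stringsAsFactors = FALSE)))
  kmers <- canon
  if (length(xna_letters) > 0) {
    kmers <- c(kmers, unname(enumerate_xna_kmers(k, xna_letters)))
  }
  kmers <- unique(kmers)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  mu <- withr_seed(stats::runif(length(kmers), mu_range[1], mu_range[2]))
  entries <- tibble::tibble(
    kmer = kmers, mu = mu, mean = mu, median = mu,
    std = sigma, min = mu, max = mu, iqr = 0, coverage = 0L
  )
  new_kmer_model(k = k, entries = entries, sigma_policy = "global",
                 estimator = "mean")
}

#' Simulate reads from a kmer model
#'
#' Draws per-read level vectors for a set of reference sequences. The level
#' assigned to position `q` of a read is sampled from
#' `Normal(mu[kmer starting at q], sigma)`; the trailing `k - 1` positions,
#' whose kmers extend past the sequence end and are never scored, are
#' padded with `Normal(0, sigma)` noise so every record keeps one level per
#' base. Each sequence uses an independent child seed derived from `seed`,
#' so subsets are reproducible.
#'
#' @param model An `xna_kmer_model` covering all kmers of the sequences.
#' @param sequences Named character vector of reference sequences (names
#'   become `reference_name`), or a data frame with `name` and `sequence`.
#' @param n_per_seq Reads simulated per sequence.
#' @param sigma Sampling standard deviation; defaults to the model's global
#'   sigma.
#' @param seed Root seed.
#' @return A level table (`xna_levels` tibble) with `n_per_seq * length(sequences)`
#'   rows; simulated reads carry `q_score = 12` and `match_score = 0` so
#'   they pass default filtering.
#' @export
simulate_reads <- function(model, sequences, n_per_seq = 1000,
                           sigma = NULL, seed = 1) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$name)
  }
  stopifnot(n_per_seq >= 1, !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  if (is.null(sigma)) sigma <- model$global_sigma
  stopifnot(sigma > 0)
  k <- model$k
  groups <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    len <- nchar(s)
    stopifnot(len >= k)
    starts <- seq_len(len - k + 1)
    mus <- c(model_mu(model, substring(s, starts, starts + k - 1)),
             rep(0, k - 1))
    set.seed(child_seed(seed, i))
    mat <- matrix(stats::rnorm(n_per_seq * len,
                               mean = rep(mus, each = n_per_seq),
                               sd = sigma),
                  nrow = n_per_seq)
    groups[[i]] <- tibble::tibble(
      read_id = paste0(names(sequences)[i], ":read", seq_len(n_per_seq)),
      reference_name = names(sequences)[i],
      reference_seq = s,
      levels = lapply(seq_len(n_per_seq), function(r) mat[r, ]),
      q_score = 12,
      match_score = 0
    )
  }
  as_xna_levels(dplyr::bind_rows(groups))
}

#' Simulate the full heptamer space for one substitution base
#'
#' Enumerates every heptamer `NNNxNNN` (`N` = A, T, G, C; `x` the
#' substitution base) and simulates `n_per_heptamer` reads per heptamer
#' from the kmer model, i.e. `4096 * n_per_heptamer` reads in total (the
#' standard genetic-code simulation: 4,096,000 reads per substitution base
#' at the default of 1000).
#'
#' @param model An `xna_kmer_model` covering all heptamer kmers for `x`.
#' @param substitution_base Single letter placed at the heptamer centre
#'   (an XNA letter or a standard base).
#' @param n_per_heptamer Reads per heptamer (default 1000).
#' @param sigma Sampling standard deviation (default 0.4, the fixed global
#'   model sigma used for genetic-code simulations).
#' @param seed Root seed.
#' @return A level table with one record per simulated read.
#' @export
simulate_code <- function(model, substitution_base, n_per_heptamer = 1000,
                          sigma = 0.4, seed = 1) {
  stopifnot(nchar(substitution_base) == 1)
  heptamers <- heptamer_space(substitution_base)
  simulate_reads(model, heptamers, n_per_seq = n_per_heptamer,
                 sigma = sigma, seed = seed)
}

# All 4^6 = 4096 heptamers NNNxNNN with canonical flanks.
heptamer_space <- function(x) {
  flanks <- expand.grid(rep(list(STANDARD_BASES), 6), stringsAsFactors = FALSE)
  h <- paste0(flanks[[1]], flanks[[2]], flanks[[3]], x,
              flanks[[4]], flanks[[5]], flanks[[6]])
  stats::setNames(h, h)
}

#' Closed-form discrimination probability for a heptamer
#'
#' Analytic probability that a read simulated from base `base_i` at the
#' heptamer centre is called as `base_i` rather than `base_j` by the
#' summed-LLR test at threshold 0: `pnorm(sqrt(sum(delta^2)) / (2 * sigma))`
#' where `delta` are the per-kmer mean differences between the two
#' hypotheses. Serves as the independent oracle for simulated recall.
#'
#' @param model An `xna_kmer_model`.
#' @param heptamer A 7-letter sequence whose centre base is replaced by the
#'   two hypotheses.
#' @param base_i Truth base (reads simulated from its model).
#' @param base_j Alternative base.
#' @param sigma Level standard deviation; defaults to the model's global
#'   sigma.
#' @return Probability in `[0.5, 1)` (0.5 when the models coincide).
#' @export
theoretical_recall <- function(model, heptamer, base_i, base_j, sigma = NULL) {
  stopifnot(nchar(heptamer) == 2 * (model$k - 1) + 1)
  if (is.null(sigma)) sigma <- model$global_sigma
  focal <- model$k
  seq_i <- replace_base(heptamer, focal, base_i)
  seq_j <- replace_base(heptamer, focal, base_j)
  d <- decompose_heptamer(seq_i, focal, model$k)
  kmers_i <- d$kmer
  kmers_j <- decompose_heptamer(seq_j, focal, model$k)$kmer
  delta <- model_mu(model, kmers_i) - model_mu(model, kmers_j)
  stats::pnorm(sqrt(sum(delta^2)) / (2 * sigma))
}

replace_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
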