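# Per-read and consensus XNA basecalling by maximum likelihood with LLR /
# outlier-robust LLR (ORLLR) test statistics.
#
# Level-to-kmer convention: the level at position q of a read is modeled by
# the kmer starting at q, so the four kmers covering a focal base use the
# levels at positions focal-3 .. focal (see decompose_heptamer()).

#' ORLLR scaling parameters
#'
#' The outlier-robust LLR damps each per-kmer LLR term by a Gaussian factor
#' in the distance of the observed level from the midpoint of the two
#' hypothesis means, and rescales by the model separation. The defaults
#' (Sf = 4, Sf2 = 3, Sp = 0.3) are the standard resquiggle-toolkit values
#' used throughout.
#'
#' @param sf Width of the Gaussian damping factor (> 0).
#' @param sf2 Overall scale divisor (> 0).
#' @param sp Exponent on the model separation (>= 0).
#' @return A list of class `orllr_params`.
#' @export
orllr_params <- function(sf = 4, sf2 = 3, sp = 0.3) {
  stopifnot(sf > 0, sf2 > 0, sp >= 0)
  structure(list(sf = sf, sf2 = sf2, sp = sp), class = "orllr_params")
}

#' Total log10 likelihood of levels under a candidate sequence
#'
#' Sums the per-kmer log10 densities of the observed levels under the kmer
#' model, over a window of kmer start positions (by default every full kmer
#' in the sequence). For single-position calls, pass the four start
#' positions covering the focal base (see [decompose_heptamer()]).
#'
#' @param levels Numeric vector, one level per base of `candidate_seq`.
#' @param candidate_seq Sequence the levels are scored against.
#' @param model An `xna_kmer_model`.
#' @param starts Kmer start positions to score (default: all).
#' @return Total log10 likelihood (double).
#' @export
sequence_log10_likelihood <- function(levels, candidate_seq, model,
                                      starts = NULL) {
  stopifnot(length(levels) == nchar(candidate_seq))
  k <- model$k
  if (is.null(starts)) starts <- seq_len(nchar(candidate_seq) - k + 1)
  kmers <- substring(candidate_seq, starts, starts + k - 1)
  sum(level_log10_pdf(levels[starts], model_mu(model, kmers),
                      model_sigma(model, kmers)))
}

# Per-kmer pieces shared by llr()/orllr(): observed levels, the two
# hypothesis means and sigma for the 4 kmers covering pos.
hypothesis_kmers <- function(seq, pos, base_i, base_j, model) {
  d_i <- decompose_heptamer(replace_base(seq, pos, base_i), pos, model$k)
  d_j <- decompose_heptamer(replace_base(seq, pos, base_j), pos, model$k)
  list(
    starts = d_i$start,
    mu_i = model_mu(model, d_i$kmer),
    mu_j = model_mu(model, d_j$kmer),
    sigma = model_sigma(model, d_i$kmer)
  )
}

#' Log-likelihood ratio for one position of one read
#'
#' Per-kmer log10 density ratio between base `base_i` and base `base_j` at
#' position `pos`, summed over the four kmers covering the position.
#' Positive values favor `base_i`; `llr(i, j) = -llr(j, i)`.
#'
#' @param levels Numeric vector of the read's normalized levels.
#' @param seq The read's reference sequence.
#' @param pos Position being tested (heptamer context required).
#' @param base_i,base_j The two hypothesis bases.
#' @param model An `xna_kmer_model`.
#' @return The summed LLR (double).
#' @export
llr <- function(levels, seq, pos, base_i, base_j, model) {
  sum(llr_terms(levels, seq, pos, base_i, base_j, model))
}

llr_terms <- function(levels, seq, pos, base_i, base_j, model) {
  h <- hypothesis_kmers(seq, pos, base_i, base_j, model)
  x <- levels[h$starts]
  level_log10_pdf(x, h$mu_i, h$sigma) - level_log10_pdf(x, h$mu_j, h$sigma)
}

#' Outlier-robust log-likelihood ratio
#'
#' Each per-kmer LLR term is damped by `exp(-Sc_diff^2 / (Sf * sigma^2))`,
#' where `Sc_diff` is the observed level's distance from the midpoint of
#' the two hypothesis means, and divided by
#' `sigma^2 * |mu_i - mu_j|^Sp * Sf2`; the damped terms are summed over the
#' four covering kmers. All scale factors are positive, so each per-kmer
#' term keeps the sign of its LLR term. Kmers where the two hypotheses have
#' identical means contribute 0 (the separation power is otherwise
#' singular).
#'
#' @inheritParams llr
#' @param params An [orllr_params()] object.
#' @return The summed ORLLR (double).
#' @export
orllr <- function(levels, seq, pos, base_i, base_j, model,
                  params = orllr_params()) {
  h <- hypothesis_kmers(seq, pos, base_i, base_j, model)
  x <- levels[h$starts]
  lt <- level_log10_pdf(x, h$mu_i, h$sigma) - level_log10_pdf(x, h$mu_j, h$sigma)
  sum(orllr_transform(lt, x, h$mu_i, h$mu_j, h$sigma, params))
}

# Vectorized ORLLR damping of per-kmer LLR terms.
orllr_transform <- function(llr_term, level, mu_i, mu_j, sigma, params) {
  dmu <- abs(mu_i - mu_j)
  sc_diff <- level - (mu_i + mu_j) / 2
  out <- exp(-(sc_diff^2) / (params$sf * sigma^2)) * llr_term /
    (sigma^2 * dmu^params$sp * params$sf2)
  out[dmu == 0] <- 0
  out
}

#' Call XNA positions across a level table
#'
#' The central basecalling verb: for every read and every tested position,
#' scores each candidate base against the base present in the reference
#' (the null, normally the XNA) with the chosen statistic, oriented
#' candidate-versus-null. The called base is the null unless some candidate
#' exceeds `threshold`, in which case the candidate with the maximal
#' statistic wins (alphabetical tie-break). Total log10 likelihoods per
#' hypothesis are reported alongside for multi-way ranking.
#'
#' @param x A level table (see [read_levels()], [simulate_reads()]).
#' @param model An `xna_kmer_model`.
#' @param statistic `"orllr"` (default) or `"llr"`.
#' @param candidates Which alternatives to test at each position:
#'   `"most_similar"` (the null's canonical substitute), `"standard"`
#'   (A, T, G, C), `"all"` (standard plus every other XNA letter with model
#'   coverage), or a character vector of bases.
#' @param threshold Statistic value a candidate must exceed to displace the
#'   null (default 0).
#' @param positions Optional integer vector (recycled per reference) of
#'   positions to test; default: every non-ACGT position in each reference
#'   sequence.
#' @param params ORLLR scaling parameters.
#' @return A tibble of class `xna_calls`: one row per read x position with
#'   `read_id`, `reference_name`, `position`, `null_base`, `called_base`,
#'   `statistic`, `best_candidate`, `best_stat`, `loglik_null` and a
#'   `scores` list column of per-candidate tibbles (candidate, stat,
#'   loglik).
#' @export
call_positions <- function(x, model, statistic = c("orllr", "llr"),
                           candidates = "most_similar", threshold = 0,
                           positions = NULL, params = orllr_params()) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(model, "xna_kmer_model"), is.list(x$levels))
  k <- model$k
  out <- list()
  for (ref in unique(x$reference_seq)) {
    grp <- x[x$reference_seq == ref, ]
    pos_set <- positions %||% xna_positions_of(ref)
    if (length(pos_set) == 0) {
      warning("reference '", grp$reference_name[1],
              "' has no XNA position to test", call. = FALSE)
      next
    }
    lv <- do.call(rbind, grp$levels)
    for (pos in pos_set) {
      null_base <- substr(ref, pos, pos)
      cand <- resolve_candidates(candidates, null_base, model)
      if (length(cand) == 0) {
        warning("no candidate differs from the null base at position ", pos,
                call. = FALSE)
        next
      }
      d0 <- decompose_heptamer(ref, pos, k)
      starts <- d0$start
      obs <- lv[, starts, drop = FALSE]
      mu0 <- model_mu(model, d0$kmer)
      sig <- model_sigma(model, d0$kmer)
      ll0 <- log10_lik_rows(obs, mu0, sig)
      stat_mat <- matrix(NA_real_, nrow(grp), length(cand),
                         dimnames = list(NULL, cand))
      lik_mat <- stat_mat
      for (ci in seq_along(cand)) {
        kc <- decompose_heptamer(replace_base(ref, pos, cand[ci]), pos, k)$kmer
        muc <- model_mu(model, kc)
        llc <- log10_lik_rows(obs, muc, sig)
        lik_mat[, ci] <- llc
        terms <- sweep_llr_terms(obs, muc, mu0, sig)
        if (statistic == "orllr") {
          for (j in seq_len(k)) {
            terms[, j] <- orllr_transform(terms[, j], obs[, j],
                                          muc[j], mu0[j], sig[j], params)
          }
        }
        stat_mat[, ci] <- rowSums(terms)
      }
      best_idx <- apply(stat_mat, 1, which.max)
      best_stat <- stat_mat[cbind(seq_len(nrow(grp)), best_idx)]
      called <- ifelse(best_stat > threshold, cand[best_idx], null_base)
      out[[length(out) + 1]] <- tibble::tibble(
        read_id = grp$read_id,
        reference_name = grp$reference_name,
        position = pos,
        null_base = null_base,
        called_base = called,
        statistic = statistic,
        best_candidate = cand[best_idx],
        best_stat = best_stat,
        loglik_null = ll0,
        scores = lapply(seq_len(nrow(grp)), function(r) {
          tibble::tibble(candidate = cand, stat = unname(stat_mat[r, ]),
                         loglik = unname(lik_mat[r, ]))
        })
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("xna_calls", class(res)))
  res
}

xna_positions_of <- function(seq) {
  which(!strsplit(seq, "", fixed = TRUE)[[1]] %in% STANDARD_BASES)
}

resolve_candidates <- function(candidates, null_base, model) {
  if (length(candidates) == 1 &&
      candidates %in% c("most_similar", "standard", "all")) {
    cand <- switch(candidates,
      most_similar = unname(CANONICAL_SUBSTITUTION[null_base]),
      standard = STANDARD_BASES,
      all = {
        letters_in_model <- unique(unlist(strsplit(model$entries$kmer, "",
                                                   fixed = TRUE)))
        intersect(xna_collation(), letters_in_model)
      }
    )
  } else {
    cand <- candidates
  }
  cand <- setdiff(cand, null_base)
  sort_letters(cand)
}

sort_letters <- function(letters_vec) {
  letters_vec[order(match(letters_vec, xna_collation()))]
}

# rowSums of log10 normal densities for an n x k level matrix.
log10_lik_rows <- function(obs, mu, sigma) {
  total <- 0
  for (j in seq_len(ncol(obs))) {
    total <- total + level_log10_pdf(obs[, j], mu[j], sigma[j])
  }
  total
}

# n x k matrix of per-kmer LLR terms (candidate vs null).
sweep_llr_terms <- function(obs, mu_i, mu_j, sigma) {
  terms <- obs
  for (j in seq_len(ncol(obs))) {
    terms[, j] <- level_log10_pdf(obs[, j], mu_i[j], sigma[j]) -
      level_log10_pdf(obs[, j], mu_j[j], sigma[j])
  }
  terms
}

#' Consensus call by majority vote
#'
#' Collapses per-read calls to one consensus call per reference position.
#' Groups with fewer than `min_reads` reads yield a no-call (`NA` called
#' base, reason `"min_reads"`); exact vote ties also yield a no-call
#' (reason `"tie"`).
#'
#' @param calls An `xna_calls` tibble from [call_positions()].
#' @param min_reads Minimum reads required for a consensus call
#'   (default 10).
#' @return A tibble with one row per (reference_name, position):
#'   `null_base`, `called_base`, `n_reads`, `n_votes` (for the winner),
#'   `vote_frac` and `no_call_reason`.
#' @export
consensus_call <- function(calls, min_reads = 10) {
  calls |>
    dplyr::group_by(.data$reference_name, .data$position, .data$null_base) |>
    dplyr::group_modify(function(g, key) {
      tab <- sort(table(g$called_base), decreasing = TRUE)
      n <- nrow(g)
      if (n < min_reads) {
        return(tibble::tibble(called_base = NA_character_, n_reads = n,
                              n_votes = NA_integer_, vote_frac = NA_real_,
                              no_call_reason = "min_reads"))
      }
      if (length(tab) > 1 && tab[1] == tab[2]) {
        return(tibble::tibble(called_base = NA_character_, n_reads = n,
                              n_votes = as.integer(tab[1]),
                              vote_frac = as.integer(tab[1]) / n,
                              no_call_reason = "tie"))
      }
      tibble::tibble(called_base = names(tab)[1], n_reads = n,
                     n_votes = as.integer(tab[1]),
                     vote_frac = as.integer(tab[1]) / n,
                     no_call_reason = NA_character_)
    }) |>
    dplyr::ungroup()
}
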