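# Shared fixtures: all built in code, deterministic under fixed seeds.

# Tiny model with hand-set means: the P-containing kmers of the heptamer
# AGTPCGT and their G-substituted counterparts separated by a constant
# delta, everything else irrelevant. sigma fixed at 0.4.
fixed_delta_model <- function(delta = 0.2, sigma = 0.4) {
  hep_p <- "AGTPCGT"
  hep_g <- "AGTGCGT"
  kmers_p <- decompose_heptamer(hep_p, 4)$kmer
  kmers_g <- decompose_heptamer(hep_g, 4)$kmer
  mu_g <- c(-0.5, 0.3, 1.1, -1.2)
  entries <- tibble::tibble(
    kmer = c(kmers_p, kmers_g),
    mu = c(mu_g + delta, mu_g)
  )
  entries <- dplyr::mutate(entries, mean = mu, median = mu, std = sigma,
                           min = mu, max = mu, iqr = 0, coverage = 0L)
  xenocall:::new_kmer_model(k = 4, entries = entries, sigma_policy = "global")
}

# Random sequence over an alphabet, for property-style tests.
random_seq <- function(n, letters_set = c("A", "C", "G", "T")) {
  paste(sample(letters_set, n, replace = TRUE), collapse = "")
}

# A small level table written by hand.
tiny_level_table <- function() {
  tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    reference_name = c("ref1", "ref1", "ref2"),
    reference_seq = c("AGTPCGT", "AGTPCGT", "AATPGCA"),
    levels = list(c(0, 1, 2, 3, 4, 5, 6),
                  c(2, 3, 4, 5, 6, 7, 8),
                  c(1, 1, 1, 1, 1, 1, 1)),
    q_score = c(12, 8.9, 9.0),
    match_score = c(1, 1, 3.1)
  )
}
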