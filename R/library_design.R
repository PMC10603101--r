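# Design of barcoded hairpin oligo libraries and the ground-truth
# reference sets (including ligation side products) that kmer-model
# building depends on.
#
# Scaffold and barcode sequences here are synthetic placeholders generated
# under a seed: library correctness is driven by counts, barcode
# decodability and kmer coverage, not by particular bases.

# Simple oligo acceptability screen standing in for an interactive
# secondary-structure check: reject homopolymers longer than
# max_homopolymer and any inverted repeat (substring whose reverse
# complement also occurs) of length >= max_inverted_repeat.
passes_oligo_filter <- function(seq, max_homopolymer = 4,
                                max_inverted_repeat = 8) {
  if (grepl(paste0("([ACGT])\\1{", max_homopolymer, ",}"), seq)) return(FALSE)
  n <- nchar(seq)
  w <- max_inverted_repeat
  if (n >= 2 * w) {
    subs <- substring(seq, 1:(n - w + 1), w:n)
    rcs <- reverse_complement(subs)
    for (i in seq_along(subs)) {
      hit <- gregexpr(rcs[i], seq, fixed = TRUE)[[1]]
      if (any(hit > 0 & hit != i)) return(FALSE)
    }
  }
  TRUE
}

# n unique random canonical oligos of the given length passing the filter.
random_oligos <- function(n, len, seed) {
  set.seed(seed)
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    cand <- paste(sample(STANDARD_BASES, len, replace = TRUE), collapse = "")
    if (!cand %in% out && passes_oligo_filter(cand)) out <- c(out, cand)
    tries <- tries + 1
    if (tries > 1000 * n) stop("barcode generation failed", call. = FALSE)
  }
  out
}

all_triplets <- function() {
  g <- expand.grid(rep(list(STANDARD_BASES), 3), stringsAsFactors = FALSE)
  sort(paste0(g[[1]], g[[2]], g[[3]]))
}

new_hairpin_pool <- function(pool_name, pool_barcode, triplet_barcodes,
                             terminal_triplets, scaffold) {
  if (anyDuplicated(triplet_barcodes) || anyDuplicated(terminal_triplets)) {
    stop("triplet barcodes and terminal triplets must be unique within a pool",
         call. = FALSE)
  }
  tibble::tibble(
    pool = pool_name,
    name = paste0(pool_name, "_", terminal_triplets),
    pool_barcode = pool_barcode,
    triplet_barcode = triplet_barcodes,
    terminal_triplet = terminal_triplets,
    sequence = paste0(pool_barcode, scaffold, triplet_barcodes,
                      terminal_triplets)
  )
}

# Joined read-through sequence for a ligation of two hairpins: the tailed
# base x sits between the left hairpin and the reverse complement of the
# right one, so the heptamer context is terminal_triplet(left) + x +
# revcomp(terminal 3 bases of right).
join_product <- function(seq_left, inserted, seq_right) {
  paste0(seq_left, inserted, reverse_complement(seq_right))
}

#' Design a full-coverage heptamer-context hairpin library
#'
#' Builds the two barcoded hairpin pools whose pairwise ligation around one
#' XNA base pair produces every heptamer context `NNN-x-NNN`: each pool
#' enumerates all 64 terminal triplets (each linked 1:1 to a unique 24-nt
#' triplet barcode and sharing an 8-nt pool barcode), and joining every
#' pool-1 member to every reverse-complemented pool-2 member yields
#' 64 x 64 = 4096 target sequences with the XNA at the junction. The joined
#' set covers all 512 XNA-containing 4-mers of the base pair across the
#' two strands.
#'
#' @param xna_letter The tailed XNA letter (its pairing partner sits on the
#'   opposite strand).
#' @param scaffold Canonical spacer sequence inside each hairpin (no XNA
#'   letters allowed).
#' @param pool_barcodes Two distinct 8-nt pool barcodes; synthesized from
#'   `seed` when `NULL`.
#' @param seed Seed for barcode generation.
#' @return An object of class `xna_library`: list with `pools` (tibble of
#'   128 hairpins), `targets` (tibble of 4096 joined sequences with
#'   `xna_position`), `xna_letter` and `partner`.
#' @export
design_nnn_library <- function(xna_letter, scaffold = "CAGTCCATTGACGTCAAT",
                               pool_barcodes = NULL, seed = 101) {
  stopifnot(xna_letter %in% setdiff(names(XNA_PAIRS), STANDARD_BASES))
  assert_valid_sequence(scaffold, xna_alphabet(0))
  if (is.null(pool_barcodes)) pool_barcodes <- random_oligos(2, 8, seed)
  if (anyDuplicated(pool_barcodes)) {
    stop("pool barcodes must be distinct", call. = FALSE)
  }
  triplets <- all_triplets()
  bcs <- random_oligos(128, 24, seed + 1)
  p1 <- new_hairpin_pool("pool1", pool_barcodes[1], bcs[1:64], triplets,
                         scaffold)
  p2 <- new_hairpin_pool("pool2", pool_barcodes[2], bcs[65:128], triplets,
                         scaffold)
  pools <- dplyr::bind_rows(p1, p2)
  grid <- tidyr::expand_grid(i = seq_len(64), j = seq_len(64))
  targets <- tibble::tibble(
    name = paste0(p1$terminal_triplet[grid$i], xna_letter,
                  p2$terminal_triplet[grid$j]),
    sequence = join_product(p1$sequence[grid$i], xna_letter,
                            p2$sequence[grid$j]),
    xna_position = nchar(p1$sequence[1]) + 1L
  )
  structure(list(pools = pools, targets = targets, xna_letter = xna_letter,
                 partner = unname(XNA_PAIRS[xna_letter])),
            class = "xna_library")
}

#' @export
print.xna_library <- function(x, ...) {
  cat("<xna_library>", x$xna_letter, ":", x$partner, "|",
      nrow(x$pools), "hairpins |", nrow(x$targets), "joined targets\n")
  invisible(x)
}

#' Design a randomized validation library
#'
#' Two hairpin pools with uniform-random variable regions; joining them
#' around one XNA base pair yields `n_per_pool^2` products (100 by
#' default), each containing a single XNA in a context unseen during model
#' building.
#'
#' @param xna_letter The inserted XNA letter.
#' @param n_per_pool Hairpins per pool (default 10).
#' @param variable_len Length of the uniform-random variable region
#'   adjacent to the junction (default 20).
#' @param seed Seed; the same seed reproduces the identical library.
#' @return An `xna_library` (pools of `n_per_pool` hairpins each;
#'   `n_per_pool^2` joined targets).
#' @export
design_validation_library <- function(xna_letter, n_per_pool = 10,
                                      variable_len = 20, seed = 202) {
  stopifnot(n_per_pool >= 1, variable_len >= 3)
  pool_barcodes <- random_oligos(2, 8, seed)
  set.seed(seed + 1)
  var_regions <- replicate(2 * n_per_pool, paste(
    sample(STANDARD_BASES, variable_len, replace = TRUE), collapse = ""))
  mk_pool <- function(pool_name, pb, regions) {
    tibble::tibble(
      pool = pool_name,
      name = paste0(pool_name, "_v", seq_along(regions)),
      pool_barcode = pb,
      triplet_barcode = NA_character_,
      terminal_triplet = substring(regions, variable_len - 2, variable_len),
      sequence = paste0(pb, regions)
    )
  }
  p1 <- mk_pool("pool1", pool_barcodes[1], var_regions[seq_len(n_per_pool)])
  p2 <- mk_pool("pool2", pool_barcodes[2],
                var_regions[n_per_pool + seq_len(n_per_pool)])
  grid <- tidyr::expand_grid(i = seq_len(n_per_pool), j = seq_len(n_per_pool))
  targets <- tibble::tibble(
    name = paste0("val_", grid$i, "_", grid$j),
    sequence = join_product(p1$sequence[grid$i], xna_letter,
                            p2$sequence[grid$j]),
    xna_position = nchar(p1$sequence[1]) + 1L
  )
  structure(list(pools = dplyr::bind_rows(p1, p2), targets = targets,
                 xna_letter = xna_letter,
                 partner = unname(XNA_PAIRS[xna_letter])),
            class = "xna_library")
}

#' Enumerate all ligation products as an alignment reference set
#'
#' Lists every sequence a ligation reaction between two tailed hairpin
#' pools can plausibly produce, for use as a ground-truth alignment
#' reference: the desired hetero-ligations around the XNA pair, mismatch
#' homo-ligations (both pools self-ligated via the tailed base), blunt-end
#' ligations with no inserted base (a gap), and N-1 pyrophosphorolysis
#' products lacking one terminal base on either joining partner.
#'
#' @param pool_a,pool_b Hairpin pool tibbles (columns `name`, `sequence`),
#'   e.g. the two pools of an [design_nnn_library()] object.
#' @param xna_letter The base tailed onto pool A; its partner is tailed
#'   onto pool B.
#' @return A tibble of class `xna_reference_set` with columns `name`,
#'   `sequence`, `provenance` (one of `desired`, `homo_mismatch`,
#'   `blunt_gap`, `pyrophosphorolysis`) and `xna_position` (`NA` for
#'   products without an inserted base). Duplicate sequences are removed
#'   (first occurrence kept).
#' @export
enumerate_ligation_products <- function(pool_a, pool_b, xna_letter) {
  x <- xna_letter
  xp <- unname(XNA_PAIRS[x])
  cross <- function(pa, pb) {
    tidyr::expand_grid(i = seq_len(nrow(pa)), j = seq_len(nrow(pb)))
  }
  build <- function(pa, pb, inserted, tag, prefix) {
    g <- cross(pa, pb)
    left <- pa$sequence[g$i]
    right <- pb$sequence[g$j]
    tibble::tibble(
      name = paste0(prefix, "_", pa$name[g$i], "_", pb$name[g$j]),
      sequence = join_product(left, inserted, right),
      provenance = tag,
      xna_position = if (nzchar(inserted)) nchar(left) + 1L else NA_integer_
    )
  }
  desired <- build(pool_a, pool_b, x, "desired", "AB")
  homo <- dplyr::bind_rows(
    build(pool_a, pool_a, x, "homo_mismatch", "AA"),
    build(pool_b, pool_b, xp, "homo_mismatch", "BB")
  )
  blunt <- dplyr::bind_rows(
    build(pool_a, pool_b, "", "blunt_gap", "ABgap"),
    build(pool_a, pool_a, "", "blunt_gap", "AAgap"),
    build(pool_b, pool_b, "", "blunt_gap", "BBgap")
  )
  g <- cross(pool_a, pool_b)
  left <- pool_a$sequence[g$i]
  right <- pool_b$sequence[g$j]
  nm1 <- dplyr::bind_rows(
    tibble::tibble(   # left partner lost its terminal base
      name = paste0("ABm1L_", pool_a$name[g$i], "_", pool_b$name[g$j]),
      sequence = join_product(substring(left, 1, nchar(left) - 1), x, right),
      provenance = "pyrophosphorolysis",
      xna_position = nchar(left)
    ),
    tibble::tibble(   # right partner lost its terminal base
      name = paste0("ABm1R_", pool_a$name[g$i], "_", pool_b$name[g$j]),
      sequence = join_product(left, x, substring(right, 1, nchar(right) - 1)),
      provenance = "pyrophosphorolysis",
      xna_position = nchar(left) + 1L
    )
  )
  out <- dplyr::bind_rows(desired, homo, blunt, nm1)
  out <- dplyr::distinct(out, .data$sequence, .keep_all = TRUE)
  if (anyDuplicated(out$name)) stop("duplicate record names", call. = FALSE)
  class(out) <- unique(c("xna_reference_set", class(out)))
  out
}

#' Distinct XNA-containing kmers covered by a target set
#'
#' Decomposes each target sequence at its XNA position (and, optionally, on
#' the reverse-complement strand, where the partner letter sits) and counts
#' the distinct kmers containing a non-canonical letter. The full-coverage
#' heptamer library covers all 512 4-mers of its XNA pair.
#'
#' @param targets Tibble with `sequence` and `xna_position` columns (e.g.
#'   `design_nnn_library(...)$targets`).
#' @param k Kmer length (default 4).
#' @param both_strands Include the reverse-complement strand (default
#'   `TRUE`).
#' @return Character vector of distinct XNA-containing kmers.
#' @export
xna_kmer_coverage <- function(targets, k = 4, both_strands = TRUE) {
  kmers <- character(0)
  for (i in seq_len(nrow(targets))) {
    s <- targets$sequence[i]
    p <- targets$xna_position[i]
    if (is.na(p)) next
    kmers <- c(kmers, decompose_heptamer(s, p, k)$kmer)
    if (both_strands) {
      rc <- reverse_complement(s)
      kmers <- c(kmers, decompose_heptamer(rc, nchar(s) - p + 1, k)$kmer)
    }
  }
  sort_kmers(unique(kmers))
}

#' Write a reference set as extended FASTA plus a CSV manifest
#'
#' @param refset An `xna_reference_set` (or any tibble with `name`,
#'   `sequence`, `provenance`).
#' @param fasta_path Output FASTA path; pass `canonical = TRUE` to write
#'   canonical-substituted sequences (for aligners that only accept ACGT).
#' @param manifest_path Output CSV manifest path (name, provenance,
#'   xna_position).
#' @param canonical Substitute XNA letters before writing.
#' @return `fasta_path`, invisibly.
#' @export
write_reference_set <- function(refset, fasta_path, manifest_path = NULL,
                                canonical = FALSE) {
  seqs <- refset$sequence
  if (canonical) seqs <- substitute_canonical(seqs)$canonical
  write_xna_fasta(tibble::tibble(name = refset$name, sequence = seqs),
                  fasta_path)
  if (!is.null(manifest_path)) {
    readr::write_csv(dplyr::select(tibble::as_tibble(refset), -"sequence"),
                     manifest_path, progress = FALSE)
  }
  invisible(fasta_path)
}
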