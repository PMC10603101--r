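# Expanded 12-letter DNA alphabet: standard bases plus the orthogonal
# xenonucleotide (XNA) pairs B:S, P:Z, X:K and J:V.

# Pairing of the six orthogonal base pairs; each letter occurs exactly once.
XNA_PAIRS <- c(A = "T", T = "A", G = "C", C = "G",
               B = "S", S = "B", P = "Z", Z = "P",
               X = "K", K = "X", J = "V", V = "J")

# Chemical variants sharing one sequence letter. The sequence alphabet is
# single-character; the variant tag selects which kmer model applies.
XNA_VARIANTS <- list(S = c("Sn", "Sc"), X = "Xt", K = "Kn")

# Canonical substitute per XNA letter: the standard base whose kmer levels
# are closest, used when an aligner or basecaller needs a 4-letter sequence.
CANONICAL_SUBSTITUTION <- c(A = "A", T = "T", G = "G", C = "C",
                            B = "A", S = "A", P = "G", Z = "C",
                            X = "A", K = "G", J = "C", V = "G")

STANDARD_BASES <- c("A", "C", "G", "T")

# Deterministic collation: A, C, G, T then XNA letters alphabetically.
xna_collation <- function(letters_used = names(XNA_PAIRS)) {
  xna <- sort(setdiff(letters_used, STANDARD_BASES))
  c(STANDARD_BASES, xna)
}

#' Expanded DNA alphabet
#'
#' Builds the alphabet table for supernumerary DNA: the four standard bases
#' plus any subset of the orthogonal xenonucleotide pairs B:S, P:Z, X:K and
#' J:V. Every letter belongs to exactly one base pair, so the alphabet size
#' is always even (4, 6, 8, 10 or 12 letters).
#'
#' @param n_xna_pairs Number of XNA base pairs to include (0--4). Pairs are
#'   added in the order B:S, P:Z, X:K, J:V.
#' @return A tibble of class `xna_alphabet` with columns `letter`, `partner`
#'   (the pairing letter), `is_standard`, `canonical` (the canonical
#'   substitute) and `variants` (list column of chemical variant tags, e.g.
#'   `"Sn"`, `"Sc"` for S).
#' @examples
#' xna_alphabet()          # full 12-letter alphabet
#' xna_alphabet(1)         # 6-letter alphabet A,T,G,C,B,S
#' @export
xna_alphabet <- function(n_xna_pairs = 4) {
  stopifnot(n_xna_pairs %in% 0:4)
  pair_order <- c("B", "P", "X", "J")
  xna <- character(0)
  for (p in pair_order[seq_len(n_xna_pairs)]) xna <- c(xna, p, XNA_PAIRS[[p]])
  letters_used <- c(STANDARD_BASES, sort(xna))
  out <- tibble::tibble(
    letter      = letters_used,
    partner     = unname(XNA_PAIRS[letters_used]),
    is_standard = letters_used %in% STANDARD_BASES,
    canonical   = unname(CANONICAL_SUBSTITUTION[letters_used]),
    variants    = lapply(letters_used, function(l) {
      if (l %in% names(XNA_VARIANTS)) XNA_VARIANTS[[l]] else l
    })
  )
  class(out) <- c("xna_alphabet", class(out))
  out
}

assert_valid_sequence <- function(seq, alphabet = xna_alphabet()) {
  chars <- unique(unlist(strsplit(seq, "", fixed = TRUE)))
  bad <- setdiff(chars, alphabet$letter)
  if (length(bad) > 0) {
    stop("sequence contains letters outside the active alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement over the expanded alphabet
#'
#' Base-pairs a sequence (A:T, G:C, B:S, P:Z, X:K, J:V) and returns the
#' opposite strand read 5' to 3'. Complementation is an involution:
#' `reverse_complement(reverse_complement(s))` is `s`.
#'
#' @param seq Character vector of sequences over the alphabet.
#' @param alphabet An [xna_alphabet()] used for validation and pairing.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ATGC")   # "GCAT"
#' reverse_complement("AGTBCCT")
#' @export
reverse_complement <- function(seq, alphabet = xna_alphabet()) {
  assert_valid_sequence(seq, alphabet)
  comp <- stats::setNames(alphabet$partner, alphabet$letter)
  vapply(strsplit(seq, "", fixed = TRUE), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, character(1))
}

#' Substitute XNA letters with their canonical stand-ins
#'
#' Replaces every xenonucleotide letter by the standard base whose observed
#' kmer levels it most resembles (B, S, X to A; P, K, V to G; Z, J to C),
#' producing a 4-letter sequence usable by standard aligners and
#' basecallers, and records where the substitutions happened. Length is
#' always preserved and the operation is idempotent.
#'
#' @param seq Character vector of sequences over the expanded alphabet.
#' @param map Named character vector giving the substitute for every letter;
#'   override to experiment with alternative substitution schemes.
#' @return A tibble with one row per input sequence: `sequence` (input),
#'   `canonical` (substituted sequence) and `xna_positions` (list column of
#'   1-based positions that were substituted, ascending).
#' @examples
#' substitute_canonical("AGTBCCT")
#' @export
substitute_canonical <- function(seq, map = CANONICAL_SUBSTITUTION) {
  assert_valid_sequence(seq, xna_alphabet())
  split <- strsplit(seq, "", fixed = TRUE)
  tibble::tibble(
    sequence  = seq,
    canonical = vapply(split, function(ch) paste(unname(map[ch]), collapse = ""),
                       character(1)),
    xna_positions = lapply(split, function(ch) which(unname(map[ch]) != ch))
  )
}

#' Enumerate kmers containing exactly one xenonucleotide
#'
#' Lists every length-`k` kmer holding exactly one XNA letter, with the
#' remaining positions drawn from A, C, G, T. Per XNA letter there are
#' `k * 4^(k-1)` such kmers (256 at k = 4), so one XNA base pair contributes
#' 512 4-mers and nine measured XNA bases contribute 2304.
#'
#' @param k Kmer length (default 4).
#' @param xna_letters Character vector of XNA letters, or variant tags such
#'   as `"Sn"` / `"Sc"`: a tag's first character is the sequence letter, and
#'   distinct tags are enumerated separately (each variant has its own kmer
#'   model even though the sequence letter is shared).
#' @return Character vector of single-letter kmers, named by the XNA letter
#'   or variant tag they belong to; deduplicated within each tag and in
#'   deterministic order (A < C < G < T < XNA letters alphabetically,
#'   position by position).
#' @examples
#' length(enumerate_xna_kmers(4, "P"))        # 256
#' length(enumerate_xna_kmers(4, c("P", "Z"))) # 512
#' @export
enumerate_xna_kmers <- function(k = 4, xna_letters) {
  if (k <= 0) stop("k must be a positive integer", call. = FALSE)
  stopifnot(length(xna_letters) > 0)
  base_letter <- substr(xna_letters, 1, 1)
  if (any(base_letter %in% STANDARD_BASES)) {
    stop("xna_letters must be disjoint from A, C, G, T", call. = FALSE)
  }
  fills <- expand.grid(rep(list(STANDARD_BASES), k - 1),
                       stringsAsFactors = FALSE)
  out <- character(0)
  for (tag in unique(xna_letters)) {
    x <- substr(tag, 1, 1)
    kmers <- character(0)
    for (pos in seq_len(k)) {
      if (k == 1) {
        kmers <- c(kmers, x)
      } else {
        left  <- if (pos > 1) do.call(paste0, fills[seq_len(pos - 1)]) else ""
        right <- if (pos < k) do.call(paste0, fills[seq(pos, k - 1)]) else ""
        kmers <- c(kmers, paste0(left, x, right))
      }
    }
    kmers <- sort_kmers(unique(kmers))
    out <- c(out, stats::setNames(kmers, rep(tag, length(kmers))))
  }
  out
}

# Sort kmers by the deterministic collation (ACGT then XNA alphabetically).
# Variant tags are single letters at the sequence level, so plain character
# ranking over the collation applies per position.
sort_kmers <- function(kmers) {
  if (length(kmers) == 0) return(kmers)
  coll <- xna_collation()
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1)
  mat <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  ranks <- apply(mat, 2, function(col) match(col, coll))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = k)
  kmers[do.call(order, as.data.frame(ranks))]
}

#' Information density of an alphabet
#'
#' Bits of information carried per base: `log2(size)`. Standard DNA encodes
#' 2 bits per base; the full 12-letter alphabet encodes about 3.58.
#'
#' @param alphabet_size Number of letters (>= 1).
#' @return Bits per base (double).
#' @export
bits_per_base <- function(alphabet_size) {
  stopifnot(all(alphabet_size >= 1))
  log2(alphabet_size)
}

#' Codon space of an expanded genetic code
#'
#' Counts the distinct codon-anticodon pairs available when up to
#' `max_xna_per_codon` xenonucleotide letters may appear in a codon, by
#' explicit enumeration of all 3-mers over the enlarged alphabet. With all
#' four XNA pairs and at most one XNA per codon this gives the 64 canonical
#' codons plus 96 additional codons per XNA pair, 448 in total.
#'
#' @param n_xna_pairs Number of XNA base pairs added to the code (0--4).
#' @param max_xna_per_codon Maximum number of XNA letters per codon
#'   (default 1; multi-XNA codons additionally require that all XNA letters
#'   in one codon come from a single pair, matching single-pair expansion
#'   schemes).
#' @return Integer count of codons.
#' @examples
#' codon_space_size(0)  # 64
#' codon_space_size(4)  # 448
#' @export
codon_space_size <- function(n_xna_pairs, max_xna_per_codon = 1) {
  stopifnot(n_xna_pairs %in% 0:4)
  ab <- xna_alphabet(n_xna_pairs)
  codons <- expand.grid(rep(list(ab$letter), 3), stringsAsFactors = FALSE)
  is_xna <- !as.matrix(codons) %in% STANDARD_BASES
  dim(is_xna) <- dim(codons)
  n_xna <- rowSums(is_xna)
  keep <- n_xna <= max_xna_per_codon
  if (max_xna_per_codon > 1) {
    pair_of <- function(l) ifelse(l %in% STANDARD_BASES, NA,
                                  pmin(l, XNA_PAIRS[l]))
    pairs_used <- apply(codons, 1, function(cd) {
      length(unique(stats::na.omit(pair_of(cd))))
    })
    keep <- keep & pairs_used <= 1
  }
  sum(keep)
}

#' Read extended-alphabet FASTA
#'
#' Parses FASTA records whose sequences may contain the XNA letters B, S, P,
#' Z, X, K, J, V in addition to A, C, G, T. A header token of the form
#' `variant=Sc` records which chemical variant an ambiguous letter denotes;
#' it is returned in the `variant` column.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) reject sequences containing letters
#'   outside the 12-letter alphabet.
#' @return A tibble with columns `name`, `sequence`, `variant` (NA when the
#'   header carries no variant token).
#' @export
read_xna_fasta <- function(path, strict = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0) {
    return(tibble::tibble(name = character(), sequence = character(),
                          variant = character()))
  }
  if (!hdr[1]) stop("not a FASTA file: first line is not a header", call. = FALSE)
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  # records with a header but no sequence lines become empty strings
  all_ids <- as.character(seq_along(headers))
  seqs <- stats::setNames(seqs[all_ids], NULL)
  seqs[is.na(seqs)] <- ""
  name <- sub("\\s.*$", "", headers)
  variant <- stringr::str_match(headers, "variant=([A-Za-z0-9]+)")[, 2]
  if (strict) assert_valid_sequence(seqs[nzchar(seqs)], xna_alphabet())
  tibble::tibble(name = name, sequence = seqs, variant = variant)
}

#' Write extended-alphabet FASTA
#'
#' @param x Tibble with columns `name` and `sequence`; an optional `variant`
#'   column is written as a `variant=` header token.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_xna_fasta <- function(x, path, width = 70) {
  stopifnot(all(c("name", "sequence") %in% names(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- paste0(">", x$name[i])
    if ("variant" %in% names(x) && !is.na(x$variant[i])) {
      hdr <- paste0(hdr, " variant=", x$variant[i])
    }
    writeLines(hdr, con)
    s <- x$sequence[i]
    if (nchar(s) > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    }
  }
  invisible(path)
}
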