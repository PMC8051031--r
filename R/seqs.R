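#' Reverse complement of DNA strings
#'
#' Plain character-vector reverse complement (A/C/G/T, case-insensitive;
#' other characters become N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  revcomp_cpp(as.character(x))
}

#' Canonical form of a kmer
#'
#' The canonical form is the lexicographically smaller of a kmer and its
#' reverse complement, which makes counting strand-agnostic.
#'
#' @param x character vector of kmers (A/C/G/T only).
#' @return character vector of canonical kmers.
#' @export
canonical <- function(x) {
  rc <- revcomp_cpp(as.character(x))
  ifelse(rc < x, rc, x)
}

#' Encode kmers as numeric codes
#'
#' Packs kmers (k <= 26) 2 bits per base into integers that are exactly
#' representable as doubles; the whole pipeline joins on these codes and
#' only decodes back to strings for output.
#'
#' @param x character vector of kmers, all the same length.
#' @param canonical encode the canonical form (default TRUE).
#' @return numeric vector of codes; NA for kmers with non-ACGT characters.
#' @export
encode_kmer <- function(x, canonical = TRUE) {
  encode_kmers_cpp(as.character(x), canonical)
}

#' Decode numeric kmer codes back to strings
#'
#' @param code numeric vector of codes from [encode_kmer()].
#' @param k kmer length used at encoding.
#' @return character vector of kmers.
#' @export
decode_kmer <- function(code, k) {
  decode_kmers_cpp(as.numeric(code), as.integer(k))
}

#' Random DNA sequence
#'
#' i.i.d. bases with a configurable GC fraction; draws from R's RNG so
#' `set.seed()` governs reproducibility.
#'
#' @param n sequence length in bp.
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
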