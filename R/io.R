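#' Read and write sequence files
#'
#' Thin wrappers over Biostrings for the package's interchange formats:
#' FASTA for genomes and long reads, FASTQ (constant Q30 placeholder
#' qualities) for short reads. Readers return plain named character
#' vectors; gzip input is handled by Biostrings.
#'
#' @param path file path.
#' @return `read_fasta()`/`read_fastq()`: named character vector of
#'   sequences; writers return `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences (or a data.table with
#'   `read_id` and `sequence`).
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_named_seqs(seqs)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  seqs <- as_named_seqs(seqs)
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("?", n), collapse = ""), character(1)))  # "?" = Q30 Sanger
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

as_named_seqs <- function(seqs) {
  if (is.data.frame(seqs)) {
    s <- seqs$sequence
    names(s) <- if ("read_id" %in% names(seqs)) seqs$read_id
                else sprintf("seq_%06d", seq_along(s))
    return(s)
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq_%06d", seq_along(seqs))
  seqs
}

#' Write the ground-truth kmer table as TSV
#'
#' Columns: `kmer`, `count_A`, `count_X`, `count_Y`, `count_mito`.
#'
#' @param genome a [build_genome()] result.
#' @param path output path.
#' @export
write_truth_tsv <- function(genome, path) {
  out <- copy(genome$truth)
  out[, kmer := decode_kmer(code, genome$k)]
  fwrite(out[, .(kmer, count_A, count_X, count_Y, count_mito)], path,
         sep = "\t")
  invisible(path)
}

#' Write the merged census as sorted TSV
#'
#' Columns: `kmer`, `count_m`, `count_f`, `sum`, `cpm_m`, `cpm_f`, `cq`,
#' `class`; rows sorted by kmer.
#'
#' @param census [merge_census()] output.
#' @param path output path.
#' @param k kmer length for decoding.
#' @export
write_census_tsv <- function(census, path, k = 25L) {
  out <- census[, .(kmer = decode_kmer(code, k), count_m, count_f, sum,
                    cpm_m, cpm_f, cq, class = kmer_class)]
  setorder(out, kmer)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
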