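#' Per-gene chromosome quotient
#'
#' Computes the CQ of each gene from sexed exact-match alignment counts
#' (the all-alignments, no-mismatch convention). Genes with zero reads in
#' both sexes have undefined CQ (`NA`) and are excluded from contig
#' medians.
#'
#' @param gene_counts data.table with `gene_id`, `contig`, `reads_m`,
#'   `reads_f`.
#' @param total_m,total_f library sizes (total read counts per sex).
#' @return the input with a `cq` column.
#' @export
gene_cq <- function(gene_counts, total_m, total_f) {
  gc <- data.table::as.data.table(gene_counts)
  stopifnot(all(c("gene_id", "contig", "reads_m", "reads_f") %in% names(gc)),
            all(gc$reads_m >= 0), all(gc$reads_f >= 0))
  gc[, cq := compute_cq(reads_m, reads_f, total_m, total_f)]
  gc[]
}

#' Exact sexed read counts over gene sequences
#'
#' Counts, per gene, every full-length exact placement (both strands) of
#' each read within the gene sequence — the synthetic stand-in for
#' all-alignment zero-mismatch short-read mapping against a gene set.
#'
#' @param reads character vector of read sequences (or a data.table with a
#'   `sequence` column).
#' @param gene_seqs named character vector of gene sequences.
#' @return numeric vector of alignment counts, one per gene.
#' @export
count_gene_reads <- function(reads, gene_seqs) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  setNames(exact_read_hits_cpp(as.character(seqs),
                               as.character(gene_seqs)),
           names(gene_seqs))
}

#' Contig sex assignment by median gene CQ
#'
#' A contig's CQ is the median CQ of its member genes; contigs with fewer
#' than `min_genes` genes (default 10, the published floor) are left
#' `unassigned`. Classes reuse the census CQ thresholds.
#'
#' @param gene_table [gene_cq()] output.
#' @param min_genes minimum genes per contig for a call.
#' @param thresholds a [cq_class_thresholds()].
#' @return data.table with `contig`, `n_genes`, `median_cq`, `class`
#'   (`"X"`, `"A"`, `"Y"`, `"ambiguous"` or `"unassigned"`).
#' @export
contig_cq <- function(gene_table, min_genes = 10L,
                      thresholds = cq_class_thresholds()) {
  gt <- data.table::as.data.table(gene_table)[!is.na(cq)]
  out <- gt[, .(n_genes = .N, median_cq = median(cq)), by = contig]
  out[, class := classify_kmer(median_cq, thresholds)]
  out[n_genes < min_genes, class := "unassigned"]
  setorder(out, contig)
  out[]
}

#' Map kmers to an assembly by ungapped mismatch-tolerant scanning
#'
#' Reports every full-length ungapped placement of each kmer (both
#' strands) with at most `max_mm` substitutions — the role BLASTN plays
#' when short kmers are located in an assembly. Coordinates are 0-based,
#' half-open.
#'
#' @param kmers character vector of kmer sequences.
#' @param assembly named character vector of scaffold sequences.
#' @param max_mm maximum substitutions per placement (default 0).
#' @return data.table with `kmer`, `scaffold`, `start`, `end`, `strand`,
#'   `mismatches`.
#' @export
map_kmers_to_assembly <- function(kmers, assembly, max_mm = 0L) {
  stopifnot(max_mm >= 0, !is.null(names(assembly)))
  hits <- hamming_map_cpp(as.character(kmers), as.character(assembly),
                          as.integer(max_mm))
  data.table(kmer = as.character(kmers)[hits$pattern],
             scaffold = names(assembly)[hits$subject],
             start = hits$start,
             end = hits$start + nchar(as.character(kmers)[hits$pattern]),
             strand = hits$strand,
             mismatches = hits$mismatches)
}

#' Cluster kmer hits into repeat arrays
#'
#' Single-linkage clustering of one kmer's hits along each scaffold:
#' consecutive hits whose start-to-start gap is at most `max_gap` join the
#' same array. The median inter-hit spacing approximates the repeat-unit
#' length of a head-to-tail array carrying the kmer once per unit.
#'
#' @param hits [map_kmers_to_assembly()] output (one or more kmers).
#' @param max_gap maximum inter-hit gap within an array (default 20 kb).
#' @return data.table with `kmer`, `scaffold`, `array_id`, `span_start`,
#'   `span_end`, `span` (`span_end - span_start`), `n_hits`,
#'   `median_spacing` (`NA` for single-hit arrays).
#' @export
cluster_hits <- function(hits, max_gap = 20000L) {
  stopifnot(max_gap >= 0)
  h <- data.table::as.data.table(hits)
  if (!nrow(h))
    return(data.table(kmer = character(), scaffold = character(),
                      array_id = integer(), span_start = integer(),
                      span_end = integer(), span = integer(),
                      n_hits = integer(), median_spacing = numeric()))
  setorder(h, kmer, scaffold, start)
  h[, array_id := cumsum(c(1L, diff(start) > max_gap)),
    by = .(kmer, scaffold)]
  out <- h[, .(span_start = min(start), span_end = max(end),
               n_hits = .N,
               median_spacing = if (.N >= 2)
                 as.numeric(median(diff(sort(as.numeric(start)))))
                 else NA_real_),
           by = .(kmer, scaffold, array_id)]
  out[, span := span_end - span_start]
  data.table::setcolorder(out, c("kmer", "scaffold", "array_id",
                                 "span_start", "span_end", "span",
                                 "n_hits", "median_spacing"))
  out[]
}

#' Region-derived kmer specificity
#'
#' Censuses the canonical kmers of an assembly region, counts each kmer's
#' exact occurrences in the region, in the host scaffold and in the whole
#' assembly, and reports `specificity = scaffold_count / genome_count` —
#' the fraction of a kmer's assembly-wide copies that stay on the host
#' scaffold. A kmer confined to the region scores 1.
#'
#' @param assembly named character vector of scaffold sequences.
#' @param scaffold name of the host scaffold.
#' @param region_start,region_end 0-based half-open region coordinates.
#' @param k kmer length (default 25).
#' @return data.table with `code`, `kmer`, `region_count`,
#'   `scaffold_count`, `genome_count`, `specificity`, sorted by decreasing
#'   `region_count`.
#' @export
region_kmer_specificity <- function(assembly, scaffold, region_start,
                                    region_end, k = 25L) {
  stopifnot(scaffold %in% names(assembly),
            region_start >= 0,
            region_end <= nchar(assembly[[scaffold]]),
            region_start < region_end)
  region <- substr(assembly[[scaffold]], region_start + 1, region_end)
  if (nchar(region) < k)
    return(data.table(code = numeric(), kmer = character(),
                      region_count = numeric(), scaffold_count = numeric(),
                      genome_count = numeric(), specificity = numeric()))
  reg <- count_canonical_kmers_cpp(region, k)
  out <- data.table(code = reg$code, region_count = reg$count)
  scf <- count_canonical_kmers_cpp(assembly[[scaffold]], k)
  gen <- count_canonical_kmers_cpp(unname(as.character(assembly)), k)
  out <- merge(out, data.table(code = scf$code, scaffold_count = scf$count),
               by = "code", all.x = TRUE)
  out <- merge(out, data.table(code = gen$code, genome_count = gen$count),
               by = "code", all.x = TRUE)
  out[, kmer := decode_kmer(code, k)]
  out[, specificity := scaffold_count / genome_count]
  setorder(out, -region_count, kmer)
  data.table::setcolorder(out, c("code", "kmer", "region_count",
                                 "scaffold_count", "genome_count",
                                 "specificity"))
  out[]
}
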