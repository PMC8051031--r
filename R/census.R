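#' Census parameters
#'
#' Defaults follow the established X-shredder target discovery settings:
#' canonical 25-mers counted after trimming 5 bp from each read end, a raw
#' noise floor of 5 on the combined male+female count, and a combined
#' short-read abundance (`sum`) floor of 100 applied at candidacy.
#'
#' @param k kmer length (default 25; downstream PAM geometry assumes >= 24).
#' @param trimm5,trimm3 bases trimmed from the 5' and 3' read ends.
#' @param kmernoise minimum combined raw count for a kmer to be kept.
#' @param lsum minimum combined short-read abundance for candidacy
#'   (applied by [xsi_filter()], carried here so one object describes the
#'   census).
#' @return a `census_params` list.
#' @export
census_params <- function(k = 25L, trimm5 = 5L, trimm3 = 5L,
                          kmernoise = 5L, lsum = 100L) {
  stopifnot(k >= 1, k <= 26, trimm5 >= 0, trimm3 >= 0,
            kmernoise >= 0, lsum >= 0)
  structure(list(k = as.integer(k), trimm5 = as.integer(trimm5),
                 trimm3 = as.integer(trimm3),
                 kmernoise = as.integer(kmernoise), lsum = as.integer(lsum)),
            class = "census_params")
}

#' Trim read ends
#'
#' Removes `trimm5` leading and `trimm3` trailing bases; reads shorter than
#' the combined trim collapse to the empty string.
#'
#' @param sequence character vector of reads.
#' @param trimm5,trimm3 bases to remove from each end.
#' @return trimmed character vector.
#' @export
trim_read <- function(sequence, trimm5 = 5L, trimm3 = 5L) {
  stopifnot(trimm5 >= 0, trimm3 >= 0)
  n <- nchar(sequence)
  out <- substring(sequence, trimm5 + 1L, n - trimm3)
  out[n <= trimm5 + trimm3] <- ""
  out
}

#' Count canonical kmers in a read library
#'
#' Every window of length `k` in every trimmed read contributes one count
#' to its canonical kmer; windows containing a non-ACGT base are skipped
#' (and tallied). Totals obey
#' `valid + invalid = sum(max(0, trimmed_length - k + 1))`.
#'
#' @param reads character vector of read sequences, or a data.table with a
#'   `sequence` column (as produced by [simulate_short_reads()]).
#' @param params a [census_params()].
#' @return a `kmer_census`: list with `table` (data.table `code`, `count`),
#'   `total_valid`, `invalid_windows`, `n_reads` and the `params`.
#' @export
count_kmers <- function(reads, params = census_params()) {
  stopifnot(inherits(params, "census_params"))
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  res <- count_canonical_kmers_cpp(as.character(seqs), params$k,
                                   params$trimm5, params$trimm3)
  tab <- data.table(code = res$code, count = res$count)
  setkey(tab, code)
  structure(list(table = tab, total_valid = res$valid_windows,
                 invalid_windows = res$invalid_windows,
                 n_reads = length(seqs), params = params),
            class = "kmer_census")
}

#' Chromosome quotient
#'
#' CQ is the library-size-normalised ratio of female over male counts:
#' `(count_f / total_f) / (count_m / total_m)`. It sits near 2 for X-linked,
#' 1 for autosomal and 0 for Y-linked sequence in an XX/XY system. A zero
#' male count maps to `Inf` (ordered above every finite CQ, so such kmers
#' fall in the X-candidate band and are vetted later by XSI); a zero female
#' count maps to 0; zero in both is undefined (`NA`).
#'
#' @param count_m,count_f raw counts per library.
#' @param total_m,total_f library sizes (total valid kmer instances).
#' @return numeric CQ vector.
#' @export
compute_cq <- function(count_m, count_f, total_m, total_f) {
  stopifnot(total_m > 0, total_f > 0)
  cq <- (count_f / total_f) / (count_m / total_m)
  cq[count_m == 0 & count_f > 0] <- Inf
  cq[count_f == 0 & count_m > 0] <- 0
  cq[count_m == 0 & count_f == 0] <- NA_real_
  cq
}

#' CQ class thresholds
#'
#' Non-overlapping bands over CQ: Y-like at the bottom, autosomal around 1,
#' X-candidate at the top (the `Inf` sentinel included), ambiguous between
#' bands. The discovery pipeline the thresholds come from does not publish
#' its exact boundaries, so they are parameters with conventional defaults.
#'
#' @param y_max upper CQ bound of the Y-like class.
#' @param a_min,a_max CQ bounds of the autosomal class.
#' @param x_min lower CQ bound of the X-candidate class.
#' @return a `cq_class_thresholds` list.
#' @export
cq_class_thresholds <- function(y_max = 0.2, a_min = 0.5, a_max = 1.5,
                                x_min = 1.7) {
  if (!(y_max < a_min && a_min <= a_max && a_max < x_min))
    stop("class thresholds overlap: need y_max < a_min <= a_max < x_min")
  structure(list(y_max = y_max, a_min = a_min, a_max = a_max, x_min = x_min),
            class = "cq_class_thresholds")
}

#' Classify kmers by chromosome quotient
#'
#' @param cq numeric CQ vector (may contain `Inf` and `NA`).
#' @param thresholds a [cq_class_thresholds()].
#' @return character vector in `{"X", "A", "Y", "ambiguous"}` (`NA` CQ
#'   stays `NA`).
#' @export
classify_kmer <- function(cq, thresholds = cq_class_thresholds()) {
  stopifnot(inherits(thresholds, "cq_class_thresholds"))
  out <- rep(NA_character_, length(cq))
  ok <- !is.na(cq)
  out[ok] <- "ambiguous"
  out[ok & cq <= thresholds$y_max] <- "Y"
  out[ok & cq >= thresholds$a_min & cq <= thresholds$a_max] <- "A"
  out[ok & cq >= thresholds$x_min] <- "X"
  out
}

#' Merge male and female censuses into the kmer table
#'
#' Takes the union of kmers from both libraries, drops records whose
#' combined raw count (`sum`) falls below the noise floor, computes
#' counts-per-million against each library's total valid kmer instances,
#' the chromosome quotient, and the CQ class.
#'
#' The noise floor applies to the combined count rather than per library:
#' a genuinely Y-specific kmer has a female count of 0 and would otherwise
#' be erased.
#'
#' @param census_m,census_f [count_kmers()] results for the male and female
#'   libraries (identical `k` and trims required).
#' @param params a [census_params()] supplying `kmernoise`.
#' @param thresholds a [cq_class_thresholds()].
#' @return data.table keyed by `code` with `count_m`, `count_f`, `sum`,
#'   `cpm_m`, `cpm_f`, `cq`, `kmer_class`, plus attributes `total_m`,
#'   `total_f`, `dropped` (records removed by the noise floor).
#' @export
merge_census <- function(census_m, census_f, params = census_params(),
                         thresholds = cq_class_thresholds()) {
  stopifnot(inherits(census_m, "kmer_census"),
            inherits(census_f, "kmer_census"))
  if (census_m$params$k != census_f$params$k ||
      census_m$params$trimm5 != census_f$params$trimm5 ||
      census_m$params$trimm3 != census_f$params$trimm3)
    stop("male and female censuses were produced with different k or trims")
  if (census_m$params$k != params$k)
    stop("census k does not match params k")
  tab <- merge(census_m$table, census_f$table, by = "code", all = TRUE,
               suffixes = c("_m", "_f"))
  tab[is.na(count_m), count_m := 0]
  tab[is.na(count_f), count_f := 0]
  tab[, sum := count_m + count_f]
  dropped <- tab[sum < params$kmernoise, .N]
  tab <- tab[sum >= params$kmernoise]
  total_m <- census_m$total_valid
  total_f <- census_f$total_valid
  tab[, cpm_m := count_m / total_m * 1e6]
  tab[, cpm_f := count_f / total_f * 1e6]
  tab[, cq := compute_cq(count_m, count_f, total_m, total_f)]
  tab[, kmer_class := classify_kmer(cq, thresholds)]
  setkey(tab, code)
  data.table::setattr(tab, "total_m", total_m)
  data.table::setattr(tab, "total_f", total_f)
  data.table::setattr(tab, "dropped", dropped)
  tab[]
}
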