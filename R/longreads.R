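#' Filter long reads by length
#'
#' Admits reads with `min_len <= length <= max_len` (bounds inclusive); the
#' defaults are the 2 kb / 100 kb admission window used for corrected
#' PacBio reads.
#'
#' @param reads data.table with `read_id` and `sequence` (a `length` column
#'   is used when present, otherwise computed).
#' @param min_len,max_len inclusive length bounds in bp.
#' @return the input with a `status` column: `kept`, `too_short` or
#'   `too_long`.
#' @export
filter_long_reads <- function(reads, min_len = 2000L, max_len = 100000L) {
  stopifnot(min_len <= max_len)
  reads <- data.table::as.data.table(reads)
  if (!"length" %in% names(reads)) reads[, length := nchar(sequence)]
  reads[, status := ifelse(length < min_len, "too_short",
                           ifelse(length > max_len, "too_long", "kept"))]
  reads[]
}

#' Flag mitochondrial long reads by kmer sharing
#'
#' A read is tagged `mito` when the fraction of its canonical kmers present
#' in the mitochondrial reference's kmer set reaches `share_threshold`.
#' Kmer sharing stands in for alignment: at k = 25 a genuine mitochondrial
#' read shares nearly all its kmers with the reference while a nuclear read
#' shares essentially none, so the threshold is not delicate.
#'
#' @param reads data.table with `sequence` and a `status` column from
#'   [filter_long_reads()]; only `kept` reads are examined.
#' @param mito_reference character vector of mitochondrial reference
#'   sequence(s).
#' @param share_threshold minimum shared-kmer fraction (default 0.5).
#' @param k kmer length (default 25).
#' @return the input with `mito_share` added and `status` updated to
#'   `mito` where the threshold is met.
#' @export
mito_filter <- function(reads, mito_reference, share_threshold = 0.5,
                        k = 25L) {
  stopifnot(length(mito_reference) >= 1, nzchar(mito_reference),
            share_threshold >= 0, share_threshold <= 1)
  reads <- data.table::as.data.table(reads)
  if (!"status" %in% names(reads)) reads[, status := "kept"]
  reads[, mito_share := NA_real_]
  idx <- which(reads$status == "kept")
  if (!length(idx)) return(reads[])
  ref <- count_canonical_kmers_cpp(as.character(mito_reference), k)
  res <- tally_read_classes_cpp(reads$sequence[idx], ref$code,
                                rep(1L, length(ref$code)), k, 1L)
  share <- ifelse(res$valid_windows > 0,
                  res$tallies[, 1] / res$valid_windows, 0)
  reads[idx, mito_share := share]
  reads[idx[share >= share_threshold], status := "mito"]
  reads[]
}

#' Bin long reads by diagnostic kmers
#'
#' Tallies occurrences of class-diagnostic kmers (X-candidate, autosomal,
#' Y-like from the merged census) on each kept read; the read is assigned
#' to the class with the largest tally when that class holds at least
#' `dominance_threshold` of the diagnostic hits, and to the ambiguous bin
#' `GA` otherwise (including reads with no diagnostic kmer at all).
#'
#' Diagnostic kmers are the *confidently* classified subset of the census:
#' a kmer is diagnostic only when the normalised female fraction of its
#' counts sits at least `diag_confidence` binomial standard errors away
#' from the centre of every other class (2/3 for X, 1/2 for autosomal, 0
#' for Y). At modest sequencing depth the CQ of a single-copy kmer is
#' noisy enough to stray into a neighbouring class band; without this
#' filter those strays dilute the vote on every read and push genuine
#' X reads below the dominance threshold. At high depth the filter
#' asymptotically keeps everything.
#'
#' @param reads data.table with `sequence` and `status` (`kept` reads are
#'   binned; others get `NA`).
#' @param census merged census from [merge_census()] with `kmer_class`.
#' @param dominance_threshold minimum share of diagnostic hits for a call.
#' @param k kmer length (must match the census).
#' @param diag_confidence minimum z-separation of a diagnostic kmer from
#'   the nearest other class centre (default 2; 0 disables the filter).
#' @return the input with tally columns `hits_X`, `hits_A`, `hits_Y` and a
#'   `bin` column in `{"X", "A", "Y", "GA"}`.
#' @export
bin_long_reads <- function(reads, census, dominance_threshold = 0.8,
                           k = 25L, diag_confidence = 2) {
  stopifnot(dominance_threshold > 0, dominance_threshold <= 1,
            diag_confidence >= 0)
  reads <- data.table::as.data.table(reads)
  diag <- census[kmer_class %in% c("X", "A", "Y")]
  if (diag_confidence > 0 && nrow(diag)) {
    r <- diag$cpm_f / (diag$cpm_f + diag$cpm_m)
    n <- diag$sum
    rs <- (r * n + 0.5) / (n + 1)  # smoothed, so se > 0 at r = 0 or 1
    se <- sqrt(rs * (1 - rs) / n)
    dX <- abs(r - 2 / 3); dA <- abs(r - 1 / 2); dY <- r
    dX[diag$kmer_class == "X"] <- Inf
    dA[diag$kmer_class == "A"] <- Inf
    dY[diag$kmer_class == "Y"] <- Inf
    diag <- diag[pmin(dX, dA, dY) / se >= diag_confidence]
  }
  cls <- match(diag$kmer_class, c("X", "A", "Y"))
  reads[, c("hits_X", "hits_A", "hits_Y") := 0L]
  reads[, bin := NA_character_]
  idx <- which(reads$status == "kept")
  if (!length(idx)) return(reads[])
  res <- tally_read_classes_cpp(reads$sequence[idx], diag$code,
                                as.integer(cls), k, 3L)
  t <- res$tallies
  total <- rowSums(t)
  best <- max.col(t, ties.method = "first")
  share <- ifelse(total > 0, t[cbind(seq_len(nrow(t)), best)] / total, 0)
  # a tie for the top tally can never reach a dominance threshold > 0.5
  tied <- t[cbind(seq_len(nrow(t)), best)] ==
    t[cbind(seq_len(nrow(t)), max.col(t, ties.method = "last"))] &
    max.col(t, ties.method = "first") != max.col(t, ties.method = "last")
  bin_call <- ifelse(total == 0 | share < dominance_threshold | tied, "GA",
                     c("X", "A", "Y")[best])
  reads[idx, c("hits_X", "hits_A", "hits_Y") :=
          list(t[, 1], t[, 2], t[, 3])]
  data.table::set(reads, i = idx, j = "bin", value = bin_call)
  reads[]
}

#' Per-kmer long-read statistics
#'
#' For each candidate kmer, computes across the kept reads: `hits_sum`
#' (total occurrences), `max_pt` (maximum occurrences within any single
#' read), `unique_bin_occurrence` (number of distinct reads containing the
#' kmer), per-bin hit counts, and `xsi` — the X-specificity index, the
#' fraction of all hits (X, Y, A and GA bins alike) that fall on X-bin
#' reads. Kmers absent from every read get `hits_sum = 0` and undefined
#' (`NA`) `xsi`, and are excluded from candidacy downstream.
#'
#' @param kmer_codes numeric canonical kmer codes to profile (typically the
#'   census X-candidates).
#' @param binned_reads output of [bin_long_reads()]; only `kept` reads with
#'   a bin are used.
#' @param k kmer length.
#' @return data.table keyed by `code` with `hits_sum`, `max_pt`,
#'   `unique_bin_occurrence`, `hits_X`, `hits_Y`, `hits_A`, `hits_GA`,
#'   `xsi`.
#' @export
kmer_longread_stats <- function(kmer_codes, binned_reads, k = 25L) {
  binned_reads <- data.table::as.data.table(binned_reads)
  kept <- binned_reads[status == "kept" & !is.na(bin)]
  bins <- c("X", "Y", "A", "GA")
  out <- data.table(code = as.numeric(kmer_codes))
  if (!nrow(kept)) {
    out[, c("hits_X", "hits_Y", "hits_A", "hits_GA") := 0]
    out[, c("hits_sum", "max_pt", "unique_bin_occurrence") := 0]
    out[, xsi := NA_real_]
    setkey(out, code)
    return(out[])
  }
  res <- kmer_read_stats_cpp(kept$sequence, match(kept$bin, bins),
                             out$code, k, 4L)
  out[, c("hits_X", "hits_Y", "hits_A", "hits_GA") :=
        list(res$hits[, 1], res$hits[, 2], res$hits[, 3], res$hits[, 4])]
  out[, hits_sum := hits_X + hits_Y + hits_A + hits_GA]
  out[, max_pt := res$max_pt]
  out[, unique_bin_occurrence := res$unique_reads]
  out[, xsi := ifelse(hits_sum > 0, hits_X / hits_sum, NA_real_)]
  setkey(out, code)
  out[]
}

#' Select validated X-candidate kmers
#'
#' Keeps census X-candidates whose X-specificity index reaches `xsi_min`
#' and whose combined short-read abundance reaches `lsum` (defaults 0.995
#' and 100). Kmers never seen in the long reads (undefined XSI) are
#' excluded.
#'
#' @param stats [kmer_longread_stats()] table.
#' @param census merged census from [merge_census()].
#' @param xsi_min XSI floor (inclusive).
#' @param lsum combined-abundance floor (inclusive).
#' @return data.table joining census and long-read statistics for the
#'   retained candidates, keyed by `code`.
#' @export
xsi_filter <- function(stats, census, xsi_min = 0.995, lsum = 100) {
  cand <- merge(census[kmer_class == "X"], stats, by = "code")
  cand <- cand[!is.na(xsi) & xsi >= xsi_min & sum >= lsum]
  setkey(cand, code)
  cand[]
}
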