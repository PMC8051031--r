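#' Selection parameters
#'
#' The four ranking statistics — combined short-read abundance (`sum`),
#' total long-read occurrences (`hits_sum`), maximum occurrences within one
#' long read (`max_pt`) and number of distinct long reads containing the
#' kmer (`unique_bin_occurrence`) — are each cut at the top `q` percentile;
#' the per-criterion sets are then combined and the final table truncated
#' to `top_n`.
#'
#' @param q top fraction per criterion (default 0.0005, i.e. the top
#'   0.05%).
#' @param top_n final list size (default 25).
#' @param combine `"intersection"` (with fallback to the union of the four
#'   top sets when the intersection is smaller than `top_n`) or
#'   `"rank-sum"` (union, ordered by rank-sum, always).
#' @param max_mm maximum off-target mismatch level screened (default 3).
#' @param offtarget_max_mm exclusion window: candidates with any background
#'   hit at a mismatch level `<= offtarget_max_mm` are dropped (default 2).
#' @param offtarget_max_hits hits tolerated inside the exclusion window
#'   (default 0).
#' @return a `selection_params` list.
#' @export
selection_params <- function(q = 0.0005, top_n = 25L,
                             combine = c("intersection", "rank-sum"),
                             max_mm = 3L, offtarget_max_mm = 2L,
                             offtarget_max_hits = 0L) {
  combine <- match.arg(combine)
  stopifnot(q > 0, q <= 1, top_n >= 1, max_mm >= 0,
            offtarget_max_mm <= max_mm, offtarget_max_hits >= 0)
  structure(list(q = q, top_n = as.integer(top_n), combine = combine,
                 max_mm = as.integer(max_mm),
                 offtarget_max_mm = as.integer(offtarget_max_mm),
                 offtarget_max_hits = as.integer(offtarget_max_hits)),
            class = "selection_params")
}

criteria_cols <- c("sum", "hits_sum", "max_pt", "unique_bin_occurrence")

#' Flag candidates in the top percentile of each ranking statistic
#'
#' Per criterion, the cut sits at the value ranked `ceil(q * N)` from the
#' top; every candidate at or above that value is in the criterion's top
#' set (ties are never split). The flagged set is the intersection of the
#' four top sets, falling back to their union when the intersection holds
#' fewer than `top_n` kmers; output is ordered deterministically by
#' rank-sum (smaller is better) and then lexicographically by kmer.
#'
#' @param candidates [xsi_filter()] output (needs the four statistics and a
#'   `code` column; a `kmer` column is added if absent).
#' @param params a [selection_params()].
#' @param k kmer length used to decode `code` when no `kmer` column exists.
#' @return the candidates with `flagged` (logical), `rank_sum` and `rank`
#'   columns, ordered by (`rank_sum`, `kmer`).
#' @export
percentile_filter <- function(candidates, params = selection_params(),
                              k = 25L) {
  stopifnot(inherits(params, "selection_params"))
  cand <- data.table::as.data.table(candidates)
  if (!nrow(cand)) {
    warning("empty candidate set")
    if (!"kmer" %in% names(cand)) cand[, kmer := character()]
    cand[, c("flagged", "rank_sum", "rank") := list(logical(), numeric(),
                                                    integer())]
    return(cand[])
  }
  if (!"kmer" %in% names(cand)) cand[, kmer := decode_kmer(code, k)]
  n_top <- ceiling(params$q * nrow(cand))
  in_top <- matrix(FALSE, nrow(cand), length(criteria_cols))
  ranks <- matrix(0, nrow(cand), length(criteria_cols))
  for (j in seq_along(criteria_cols)) {
    v <- cand[[criteria_cols[j]]]
    cut <- sort(v, decreasing = TRUE)[n_top]
    in_top[, j] <- v >= cut
    ranks[, j] <- frank(-v, ties.method = "min")
  }
  cand[, rank_sum := rowSums(ranks)]
  inter <- rowSums(in_top) == length(criteria_cols)
  flag <- if (params$combine == "intersection" && sum(inter) >= params$top_n)
    inter else rowSums(in_top) > 0
  cand[, flagged := flag]
  setorder(cand, rank_sum, kmer)
  cand[, rank := seq_len(.N)]
  cand[]
}

pam_placement <- function(kmer_seq, nuclease, strand, offset, protospacer,
                          pam) {
  data.table(kmer = kmer_seq, nuclease = nuclease, strand = strand,
             offset = as.integer(offset), protospacer = protospacer,
             pam = pam)
}

scan_cas9_one_strand <- function(seq, strand) {
  out <- list()
  n <- nchar(seq)
  # 20-nt protospacer immediately followed by NGG, fully inside the kmer
  for (i in seq_len(max(0, n - 23 + 1))) {
    pam <- substr(seq, i + 20, i + 22)
    if (substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G")
      out[[length(out) + 1]] <- list(strand = strand, offset = i - 1L,
                                     protospacer = substr(seq, i, i + 19),
                                     pam = pam)
  }
  out
}

#' Enumerate Cas9 placements within a kmer
#'
#' Finds every position (both strands) where a 20-nt protospacer
#' immediately followed by an NGG PAM fits wholly inside the 25-mer — at
#' most 3 offsets per strand. Offsets are 0-based within the scanned
#' orientation (the stored kmer for `+`, its reverse complement for `-`).
#'
#' @param kmer_seq character vector of 25-mers.
#' @return data.table with `kmer`, `nuclease`, `strand`, `offset`,
#'   `protospacer`, `pam` (zero rows when nothing fits).
#' @export
pam_scan_cas9 <- function(kmer_seq) {
  res <- lapply(kmer_seq, function(s) {
    hits <- c(scan_cas9_one_strand(s, "+"),
              scan_cas9_one_strand(revcomp(s), "-"))
    if (!length(hits)) return(NULL)
    rbindlist(lapply(hits, function(h)
      pam_placement(s, "Cas9", h$strand, h$offset, h$protospacer, h$pam)))
  })
  empty <- pam_placement(character(), character(), character(), integer(),
                         character(), character())
  rbindlist(c(list(empty), res))
}

scan_cas12a_one_strand <- function(seq, strand, min_spacer) {
  out <- list()
  n <- nchar(seq)
  for (i in seq_len(max(0, n - 4 + 1))) {
    pam <- substr(seq, i, i + 3)
    if (substr(pam, 1, 3) == "TTT" && substr(pam, 4, 4) %in% c("A", "C", "G")) {
      avail <- n - (i + 3)
      if (avail >= min_spacer)
        out[[length(out) + 1]] <- list(strand = strand, offset = i - 1L,
                                       protospacer = substr(seq, i + 4, n),
                                       pam = pam)
    }
  }
  out
}

#' Enumerate Cas12a placements within a kmer
#'
#' Finds every position (both strands) where a TTTV PAM is followed by a
#' protospacer of at least `min_spacer` nt inside the 25-mer — at most 2
#' offsets per strand at the default spacer floor. Inside a 25-mer a
#' Cas12a spacer is necessarily <= 21 nt; the full remainder after the PAM
#' is reported as the protospacer.
#'
#' @param kmer_seq character vector of 25-mers.
#' @param min_spacer minimum protospacer length (default 20).
#' @return data.table as in [pam_scan_cas9()].
#' @export
pam_scan_cas12a <- function(kmer_seq, min_spacer = 20L) {
  res <- lapply(kmer_seq, function(s) {
    hits <- c(scan_cas12a_one_strand(s, "+", min_spacer),
              scan_cas12a_one_strand(revcomp(s), "-", min_spacer))
    if (!length(hits)) return(NULL)
    rbindlist(lapply(hits, function(h)
      pam_placement(s, "Cas12a", h$strand, h$offset, h$protospacer, h$pam)))
  })
  empty <- pam_placement(character(), character(), character(), integer(),
                         character(), character())
  rbindlist(c(list(empty), res))
}

#' Screen protospacers for off-targets in background reads
#'
#' Counts occurrences of each protospacer (both strands, PAM-agnostic) in
#' the background reads at Hamming distance 0..`max_mm`. The background is
#' the non-X long-read bins (autosomal, Y-like and optionally ambiguous),
#' mirroring the use of those bins as an off-target genome.
#'
#' @param protospacers character vector.
#' @param background_reads character vector of background read sequences
#'   (may be empty, with a warning).
#' @param max_mm maximum mismatch level (default 3).
#' @return data.table with `protospacer` and columns `mm0` .. `mm<max_mm>`.
#' @export
offtarget_screen <- function(protospacers, background_reads, max_mm = 3L) {
  stopifnot(max_mm >= 0)
  background_reads <- as.character(background_reads)
  if (!length(background_reads))
    warning("empty background: all off-target counts are zero")
  uniq <- unique(as.character(protospacers))
  out <- data.table(protospacer = uniq)
  m <- matrix(0, length(uniq), max_mm + 1)
  if (length(background_reads)) {
    for (len in unique(nchar(uniq))) {  # scanner needs uniform length
      idx <- which(nchar(uniq) == len)
      m[idx, ] <- hamming_counts_multi_cpp(uniq[idx], background_reads,
                                           max_mm)
    }
  }
  for (j in 0:max_mm) out[, (paste0("mm", j)) := m[, j + 1]]
  out[match(protospacers, uniq)]
}

#' Assemble the final ranked target table
#'
#' Joins the flagged candidates with their nuclease placements and
#' off-target profiles, drops candidates with no placement or with more
#' than `offtarget_max_hits` background hits at mismatch levels up to
#' `offtarget_max_mm`, and returns the `top_n` survivors in the
#' deterministic (`rank_sum`, `kmer`) order. One row per placement;
#' `selected` marks rows of the final list.
#'
#' @param flagged [percentile_filter()] output.
#' @param placements row-bound [pam_scan_cas9()] / [pam_scan_cas12a()]
#'   tables for the flagged kmers.
#' @param offtargets [offtarget_screen()] table aligned with `placements`
#'   (same row order).
#' @param params a [selection_params()].
#' @return data.table of selected placements with statistics, off-target
#'   counts, `rank` and `selected`.
#' @export
rank_targets <- function(flagged, placements, offtargets,
                         params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  flagged <- data.table::as.data.table(flagged)[flagged == TRUE]
  placements <- data.table::as.data.table(placements)
  if (nrow(placements) != nrow(offtargets))
    stop("placements and offtargets must align row for row")
  pl <- cbind(placements,
              data.table::as.data.table(offtargets)[, -"protospacer"])
  mm_cols <- paste0("mm", 0:params$offtarget_max_mm)
  pl[, offtarget_hits := rowSums(.SD), .SDcols = mm_cols]
  pl <- pl[offtarget_hits <= params$offtarget_max_hits]
  tab <- merge(flagged, pl, by = "kmer")
  setorder(tab, rank_sum, kmer, nuclease, strand, offset)
  keep_kmers <- head(unique(tab$kmer), params$top_n)
  if (length(keep_kmers) < params$top_n)
    warning("only ", length(keep_kmers), " targetable candidates survive (",
            params$top_n, " requested)")
  tab <- tab[kmer %in% keep_kmers]
  tab[, rank := match(kmer, keep_kmers)]
  tab[, selected := TRUE]
  setorder(tab, rank, nuclease, strand, offset)
  tab[]
}
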