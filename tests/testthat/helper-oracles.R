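# Independent brute-force oracles. These deliberately avoid the package's
# compiled code paths: plain string handling, window enumeration and regex.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA",
                     strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# canonical k-mer census by window enumeration; returns named count vector
oracle_census <- function(seqs, k, trim5 = 0, trim3 = 0) {
  out <- new.env()
  for (s in seqs) {
    n <- nchar(s)
    s <- substring(s, trim5 + 1, n - trim3)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      cn <- if (rc < km) rc else km
      out[[cn]] <- (if (is.null(out[[cn]])) 0 else out[[cn]]) + 1
    }
  }
  unlist(as.list(out))
}

# Hamming mismatch count between equal-length strings
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# both-strand sliding-window Hamming scan: counts per mismatch level
oracle_hamming_counts <- function(pattern, subjects, max_mm) {
  rc <- oracle_revcomp(pattern)
  pats <- if (rc == pattern) pattern else c(pattern, rc)
  m <- nchar(pattern)
  counts <- rep(0, max_mm + 1)
  for (s in subjects) {
    n <- nchar(s)
    if (n < m) next
    for (i in seq_len(n - m + 1)) {
      w <- substr(s, i, i + m - 1)
      for (p in pats) {
        mm <- oracle_hamming(p, w)
        if (mm <= max_mm) counts[mm + 1] <- counts[mm + 1] + 1
      }
    }
  }
  counts
}

# both-strand hit table on one subject (start 0-based)
oracle_hamming_hits <- function(pattern, subject, max_mm) {
  rc <- oracle_revcomp(pattern)
  m <- nchar(pattern)
  n <- nchar(subject)
  hits <- list()
  if (n >= m) {
    for (i in seq_len(n - m + 1)) {
      w <- substr(subject, i, i + m - 1)
      mm <- oracle_hamming(pattern, w)
      if (mm <= max_mm)
        hits[[length(hits) + 1]] <- data.frame(start = i - 1, strand = "+",
                                               mismatches = mm)
      if (rc != pattern) {
        mm <- oracle_hamming(rc, w)
        if (mm <= max_mm)
          hits[[length(hits) + 1]] <- data.frame(start = i - 1, strand = "-",
                                                 mismatches = mm)
      }
    }
  }
  do.call(rbind, c(list(data.frame(start = integer(), strand = character(),
                                   mismatches = integer())), hits))
}

# regex-lookahead PAM oracles; return sorted "strand:offset" keys
oracle_pam_cas9_keys <- function(kmer) {
  keys <- character()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") kmer else oracle_revcomp(kmer)
    m <- gregexpr("(?=[ACGT]{20}[ACGT]GG)", s, perl = TRUE)[[1]]
    if (m[1] != -1) keys <- c(keys, paste0(strand, ":", m - 1))
  }
  sort(keys)
}

oracle_pam_cas12a_keys <- function(kmer, min_spacer = 20) {
  keys <- character()
  pat <- sprintf("(?=TTT[ACG][ACGT]{%d})", min_spacer)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") kmer else oracle_revcomp(kmer)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] != -1) keys <- c(keys, paste0(strand, ":", m - 1))
  }
  sort(keys)
}

placement_keys <- function(placements) {
  if (nrow(placements) == 0) return(character(0))
  sort(paste0(placements$strand, ":", placements$offset))
}

# one tiny shared genome for unit tests (memoised per test session)
tiny_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- genome_spec(
        chromosomes = c(A1 = 60000L, X = 50000L, Y = 20000L),
        mito_length = 2000L, gc = 0.45,
        clusters = list(
          repeat_cluster_spec("xa", "X", 400L, 20L, unit_seed = 11L),
          repeat_cluster_spec("ya", "Y", 300L, 15L, unit_seed = 12L),
          repeat_cluster_spec("aa", "A1", 350L, 15L, unit_seed = 13L)),
        seed = 424L)
      cache <<- build_genome(spec)
    }
    cache
  }
})
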