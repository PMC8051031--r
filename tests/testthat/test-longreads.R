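make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  data.table::data.table(read_id = ids, sequence = seqs,
                         length = nchar(seqs))
}

test_that("length admission window is inclusive at both bounds", {
  set.seed(301)
  reads <- make_reads(vapply(c(1999L, 2000L, 50000L, 100000L, 100001L),
                             rand_dna, character(1)))
  out <- filter_long_reads(reads, 2000L, 100000L)
  expect_equal(out$status,
               c("too_short", "kept", "kept", "kept", "too_long"))
  empty <- filter_long_reads(make_reads(character()), 2000L, 100000L)
  expect_equal(nrow(empty), 0L)
  # every read lands in exactly one status category
  expect_false(anyNA(out$status))
})

test_that("mitochondrial reads are flagged by kmer sharing", {
  set.seed(302)
  mito <- rand_dna(2000)
  verbatim <- substr(mito, 100, 1700)       # pure mito content
  nuclear <- rand_dna(1600)
  # 900 mito + 700 random bases: share (900-24)/(1600-24) ~ 0.556
  mixed <- paste0(substr(mito, 1, 900), rand_dna(700))
  reads <- make_reads(c(verbatim, nuclear, mixed))
  reads$status <- "kept"
  out <- mito_filter(reads, mito, share_threshold = 0.5)
  expect_equal(out$status, c("mito", "kept", "mito"))
  expect_equal(out$mito_share[1], 1.0)
  expect_lt(out$mito_share[2], 0.01)
  expect_equal(out$mito_share[3], (900 - 24) / (1600 - 24))
  out9 <- mito_filter(reads, mito, share_threshold = 0.9)
  expect_equal(out9$status, c("mito", "kept", "kept"))
})

test_that("read binning requires a dominant diagnostic class", {
  g <- tiny_genome()
  set.seed(303)
  # construct a census by hand: X/A/Y diagnostic kmers with clean counts
  xa <- cluster_kmers(g, "xa"); aa <- cluster_kmers(g, "aa")
  ya <- cluster_kmers(g, "ya")
  census <- data.table::data.table(
    code = c(xa, aa, ya),
    count_m = c(rep(100, length(xa)), rep(200, length(aa)),
                rep(100, length(ya))),
    count_f = c(rep(200, length(xa)), rep(200, length(aa)),
                rep(0, length(ya))))
  census[, sum := count_m + count_f]
  census[, cpm_m := count_m]; census[, cpm_f := count_f]
  census[, cq := compute_cq(count_m, count_f, 1e6, 1e6)]
  census[, kmer_class := classify_kmer(cq)]
  cl <- g$clusters
  xr <- substr(g$sequences[["X"]], cl[name == "xa", start],
               cl[name == "xa", start] + 3000)
  ar <- substr(g$sequences[["A1"]], cl[name == "aa", start],
               cl[name == "aa", start] + 3000)
  mixed <- paste0(substr(xr, 1, 1500), substr(ar, 1, 1500))
  none <- rand_dna(2500)
  reads <- make_reads(c(xr, ar, mixed, none))
  reads$status <- "kept"
  out <- bin_long_reads(reads, census, dominance_threshold = 0.8)
  expect_equal(out$bin, c("X", "A", "GA", "GA"))
  expect_gt(out$hits_X[1], 0)
  expect_equal(out$hits_A[1], 0)
  # an exact 50/50 tie can never dominate
  expect_equal(out[3, hits_X > 0 && hits_A > 0], TRUE)
})

test_that("per-kmer long-read statistics match hand enumeration", {
  set.seed(304)
  km <- rand_dna(25)
  filler <- function(n) rand_dna(n)
  # kmer on 3 reads with per-read occurrences (4, 2, 2)
  r1 <- paste0(filler(30), km, filler(10), km, filler(10), km,
               filler(10), km, filler(30))
  r2 <- paste0(filler(20), km, filler(40), km, filler(20))
  r3 <- paste0(filler(25), revcomp(km), filler(30), km, filler(25))
  r4 <- filler(150)
  reads <- make_reads(c(r1, r2, r3, r4))
  reads$status <- "kept"
  reads$bin <- c("X", "X", "A", "X")
  st <- kmer_longread_stats(encode_kmer(km), reads)
  expect_equal(st$hits_sum, 8)
  expect_equal(st$max_pt, 4)
  expect_equal(st$unique_bin_occurrence, 3)
  expect_equal(st$hits_X, 6)
  expect_equal(st$hits_A, 2)
  expect_equal(st$xsi, 6 / 8)
  # absent kmer: zero hits, undefined xsi
  st0 <- kmer_longread_stats(encode_kmer(rand_dna(25)), reads)
  expect_equal(st0$hits_sum, 0)
  expect_true(is.na(st0$xsi))
})

test_that("XSI floor and combined-abundance floor behave at the boundaries", {
  codes <- encode_kmer(c("ACGTACGTACGTACGTACGTACGTA",
                         "CCGTACGTACGTACGTACGTACGTA",
                         "GTGTACGTACGTACGTACGTACGTA"))
  census <- data.table::data.table(
    code = codes, count_m = 50, count_f = 150,
    sum = c(200, 200, 99), cpm_m = 1, cpm_f = 2, cq = 2,
    kmer_class = "X")
  stats <- data.table::data.table(
    code = codes,
    hits_sum = c(200, 1000, 50), max_pt = 5,
    unique_bin_occurrence = 10,
    hits_X = c(199, 994, 50), hits_Y = 0,
    hits_A = c(1, 6, 0), hits_GA = 0,
    xsi = c(199 / 200, 0.994, 1.0))
  out <- xsi_filter(stats, census, xsi_min = 0.995, lsum = 100)
  # 199/200 = 0.995 passes (inclusive floor); 0.994 fails; sum 99 fails
  expect_equal(out$code, codes[1])
  out_all <- xsi_filter(stats, census, xsi_min = 0, lsum = 0)
  expect_equal(nrow(out_all), 3L)
})
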