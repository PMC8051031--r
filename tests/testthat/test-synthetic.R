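test_that("ground truth equals a brute-force window census of the emitted genome", {
  spec <- genome_spec(c(A1 = 3000L, X = 2500L, Y = 1200L), mito_length = 500L,
                      clusters = list(
                        repeat_cluster_spec("xa", "X", 60L, 8L,
                                            unit_seed = 5L)),
                      seed = 7L)
  g <- build_genome(spec)
  cls <- c(A1 = "A", X = "X", Y = "Y", mito = "mito")
  for (chrom in names(g$sequences)) {
    bf <- oracle_census(g$sequences[chrom], g$k)
    tt <- g$truth[g$truth[[paste0("count_", cls[[chrom]])]] > 0]
    kk <- decode_kmer(tt$code, g$k)
    expect_setequal(kk, names(bf))
    expect_equal(unname(tt[[paste0("count_", cls[[chrom]])]]),
                 unname(bf[kk]))
  }
})

test_that("planted head-to-tail arrays give exact unit-interior copy counts", {
  spec <- genome_spec(c(A1 = 5000L, X = 100000L), mito_length = 0L,
                      clusters = list(
                        repeat_cluster_spec("xa", "X", 1700L, 50L,
                                            unit_seed = 9L)),
                      seed = 21L)
  g <- build_genome(spec)
  # kmers interior to the unit occur exactly once per copy
  interior <- g$truth[count_X == 50 & count_A == 0]
  expect_gte(nrow(interior), 1700 - 24 - 50)  # allow rare self-overlap loss
  cl <- g$clusters[name == "xa"]
  expect_equal(cl$end - cl$start + 1L, 1700L * 50L)
})

test_that("an inverted central block is invisible to canonical counting away from its edges", {
  base <- list(chromosomes = c(A1 = 4000L, X = 60000L), mito_length = 0L)
  g_plain <- build_genome(genome_spec(
    base$chromosomes, base$mito_length,
    clusters = list(repeat_cluster_spec("xa", "X", 500L, 50L,
                                        unit_seed = 3L)),
    seed = 11L))
  g_inv <- build_genome(genome_spec(
    base$chromosomes, base$mito_length,
    clusters = list(repeat_cluster_spec("xa", "X", 500L, 50L,
                                        inverted_block = c(21L, 30L),
                                        unit_seed = 3L)),
    seed = 11L))
  # the emitted sequences differ (the block really is inverted) ...
  expect_false(identical(g_plain$sequences[["X"]], g_inv$sequences[["X"]]))
  # ... but window totals are conserved ...
  expect_equal(g_plain$truth[, sum(count_X)], g_inv$truth[, sum(count_X)])
  # ... and every kmer of the repeat unit itself keeps its exact count:
  # reverse-complemented copies are canonically identical, so only windows
  # crossing the two block boundaries can change
  cl <- g_plain$clusters[name == "xa"]
  unit <- substr(g_plain$sequences[["X"]], cl$start, cl$start + 500L - 1L)
  ucodes <- unique(encode_kmer(substring(unit, 1:476, 25:500)))
  m <- merge(g_plain$truth[code %in% ucodes], g_inv$truth[code %in% ucodes],
             by = "code")
  expect_equal(nrow(m), length(ucodes))
  expect_equal(m$count_X.x, m$count_X.y)
  # differences are confined to the boundary neighbourhoods
  d <- merge(g_plain$truth, g_inv$truth, by = "code", all = TRUE)
  n_diff <- nrow(d[is.na(count_X.x) | is.na(count_X.y) |
                     count_X.x != count_X.y])
  expect_lte(n_diff, 4L * 24L * 2L)
})

test_that("cluster overflow is rejected naming the cluster", {
  spec <- genome_spec(c(X = 1000L), mito_length = 0L,
                      clusters = list(
                        repeat_cluster_spec("toobig", "X", 100L, 20L,
                                            unit_seed = 1L)),
                      seed = 1L)
  expect_error(build_genome(spec), "toobig")
  expect_error(
    genome_spec(c(X = 1000L), clusters = list(
      repeat_cluster_spec("bad", "Z", 50L, 2L))),
    "unknown chromosome")
  expect_error(repeat_cluster_spec("b", "X", 50L, 5L,
                                   inverted_block = c(2L, 9L)),
               "inverted_block")
})

test_that("genome build is deterministic per seed", {
  spec <- demo_genome_spec(seed = 5, scale = 0.02)
  g1 <- build_genome(spec)
  g2 <- build_genome(spec)
  expect_identical(g1$sequences, g2$sequences)
  g3 <- build_genome(demo_genome_spec(seed = 6, scale = 0.02))
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("short-read simulation respects depth, ploidy and determinism", {
  g <- tiny_genome()
  expect_equal(nrow(simulate_short_reads(
    g, short_read_params("male", depth = 0, seed = 1))), 0L)
  p <- short_read_params("female", depth = 10, read_length = 100L,
                         error_rate = 0, mito_copy_multiplier = 10,
                         seed = 33L)
  reads <- simulate_short_reads(g, p)
  # female template: A1 x2, X x2, no Y, mito x10
  expect_equal(sum(reads$chromosome == "Y"), 0L)
  weighted <- 2 * 60000 + 2 * 50000 + 10 * 2000
  expect_lt(abs(sum(nchar(reads$sequence)) - 10 * weighted) /
              (10 * weighted), 0.01)
  # X:autosome per-base coverage ratio 2 in females vs males at equal depth
  pm <- short_read_params("male", depth = 10, error_rate = 0, seed = 34L)
  rm_ <- simulate_short_reads(g, pm)
  ratio_f <- (sum(reads$chromosome == "X") / 50000) /
    (sum(reads$chromosome == "A1") / 60000)
  ratio_m <- (sum(rm_$chromosome == "X") / 50000) /
    (sum(rm_$chromosome == "A1") / 60000)
  expect_lt(abs(ratio_f - 1), 0.1)   # female: both diploid
  expect_lt(abs(ratio_m - 0.5), 0.1) # male: X haploid
  expect_identical(simulate_short_reads(g, p), reads)
})

test_that("long-read lengths respect the clip bounds", {
  g <- tiny_genome()
  expect_equal(nrow(simulate_long_reads(
    g, long_read_params(n_reads = 0, seed = 1))), 0L)
  # degenerate clip: every read exactly 2000 bp
  lr <- simulate_long_reads(g, long_read_params(
    n_reads = 50, min_length = 2000L, max_length = 2000L, seed = 2))
  expect_true(all(lr$length == 2000L))
  expect_true(all(nchar(lr$sequence) == 2000L))
  lr2 <- simulate_long_reads(g, long_read_params(
    n_reads = 500, mean_length = 3000, sdlog = 1.2, seed = 3))
  expect_gte(min(lr2$length), 2000L)
  expect_lte(max(lr2$length), 100000L)
  expect_error(long_read_params(n_reads = 5, min_length = 10L,
                                max_length = 5L))
})

test_that("female:male coverage of planted X kmers is ~2 across seeds", {
  # ploidy signal at the kmer level, aggregated over planted X-cluster kmers
  g <- tiny_genome()
  xa <- intersect(cluster_kmers(g, "xa"), x_specific_kmers(g))
  ya <- intersect(cluster_kmers(g, "ya"),
                  g$truth[count_Y > 0 & count_X == 0 & count_A == 0, code])
  ratios <- vapply(1:20, function(s) {
    cm <- count_kmers(simulate_short_reads(
      g, short_read_params("male", 20, error_rate = 0,
                           mito_copy_multiplier = 2, seed = s)))
    cf <- count_kmers(simulate_short_reads(
      g, short_read_params("female", 20, error_rate = 0,
                           mito_copy_multiplier = 2, seed = s + 100)))
    fx <- cf$table[code %in% xa, sum(count)]
    mx <- cm$table[code %in% xa, sum(count)]
    fy <- cf$table[code %in% ya, sum(count)]
    expect_equal(fy, 0)  # error-free: Y kmers absent from female reads
    fx / mx
  }, numeric(1))
  expect_gt(mean(ratios), 1.8)
  expect_lt(mean(ratios), 2.2)
})
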