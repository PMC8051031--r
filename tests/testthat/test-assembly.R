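test_that("gene CQ reproduces the census formula on alignment counts", {
  gt <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4"),
    contig = "c1",
    reads_m = c(100, 100, 0, 0),
    reads_f = c(100, 0, 200, 0))
  out <- gene_cq(gt, total_m = 1e6, total_f = 1e6)
  expect_equal(out$cq, c(1.0, 0.0, Inf, NA_real_))
  # library-size normalisation
  out2 <- gene_cq(gt[1], total_m = 1e6, total_f = 2e6)
  expect_equal(out2$cq, 0.5)
})

test_that("contig classification uses the median gene CQ with a 10-gene floor", {
  mk <- function(contig, cqs) {
    # reverse-engineer counts that give the wanted cq at equal totals
    data.table::data.table(gene_id = sprintf("%s_g%d", contig,
                                             seq_along(cqs)),
                           contig = contig, reads_m = 100,
                           reads_f = 100 * cqs)
  }
  gt <- rbind(mk("cA", rep(1.0, 12)),
              mk("cX", c(rep(2.0, 6), rep(1.0, 5))),   # median 2.0
              mk("cY", rep(0.0, 15)),
              mk("cSmall", rep(2.0, 9)))               # below the floor
  out <- contig_cq(gene_cq(gt, 1e6, 1e6), min_genes = 10)
  expect_equal(out[contig == "cA", class], "A")
  expect_equal(out[contig == "cX", class], "X")
  expect_equal(out[contig == "cX", median_cq], 2.0)
  expect_equal(out[contig == "cY", class], "Y")
  expect_equal(out[contig == "cSmall", class], "unassigned")
  expect_equal(out[contig == "cSmall", n_genes], 9L)
})

test_that("median contig CQ shrugs off any single-gene perturbation", {
  set.seed(501)
  cqs <- c(rep(2, 6), rep(1.9, 5))
  gt <- data.table::data.table(gene_id = sprintf("g%d", 1:11),
                               contig = "c", reads_m = 100,
                               reads_f = 100 * cqs)
  base <- contig_cq(gene_cq(gt, 1e6, 1e6))$median_cq
  for (i in c(1, 6, 11)) {
    gt2 <- data.table::copy(gt)
    gt2[i, reads_f := sample(c(0, 1e5), 1)]
    pert <- contig_cq(gene_cq(gt2, 1e6, 1e6))$median_cq
    expect_lt(abs(pert - base), 0.11)
  }
})

test_that("exact read placement counts all alignments on both strands", {
  set.seed(502)
  genes <- c(gA = rand_dna(400), gB = rand_dna(400))
  r1 <- substr(genes[["gA"]], 50, 149)        # forward in gA
  r2 <- revcomp(substr(genes[["gB"]], 100, 199))  # reverse in gB
  r3 <- rand_dna(100)                          # nowhere
  dup <- paste0(substr(genes[["gA"]], 1, 150),
                substr(genes[["gA"]], 1, 150)) # gA prefix twice
  genes <- c(genes, gDup = dup)
  counts <- count_gene_reads(c(r1, r2, r3), genes)
  expect_equal(unname(counts["gA"]), 1)
  expect_equal(unname(counts["gB"]), 1)
  # r1 also lies inside gDup twice (all alignments are counted)
  expect_equal(unname(counts["gDup"]), 2)
})

test_that("kmer-to-assembly mapping equals the Hamming oracle", {
  set.seed(503)
  asm <- c(s1 = rand_dna(600), s2 = rand_dna(400))
  km <- rand_dna(25)
  # absent kmer, exact matching: no hits; short scaffold: no error
  expect_equal(nrow(map_kmers_to_assembly(km, c(asm, tiny = "ACGT"), 0)), 0L)
  # plant 7 copies across scaffolds, some reverse-complemented
  s1 <- asm[["s1"]]
  for (pos in c(10, 100, 200, 300)) substr(s1, pos, pos + 24) <- km
  s2 <- asm[["s2"]]
  for (pos in c(50, 150)) substr(s2, pos, pos + 24) <- revcomp(km)
  substr(s2, 250, 274) <- km
  asm2 <- c(s1 = s1, s2 = s2)
  hits <- map_kmers_to_assembly(km, asm2, 0)
  expect_equal(nrow(hits), 7L)
  expect_equal(sum(hits$strand == "-"), 2L)
  expect_true(all(hits$end - hits$start == 25L))
  # 1-substitution variant: invisible at max_mm 0, found at max_mm 1
  v <- km
  substr(v, 13, 13) <- setdiff(c("A", "C", "G", "T"), substr(km, 13, 13))[1]
  asm3 <- c(s = paste0(rand_dna(40), v, rand_dna(40)))
  expect_equal(nrow(map_kmers_to_assembly(km, asm3, 0)), 0L)
  h1 <- map_kmers_to_assembly(km, asm3, 1)
  expect_equal(h1$mismatches, 1L)
  expect_equal(h1$start, 40L)
  # randomized oracle equivalence
  for (rep in 1:40) {
    subj <- rand_dna(200)
    pat <- if (rep %% 2) rand_dna(25) else
      substr(subj, 60, 84)  # guarantee some true hits
    got <- map_kmers_to_assembly(pat, c(chr = subj), max_mm = 2)
    want <- oracle_hamming_hits(pat, subj, 2)
    data.table::setorder(got, start, strand)
    expect_equal(got$start, want$start[order(want$start, want$strand)])
    expect_equal(got$mismatches,
                 want$mismatches[order(want$start, want$strand)])
  }
})

test_that("hit clustering recovers array span, count and unit spacing", {
  # published-style coordinates: one cluster spanning 85,034 bp
  hits <- data.table::data.table(
    kmer = "K", scaffold = "scaffold_3",
    start = c(8001979L, seq(8010000L, 8080000L, by = 10000L), 8086988L),
    strand = "+", mismatches = 0L)
  hits[, end := start + 25L]
  arr <- cluster_hits(hits, max_gap = 20000L)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$span_start, 8001979L)
  expect_equal(arr$span_end, 8087013L)
  expect_equal(arr$span, 85034L)
  # a single hit spans exactly k
  single <- cluster_hits(hits[1], max_gap = 1000L)
  expect_equal(single$span, 25L)
  expect_true(is.na(single$median_spacing))
  # 50 head-to-tail copies of a 4 kb unit, one kmer per unit
  tandem <- data.table::data.table(
    kmer = "K", scaffold = "s", start = 1000L + 4000L * (0:49),
    strand = "+", mismatches = 0L)
  tandem[, end := start + 25L]
  arr2 <- cluster_hits(tandem, max_gap = 20000L)
  expect_equal(arr2$n_hits, 50L)
  expect_equal(arr2$median_spacing, 4000)
  expect_equal(arr2$span, 4000L * 49L + 25L)
  # span grows monotonically with max_gap
  spread <- data.table::data.table(
    kmer = "K", scaffold = "s",
    start = c(0L, 5000L, 30000L, 36000L, 90000L),
    strand = "+", mismatches = 0L)
  spread[, end := start + 25L]
  spans <- vapply(c(1000L, 10000L, 30000L, 60000L), function(gp)
    max(cluster_hits(spread, gp)$span), numeric(1))
  expect_true(all(diff(spans) >= 0))
})

test_that("region kmer specificity separates private from shared kmers", {
  set.seed(504)
  region <- rand_dna(300)
  shared <- substr(region, 100, 124)
  s_other <- paste0(rand_dna(100), shared, rand_dna(100))
  asm <- c(host = paste0(rand_dna(200), region, rand_dna(200)),
           other = s_other)
  out <- region_kmer_specificity(asm, "host", 200, 500)
  # census totals: every valid window of the region counted once
  expect_equal(sum(out$region_count), 300 - 25 + 1)
  expect_equal(out[kmer == canonical(shared), specificity], 0.5)
  private <- out[kmer != canonical(shared)]
  expect_true(all(private$specificity == 1))
  # region shorter than k: empty census
  empty <- region_kmer_specificity(asm, "host", 10, 20)
  expect_equal(nrow(empty), 0L)
})
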