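fake_candidates <- function(n, seed = 1) {
  set.seed(seed)
  data.table::data.table(
    code = encode_kmer(replicate(n, rand_dna(25))),
    sum = sample(100:10000, n, TRUE),
    hits_sum = sample(50:5000, n, TRUE),
    max_pt = sample(1:30, n, TRUE),
    unique_bin_occurrence = sample(1:500, n, TRUE),
    xsi = 1)
}

test_that("percentile cut sits at rank ceil(q*N) with ties included", {
  cand <- fake_candidates(10000, seed = 401)
  out <- percentile_filter(cand, selection_params(q = 0.0005, top_n = 1))
  # per criterion the cut is the value at rank ceil(0.0005 * 10000) = 5;
  # with independent random statistics the four top sets are disjoint, so
  # the flagged set is their union and nothing below every cut is flagged
  cuts <- vapply(c("sum", "hits_sum", "max_pt", "unique_bin_occurrence"),
                 function(col) sort(cand[[col]], decreasing = TRUE)[5],
                 numeric(1))
  in_any <- rowSums(mapply(function(col, cut) out[[col]] >= cut,
                           names(cuts), cuts)) > 0
  expect_equal(out$flagged, in_any)
  for (col in names(cuts))
    expect_gte(sum(cand[[col]] >= cuts[[col]]), 5)  # ties never split
  # q = 100% flags everything
  all_fl <- percentile_filter(cand, selection_params(q = 1))
  expect_true(all(all_fl$flagged))
  # deterministic ordering: rank_sum then lexicographic kmer
  expect_true(all(diff(all_fl$rank_sum) >= 0))
  ties <- all_fl[, .N, by = rank_sum][N > 1]
  if (nrow(ties)) {
    grp <- all_fl[rank_sum == ties$rank_sum[1], kmer]
    expect_identical(grp, sort(grp))
  }
})

test_that("percentile union fallback includes every per-criterion top set", {
  cand <- fake_candidates(2000, seed = 402)
  out <- percentile_filter(cand, selection_params(q = 0.0005, top_n = 25))
  n_top <- ceiling(0.0005 * 2000)  # = 1
  for (col in c("sum", "hits_sum", "max_pt", "unique_bin_occurrence")) {
    cut <- sort(cand[[col]], decreasing = TRUE)[n_top]
    top_codes <- cand[cand[[col]] >= cut, code]
    expect_true(all(top_codes %in% out[flagged == TRUE, code]))
  }
  # identical statistics => identical rank_sum
  two <- fake_candidates(50, seed = 403)
  two2 <- data.table::copy(two[1:2])
  two2[, code := encode_kmer(c(paste0(strrep("A", 24), "C"),
                               paste0(strrep("A", 24), "G")))]
  two2[, (c("sum", "hits_sum", "max_pt", "unique_bin_occurrence")) :=
         two[1, .(sum, hits_sum, max_pt, unique_bin_occurrence)]]
  out2 <- percentile_filter(rbind(two, two2), selection_params())
  rs <- out2[code %in% two2$code, rank_sum]
  expect_equal(rs[1], rs[2])
  # empty candidate set warns and returns empty
  expect_warning(empty <- percentile_filter(fake_candidates(0)),
                 "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("Cas9 placements match a regex oracle on random and edge kmers", {
  expect_equal(nrow(pam_scan_cas9(strrep("A", 25))), 0L)
  gg <- pam_scan_cas9(strrep("G", 25))
  expect_equal(nrow(gg), 3L)          # 3 forward offsets, none reverse
  expect_true(all(gg$strand == "+"))
  expect_true(all(nchar(gg$protospacer) == 20L))
  set.seed(404)
  for (km in replicate(1000, rand_dna(25))) {
    got <- pam_scan_cas9(km)
    expect_identical(placement_keys(got), oracle_pam_cas9_keys(km))
  }
})

test_that("Cas12a placements match a regex oracle on random and edge kmers", {
  expect_equal(nrow(pam_scan_cas12a(strrep("T", 25))), 0L)
  one <- pam_scan_cas12a(paste0("TTTA", strrep("A", 21)))
  fwd <- one[one$strand == "+", ]
  expect_equal(fwd$offset, 0L)
  expect_equal(nchar(fwd$protospacer), 21L)
  set.seed(405)
  for (km in replicate(1000, rand_dna(25))) {
    got <- pam_scan_cas12a(km)
    expect_identical(placement_keys(got), oracle_pam_cas12a_keys(km))
  }
})

test_that("off-target screen equals the brute-force Hamming oracle", {
  set.seed(406)
  # empty background: zeros with a warning
  expect_warning(z <- offtarget_screen("ACGTACGTACGTACGTACGT",
                                       character(), 3),
                 "empty background")
  expect_equal(unlist(z[, .(mm0, mm1, mm2, mm3)]), c(mm0 = 0, mm1 = 0,
                                                     mm2 = 0, mm3 = 0))
  # planted exact and 1-mismatch copies are found at the right level
  p <- rand_dna(20)
  v1 <- p
  substr(v1, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                              substr(p, 7, 7))[1]
  bg <- c(paste0(rand_dna(50), p, rand_dna(50)),
          paste0(rand_dna(30), v1, rand_dna(30)))
  out <- offtarget_screen(p, bg, 3)
  oracle <- oracle_hamming_counts(p, bg, 3)
  expect_equal(unname(unlist(out[, .(mm0, mm1, mm2, mm3)])), oracle)
  expect_gte(out$mm0, 1)
  expect_gte(out$mm1, 1)
  # randomized oracle equivalence, mixed protospacer lengths
  subjects <- replicate(8, rand_dna(300))
  pats <- c(replicate(10, rand_dna(20)), replicate(10, rand_dna(21)))
  got <- offtarget_screen(pats, subjects, 3)
  for (i in seq_along(pats))
    expect_equal(unname(unlist(got[i, .(mm0, mm1, mm2, mm3)])),
                 oracle_hamming_counts(pats[i], subjects, 3))
})

test_that("target ranking drops unplaceable and off-target-laden candidates", {
  cand <- fake_candidates(40, seed = 407)
  cand[, kmer := decode_kmer(code, 25)]
  fl <- percentile_filter(cand, selection_params(q = 1, top_n = 5))
  pl <- data.table::rbindlist(list(pam_scan_cas9(fl$kmer),
                                   pam_scan_cas12a(fl$kmer)))
  expect_gte(nrow(pl), 3)  # 40 random 25-mers always yield placements
  ot <- data.table::data.table(protospacer = pl$protospacer,
                               mm0 = 0, mm1 = 0, mm2 = 0, mm3 = 5)
  out <- rank_targets(fl, pl, ot, selection_params(q = 1, top_n = 5))
  expect_lte(length(unique(out$kmer)), 5L)
  expect_true(all(out$kmer %in% pl$kmer))     # no placement, no selection
  expect_true(all(out$selected))
  # any hit at mm <= 2 excludes; mm3 hits are tolerated
  ot2 <- data.table::copy(ot)
  ot2[1, mm2 := 1]
  out2 <- rank_targets(fl, pl, ot2, selection_params(q = 1, top_n = 5))
  expect_false(any(out2$kmer == pl$kmer[1] & out2$protospacer ==
                     pl$protospacer[1]))
  # ranking is deterministic and dense within the returned table
  expect_true(all(diff(out$rank) >= 0))
})
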