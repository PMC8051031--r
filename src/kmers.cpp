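// Core sequence primitives: canonical k-mer census, diagnostic-kmer tallies
// over reads, per-kmer long-read statistics, ungapped Hamming scans, i.i.d.
// substitution noise, and exact full-length read placement.
//
// Canonical k-mers (k <= 26) are packed 2 bits/base into a uint64 and
// returned to R as doubles: 2k <= 52 bits, so every code is exactly
// representable and data.table can join on them natively.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp_char(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static void check_k(int k) {
  if (k < 1 || k > 26)
    stop("k must be in [1, 26] (codes must fit exactly in a double)");
}

// Streams the canonical code of every valid window of `seq` into `fn`.
// A window is valid iff it contains only A/C/G/T; `invalid` accumulates
// skipped windows.
template <typename F>
static void for_each_canonical(const char* seq, int len, int k,
                               double& invalid, F fn) {
  if (len < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // consecutive valid bases ending here
  for (int i = 0; i < len; ++i) {
    int b = base2code(seq[i]);
    if (b < 0) {
      run = 0;
      fwd = 0; rev = 0;
      if (i >= k - 1) invalid += 1.0;  // window ending here spans this base
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    ++run;
    if (i >= k - 1) {
      if (run >= k) fn(fwd < rev ? fwd : rev);
      else invalid += 1.0;
    }
  }
}

// [[Rcpp::export]]
List count_canonical_kmers_cpp(CharacterVector seqs, int k,
                               int trim5 = 0, int trim3 = 0) {
  check_k(k);
  if (trim5 < 0 || trim3 < 0) stop("trims must be >= 0");
  std::unordered_map<uint64_t, double> counts;
  double valid = 0.0, invalid = 0.0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (seqs[s] == NA_STRING) stop("NA sequence at record %d", (int)(s + 1));
    const char* str = CHAR(seqs[s]);
    int len = LENGTH(seqs[s]);
    int from = trim5, to = len - trim3;
    if (to - from < k) continue;
    for_each_canonical(str + from, to - from, k, invalid,
                       [&](uint64_t code) { counts[code] += 1.0; valid += 1.0; });
  }
  NumericVector code(counts.size()), count(counts.size());
  R_xlen_t i = 0;
  for (auto& kv : counts) {
    code[i] = (double)kv.first;
    count[i] = kv.second;
    ++i;
  }
  return List::create(_["code"] = code, _["count"] = count,
                      _["valid_windows"] = valid,
                      _["invalid_windows"] = invalid);
}

// Per-read tallies of class-labelled diagnostic kmers. `codes` carry integer
// class labels 1..nclass; returns an n_reads x nclass hit matrix plus the
// number of valid windows per read (used for mito share).
// [[Rcpp::export]]
List tally_read_classes_cpp(CharacterVector reads, NumericVector codes,
                            IntegerVector cls, int k, int nclass) {
  check_k(k);
  if (codes.size() != cls.size()) stop("codes/cls length mismatch");
  std::unordered_map<uint64_t, int> lut;
  lut.reserve(codes.size() * 2);
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    int c = cls[i];
    if (c < 1 || c > nclass) stop("class label out of range");
    lut[(uint64_t)codes[i]] = c;
  }
  R_xlen_t n = reads.size();
  IntegerMatrix tallies(n, nclass);
  NumericVector valid(n);
  double invalid = 0.0;
  for (R_xlen_t r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) stop("NA read at record %d", (int)(r + 1));
    const char* str = CHAR(reads[r]);
    int len = LENGTH(reads[r]);
    double v = 0.0;
    for_each_canonical(str, len, k, invalid, [&](uint64_t code) {
      v += 1.0;
      auto it = lut.find(code);
      if (it != lut.end()) tallies(r, it->second - 1) += 1;
    });
    valid[r] = v;
  }
  return List::create(_["tallies"] = tallies, _["valid_windows"] = valid);
}

// Long-read statistics for candidate kmers: per-bin hit counts, maximum
// occurrences within a single read (max.pt) and number of distinct reads
// containing the kmer (unique bin occurrence). `bins` labels each read
// 1..nbins.
// [[Rcpp::export]]
List kmer_read_stats_cpp(CharacterVector reads, IntegerVector bins,
                         NumericVector cand, int k, int nbins) {
  check_k(k);
  if (reads.size() != bins.size()) stop("reads/bins length mismatch");
  std::unordered_map<uint64_t, int> idx;
  idx.reserve(cand.size() * 2);
  for (R_xlen_t i = 0; i < cand.size(); ++i)
    idx[(uint64_t)cand[i]] = (int)i;
  R_xlen_t m = cand.size();
  IntegerMatrix hits(m, nbins);
  std::vector<double> maxpt(m, 0.0), cur(m, 0.0);
  std::vector<double> uniq(m, 0.0);
  std::vector<R_xlen_t> last(m, -1);
  double invalid = 0.0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) stop("NA read at record %d", (int)(r + 1));
    int b = bins[r];
    if (b < 1 || b > nbins) stop("bin label out of range");
    const char* str = CHAR(reads[r]);
    int len = LENGTH(reads[r]);
    for_each_canonical(str, len, k, invalid, [&](uint64_t code) {
      auto it = idx.find(code);
      if (it == idx.end()) return;
      int i = it->second;
      hits(i, b - 1) += 1;
      if (last[i] != r) {
        if (cur[i] > maxpt[i]) maxpt[i] = cur[i];
        cur[i] = 1.0;
        last[i] = r;
        uniq[i] += 1.0;
      } else {
        cur[i] += 1.0;
      }
    });
  }
  for (R_xlen_t i = 0; i < m; ++i)
    if (cur[i] > maxpt[i]) maxpt[i] = cur[i];
  return List::create(_["hits"] = hits,
                      _["max_pt"] = NumericVector(maxpt.begin(), maxpt.end()),
                      _["unique_reads"] = NumericVector(uniq.begin(), uniq.end()));
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_char(s[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// Number of mismatches between pattern p (length m) and subject window,
// with early abort past limit. Non-ACGT subject characters always mismatch.
static inline int window_mm(const char* p, const char* w, int m, int limit) {
  int mm = 0;
  for (int i = 0; i < m; ++i) {
    if (p[i] != w[i]) {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

// Counts occurrences of `pattern` (and its reverse complement) in each
// subject at Hamming distance 0..max_mm. Returns a vector of length
// max_mm + 1 with the count at each exact mismatch level.
// [[Rcpp::export]]
NumericVector hamming_counts_cpp(std::string pattern, CharacterVector subjects,
                                 int max_mm) {
  if (max_mm < 0) stop("max_mm must be >= 0");
  int m = (int)pattern.size();
  std::string rc = revcomp_str(pattern);
  bool palindrome = (rc == pattern);
  NumericVector out(max_mm + 1);
  for (R_xlen_t s = 0; s < subjects.size(); ++s) {
    if (subjects[s] == NA_STRING) continue;
    const char* str = CHAR(subjects[s]);
    int len = LENGTH(subjects[s]);
    for (int i = 0; i + m <= len; ++i) {
      int mm = window_mm(pattern.c_str(), str + i, m, max_mm);
      if (mm <= max_mm) out[mm] += 1.0;
      if (!palindrome) {
        mm = window_mm(rc.c_str(), str + i, m, max_mm);
        if (mm <= max_mm) out[mm] += 1.0;
      }
    }
  }
  return out;
}

// Multi-pattern Hamming counting with a pigeonhole filter: each pattern is
// split into max_mm + 1 disjoint pieces, so any placement within max_mm
// substitutions matches at least one piece exactly. Subjects are scanned
// once with rolling piece codes; only windows sharing an exact piece with a
// pattern are verified. Counts are identical to the naive scan (a window is
// attributed to its first exact piece to avoid double counting). All
// patterns must share one length; mixed lengths are grouped by the caller.
// [[Rcpp::export]]
NumericMatrix hamming_counts_multi_cpp(CharacterVector patterns,
                                       CharacterVector subjects,
                                       int max_mm) {
  if (max_mm < 0) stop("max_mm must be >= 0");
  int P = (int)patterns.size();
  NumericMatrix out(P, max_mm + 1);
  if (P == 0) return out;
  int m = LENGTH(patterns[0]);
  int npieces = max_mm + 1;
  int plen = m / npieces;
  std::vector<std::string> pats;
  std::vector<int> owner;
  for (int p = 0; p < P; ++p) {
    if (LENGTH(patterns[p]) != m)
      stop("all patterns must have equal length");
    std::string fwd = as<std::string>(patterns[p]);
    pats.push_back(fwd); owner.push_back(p);
    std::string rc = revcomp_str(fwd);
    if (rc != fwd) { pats.push_back(rc); owner.push_back(p); }
  }
  if (plen < 4) {
    // pieces too short to filter usefully; fall back to the naive scan
    for (int p = 0; p < P; ++p) {
      NumericVector c = hamming_counts_cpp(as<std::string>(patterns[p]),
                                           subjects, max_mm);
      for (int j = 0; j <= max_mm; ++j) out(p, j) = c[j];
    }
    return out;
  }
  const uint64_t pmask = (1ULL << (2 * plen)) - 1;
  std::unordered_map<uint64_t, std::vector<int>> piece_idx;
  for (size_t e = 0; e < pats.size(); ++e) {
    for (int pi = 0; pi < npieces; ++pi) {
      uint64_t code = 0;
      bool ok = true;
      for (int j = 0; j < plen; ++j) {
        int b = base2code(pats[e][pi * plen + j]);
        if (b < 0) { ok = false; break; }
        code = (code << 2) | (uint64_t)b;
      }
      if (!ok) stop("patterns must contain only A/C/G/T");
      piece_idx[((uint64_t)pi << (2 * plen)) | code].push_back((int)e);
    }
  }
  std::vector<uint64_t> codes;
  std::vector<char> valid;
  for (R_xlen_t s = 0; s < subjects.size(); ++s) {
    if (subjects[s] == NA_STRING) continue;
    const char* str = CHAR(subjects[s]);
    int len = LENGTH(subjects[s]);
    if (len < m) continue;
    int nq = len - plen + 1;
    codes.assign(nq, 0);
    valid.assign(nq, 0);
    uint64_t code = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int b = base2code(str[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & pmask;
      if (++run >= plen && i - plen + 1 < nq) {
        codes[i - plen + 1] = code;
        valid[i - plen + 1] = 1;
      }
    }
    for (int q = 0; q < nq; ++q) {
      if (!valid[q]) continue;
      for (int pi = 0; pi < npieces; ++pi) {
        int i = q - pi * plen;
        if (i < 0 || i + m > len) continue;
        auto it = piece_idx.find(((uint64_t)pi << (2 * plen)) | codes[q]);
        if (it == piece_idx.end()) continue;
        for (int e : it->second) {
          const std::string& pat = pats[e];
          int total = 0, first_exact = -1;
          for (int pj = 0; pj < npieces && total <= max_mm; ++pj) {
            int mm = 0;
            for (int j = pj * plen; j < (pj + 1) * plen; ++j)
              if (pat[j] != str[i + j]) ++mm;
            if (mm == 0 && first_exact < 0) first_exact = pj;
            total += mm;
          }
          for (int j = npieces * plen; j < m && total <= max_mm; ++j)
            if (pat[j] != str[i + j]) ++total;
          if (total <= max_mm && first_exact == pi)
            out(owner[e], total) += 1.0;
        }
      }
    }
  }
  return out;
}

// Full hit table of every ungapped placement (both strands, <= max_mm
// substitutions) of each pattern in each subject. Starts are 0-based.
// [[Rcpp::export]]
DataFrame hamming_map_cpp(CharacterVector patterns, CharacterVector subjects,
                          int max_mm) {
  if (max_mm < 0) stop("max_mm must be >= 0");
  std::vector<int> p_idx, s_idx, start, mism;
  std::vector<std::string> strand;
  for (R_xlen_t p = 0; p < patterns.size(); ++p) {
    std::string pat = as<std::string>(patterns[p]);
    std::string rc = revcomp_str(pat);
    int m = (int)pat.size();
    bool palindrome = (rc == pat);
    for (R_xlen_t s = 0; s < subjects.size(); ++s) {
      if (subjects[s] == NA_STRING) continue;
      const char* str = CHAR(subjects[s]);
      int len = LENGTH(subjects[s]);
      for (int i = 0; i + m <= len; ++i) {
        int mm = window_mm(pat.c_str(), str + i, m, max_mm);
        if (mm <= max_mm) {
          p_idx.push_back((int)p + 1); s_idx.push_back((int)s + 1);
          start.push_back(i); mism.push_back(mm); strand.push_back("+");
        }
        if (!palindrome) {
          mm = window_mm(rc.c_str(), str + i, m, max_mm);
          if (mm <= max_mm) {
            p_idx.push_back((int)p + 1); s_idx.push_back((int)s + 1);
            start.push_back(i); mism.push_back(mm); strand.push_back("-");
          }
        }
      }
    }
  }
  return DataFrame::create(_["pattern"] = wrap(p_idx),
                           _["subject"] = wrap(s_idx),
                           _["start"] = wrap(start),
                           _["strand"] = wrap(strand),
                           _["mismatches"] = wrap(mism),
                           _["stringsAsFactors"] = false);
}

// i.i.d. per-base substitutions at `rate`, drawn from R's RNG so set.seed()
// governs reproducibility. Each hit base is replaced by one of the other 3.
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  if (rate < 0 || rate >= 1) stop("substitution rate must be in [0, 1)");
  if (rate == 0) return clone(seqs);
  RNGScope scope;
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    buf.assign(CHAR(seqs[i]), LENGTH(seqs[i]));
    for (size_t j = 0; j < buf.size(); ++j) {
      if (unif_rand() < rate) {
        int b = base2code(buf[j]);
        if (b < 0) continue;
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        buf[j] = CODE2BASE[(b + shift) & 3];
      }
    }
    out[i] = buf;
  }
  return out;
}

// Exact full-length placement counts of reads inside target sequences,
// both strands, all placements (the bowtie -a -v 0 convention). Returns a
// per-target alignment count. Read lengths may vary.
// [[Rcpp::export]]
NumericVector exact_read_hits_cpp(CharacterVector reads,
                                  CharacterVector targets) {
  // group reads by length, hash target windows per length
  std::unordered_set<int> lens;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    lens.insert(LENGTH(reads[r]));
  }
  NumericVector out(targets.size());
  for (int L : lens) {
    std::unordered_map<std::string, std::vector<int>> windows;
    for (R_xlen_t t = 0; t < targets.size(); ++t) {
      if (targets[t] == NA_STRING) continue;
      const char* str = CHAR(targets[t]);
      int len = LENGTH(targets[t]);
      for (int i = 0; i + L <= len; ++i)
        windows[std::string(str + i, L)].push_back((int)t);
    }
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
      if (reads[r] == NA_STRING || LENGTH(reads[r]) != L) continue;
      std::string s(CHAR(reads[r]), L);
      auto it = windows.find(s);
      if (it != windows.end())
        for (int t : it->second) out[t] += 1.0;
      std::string rc = revcomp_str(s);
      if (rc != s) {
        it = windows.find(rc);
        if (it != windows.end())
          for (int t : it->second) out[t] += 1.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector encode_kmers_cpp(CharacterVector kmers, bool canonical) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* str = CHAR(kmers[i]);
    int k = LENGTH(kmers[i]);
    check_k(k);
    uint64_t fwd = 0, rev = 0;
    const int shift = 2 * (k - 1);
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2code(str[j]);
      if (b < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t)b;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    }
    if (!ok) { out[i] = NA_REAL; continue; }
    out[i] = (double)(canonical ? (fwd < rev ? fwd : rev) : fwd);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  check_k(k);
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = CODE2BASE[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}
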