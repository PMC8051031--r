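---
title: "Discovering X-linked repeat CRISPR targets from sexed WGS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering X-linked repeat CRISPR targets from sexed WGS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An X-shredder biases the sex ratio of an XX/XY species toward males by
cutting the X chromosome at many sites during male meiosis, so Y-bearing
sperm predominate. Engineering one requires target sites that are
*abundant* on the X and *absent everywhere else*: any autosomal or
Y-linked copy turns the shredder into a general genome shredder. This
package implements the computational side of that search for species like
the Mediterranean fruit fly: finding abundant, X-specific, CRISPR-targetable
25-mers directly from male and female whole-genome sequencing, without
needing a chromosome-level assembly, and auditing an assembly after the
fact to locate and dissect the targeted repeat arrays.

## The discovery model

Three statistics carry the signal.

**Chromosome quotient (CQ).** For a kmer with raw counts $m$ and $f$ in
male and female libraries of total valid kmer instances $T_m$ and $T_f$,

$$\mathrm{CQ} = \frac{f / T_f}{m / T_m}.$$

In an XX/XY system, X-linked sequence sits near 2, autosomal near 1,
Y-linked near 0. Exactly: for X-linked sequence the expectation is
$2 T_m / T_f$, which approaches 2 only when autosomes dominate both
libraries — true of real genomes, and preserved by the synthetic designs
here (autosome:X:Y of roughly 12:3:1 by ploidy-weighted bases). A zero
male count maps CQ to `Inf` (kept in the X band, because a genuinely
X-specific repeat at high female coverage can legitimately have sparse
male counts); a zero female count maps to 0; zero in both is undefined
and the record is excluded. Classification bands default to Y ≤ 0.2,
autosomal 0.5–1.5, X ≥ 1.7, with an ambiguous gap between; the upstream
discovery tool this mirrors does not publish its exact boundaries, so the
bands are parameters, not assertions.

**X-specificity index (XSI).** Male long reads are binned to
X / autosomal / Y by the classified kmers they carry. A candidate kmer's
XSI is the fraction of all its long-read occurrences that fall on X-bin
reads; the floor is 0.995 (so 199 of 200 occurrences passes, 0.994
fails). The denominator includes hits on ambiguous-bin reads — a
conservative choice: placements we cannot attribute count against
specificity.

**Abundance and dispersion.** Four ranking statistics: `sum` (combined
raw short-read count), `hits_sum` (total long-read occurrences), `max_pt`
(maximum occurrences within a single long read) and
`unique_bin_occurrence` (distinct long reads containing the kmer). High
`max_pt` indicates tight tandem arrays; high `unique_bin_occurrence`
selects kmers spread over many independent reads rather than sequencing
artefacts.

## Pipeline and parameters

| stage | parameter | default | meaning |
|---|---|---|---|
| census | `k` | 25 | kmer length (codes packed 2 bits/base) |
| census | `trimm5`, `trimm3` | 5, 5 | bases trimmed from read ends |
| census | `kmernoise` | 5 | floor on the combined male+female raw count |
| candidacy | `lsum` | 100 | floor on `sum` |
| long reads | `min_len`, `max_len` | 2000, 100000 bp | admission window, inclusive |
| long reads | `share_threshold` | 0.5 | mitochondrial kmer-share cutoff |
| binning | `dominance_threshold` | 0.8 | share of diagnostic hits needed for a bin call |
| binning | `diag_confidence` | 2 | z-separation a diagnostic kmer needs from other class centres |
| candidacy | `xsi_min` | 0.995 | X-specificity floor |
| selection | `q` | 0.05% | top percentile per ranking statistic |
| selection | `top_n` | 25 | final table size |
| selection | `max_mm` | 3 | off-target mismatch levels screened |
| selection | `offtarget_max_mm`, `offtarget_max_hits` | 2, 0 | exclusion: any background hit within 2 mismatches |

The noise floor applies to the *combined* count: a genuinely Y-specific
kmer has a female count of 0, and per-library floors would erase the Y
class.

### Why binning needs a confidence filter

At 20-fold haploid depth a single-copy X kmer has raw counts around
15 (male) and 29 (female); the Poisson noise on a CQ built from such
counts strays into the autosomal band roughly one time in five. Used
naively as diagnostics, those strays dilute every X read's vote to about
73% X — below the 0.8 dominance threshold — and genuine X reads drown in
the ambiguous bin. A kmer is therefore diagnostic only when the
normalised female fraction of its counts sits at least `diag_confidence`
binomial standard errors from the centre of every *other* class (2/3 for
X, 1/2 for autosomal, 0 for Y). The filter costs nothing asymptotically
(at high depth every classified kmer is confident) and restores ≥ 98%
binning accuracy at depth 20. Deep-coverage runs can disable it with
`diag_confidence = 0`.

### Target selection and its eligibility stages

Per statistic, the cut sits at the value ranked $\lceil qN \rceil$ from
the top, ties always included. The flagged set is the intersection of the
four top sets; if that holds fewer than `top_n` kmers, the union. Both
sets are ordered by rank-sum, then lexicographically by kmer, so output
is reproducible without any manual step. Placements are enumerated for
Cas9 (20-nt protospacer + NGG wholly inside the 25-mer; at most 3 offsets
per strand) and Cas12a (TTTV + ≥ 20-nt protospacer; at most 2 offsets per
strand; spacers within a 25-mer are necessarily ≤ 21 nt and the full
remainder is reported). Off-targets are counted PAM-agnostically as
Hamming-distance placements (0–3 substitutions) of the protospacer in the
autosomal + Y long-read bins; ambiguous-bin reads are excluded from the
background because they are frequently X-derived and would veto true
targets.

Only a quarter of random 25-mers carry any Cas9/Cas12a placement, and at
desk scale the top-0.05% pool holds only tens of kmers, so the flagged
pool alone often cannot fill 25 targetable slots. Eligibility therefore
widens in stages — intersection, union, then the remaining
XSI/LSum-validated candidates in rank-sum order — until `top_n`
targetable kmers are found or candidates are exhausted. The final table
is the top `top_n` targetable kmers in global (rank-sum, kmer) order;
when fewer survive, the table is shorter and a warning says so.

## The synthetic generator

The generator emulates exactly the structure the statistics assume:

- diploid sampling — females draw reads from {autosomes ×2, X ×2}, males
  from {autosomes ×2, X ×1, Y ×1}; a mitochondrial template is added at a
  copy multiplier (default 100×) so the mito-exclusion stage has work;
- X-linked head-to-tail tandem arrays with configurable unit length and
  copy number, including a central inverted block (emitted
  reverse-complemented) in the 4-kb-unit array;
- an X+autosome decoy: two clusters sharing one repeat unit, planted on X
  and on an autosome — abundant and differential enough to enter the CQ
  X band at small scales, but doomed at the XSI stage;
- uniform read starts, i.i.d. substitution errors (0.2% short reads, 1%
  long reads), log-normal long-read lengths clipped to bounds;
- exact ground truth: the canonical 25-mer table is counted from the
  *emitted* sequence, so background collisions with planted repeats are
  part of the truth rather than a source of test error.

It does **not** emulate indels or platform error profiles, structural
variation beyond the one inverted block, heterozygosity, GC-coverage
bias, or chimeric long reads. Passing tests therefore demonstrate the
statistical machinery — ploidy signal, specificity filtering, ranking,
array dissection — not robustness to real-platform artefacts.

One subtlety of the inverted block: reverse-complemented copies are
invisible to canonical counting *except* at the two block boundaries,
where the forward/reverse junctions create (and remove) a handful of
junction-spanning kmers — at most $2(k-1)$ windows per boundary. Unit
interior counts are identical with and without the inversion; the truth
tables as a whole are not, and the tests assert exactly that.

## Study conditions and problem sizes

The packaged demo (`demo_genome_spec()`): 3.6 Mb autosome, 1 Mb X,
0.3 Mb Y, 16 kb mitochondrion at 100×; on X a 1.7-kb unit × 50 array
(85 kb) and a 4-kb unit × 50 array (200 kb) with copies 21–30 inverted;
the shared-unit decoy at 25 copies on X and autosome; autosome-only and
Y-only background repeats; 20-fold short-read depth per sex and ~8-fold
male long-read coverage. The fixed-seed demo recovers both planted arrays
with precision and recall 1.0 and rejects the decoy (XSI ≈ 0.002 versus
the 0.995 floor). Multi-seed sweeps (CQ bands, decoy specificity) run on
proportionally smaller genomes (~0.5 Mb) at the same depth so ten
replicates complete in minutes; depth, not genome size, sets the
per-kmer counting noise those sweeps measure.

Because all four ranking statistics are nearly exchangeable between two
arrays of equal copy number, which array's kmers fill the final table at
desk scale depends on rank noise from the seed; the validated candidate
set always covers both arrays. This mirrors why the original selection
ended with a manual diversity pick across arrays.

## Numerical choices

- Canonical kmers are encoded 2 bits/base into doubles (exact for
  $k \le 26$); all joins run on numeric codes, strings are decoded only
  for output.
- Percentile cuts never split ties; ranking uses `ties.method = "min"`;
  all orderings break ties lexicographically by kmer, so every table is
  byte-reproducible for a fixed configuration.
- The off-target scanner verifies only windows sharing an exact
  pigeonhole piece (pattern split into `max_mm + 1` disjoint pieces) with
  a pattern, attributing each window to its first exact piece; counts are
  provably identical to the naive scan, which remains in the test suite
  as the oracle.
- Coordinates are 0-based half-open in kmer-hit and array tables; planted
  cluster coordinates in the generator's truth are 1-based inclusive
  (documented per field).
- `Inf` is the CQ sentinel for zero male counts; records zero in both
  sexes are dropped before classification.
- Every stage seeds R's RNG from one integer via a deterministic
  splitter, and the compiled substitution-noise code draws from R's RNG,
  so a configuration reproduces its outputs byte for byte.

## Known limitations

- Exact canonical matching of long reads (no mismatch tolerance) makes
  long-read error the main driver of lost hits; at 1% substitution a
  25-mer survives a window with probability ~0.78, uniformly attenuating
  `hits_sum` without biasing XSI.
- In-memory hash counting targets desk-scale libraries (tens of millions
  of kmers); multi-billion-kmer censuses would need disk-backed counting,
  deliberately out of scope.
- Off-target screening is Hamming-only and PAM-agnostic; no activity or
  efficiency scoring of guides.
- Contig CQ on real data expects precomputed per-gene alignment counts;
  the built-in exact placement is for synthetic audits.
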