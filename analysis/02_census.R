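#!/usr/bin/env Rscript
# Step 2 — sexed short-read census and chromosome quotient.
#
# Simulates male (XY) and female (XX) Illumina-like libraries at 20-fold
# haploid depth, counts canonical 25-mers after 5/5 end trimming, applies
# the combined-count noise floor of 5, and classifies every kmer by its
# library-size-normalised female/male ratio (CQ). The planted repeat
# classes should land near CQ 2 (X), 1 (autosomal) and 0 (Y).

suppressPackageStartupMessages({
  library(data.table)
  library(xshred)
})

genome <- readRDS("scratch/01_genome.rds")
seed <- 1L

reads <- lapply(c(male = "male", female = "female"), function(sex)
  simulate_short_reads(genome, short_read_params(
    sex = sex, depth = 20, seed = seed + (sex == "female"))))
message("reads: ", nrow(reads$male), " male / ", nrow(reads$female),
        " female")

census <- merge_census(count_kmers(reads$male), count_kmers(reads$female))
message("census kmers after noise floor: ", nrow(census),
        " (dropped ", attr(census, "dropped"), ")")
print(table(census$kmer_class))

planted <- list(
  X = intersect(cluster_kmers(genome, "x_array_1700"),
                x_specific_kmers(genome)),
  A = intersect(cluster_kmers(genome, "a_repeat"),
                genome$truth[count_A > 0 & count_X == 0 & count_Y == 0,
                             code]),
  Y = intersect(cluster_kmers(genome, "y_repeat"),
                genome$truth[count_Y > 0 & count_X == 0 & count_A == 0,
                             code]))
cq_tab <- rbindlist(lapply(names(planted), function(cl) {
  sub <- census[code %in% planted[[cl]]]
  data.table(planted_class = cl, n_kmers = nrow(sub),
             mean_cq = sub[, mean(cq[is.finite(cq)])],
             share_classified_correctly = sub[, mean(kmer_class == cl)])
}))
print(cq_tab)
fwrite(cq_tab, "results/02_planted_cq.tsv", sep = "\t")

class_tab <- census[, .N, by = kmer_class]
fwrite(class_tab, "results/02_census_classes.tsv", sep = "\t")
saveRDS(census, "scratch/02_census.rds")
saveRDS(reads, "scratch/02_reads.rds")
message("wrote results/02_planted_cq.tsv, results/02_census_classes.tsv")
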