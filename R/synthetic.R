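#' Specify a planted tandem repeat array
#'
#' Describes one head-to-tail tandem repeat cluster to plant on a synthetic
#' chromosome: a random repeat unit (reproducible from `unit_seed`, so two
#' clusters sharing a `unit_seed` carry the same unit — the way an
#' X+autosome decoy is built) repeated `copy_number` times, optionally with
#' a central block of copies emitted reverse-complemented, emulating the
#' large repeat inversion seen in real X-linked arrays.
#'
#' @param name cluster identifier (used in error messages and truth tables).
#' @param chromosome chromosome label the cluster is planted on.
#' @param unit_length repeat unit length in bp (>= 25).
#' @param copy_number number of tandem copies (>= 1).
#' @param start optional 1-based start position; when NULL the builder
#'   places clusters left to right with equal gaps.
#' @param inverted_block optional integer pair `c(from, to)`: copies in
#'   this range (inclusive) are emitted reverse-complemented.
#' @param unit_seed integer seed for the unit sequence.
#' @param per_copy_sub per-copy substitution rate (fraction of unit bases
#'   mutated independently in each copy; default 0 = identical copies).
#' @return a `repeat_cluster_spec` list.
#' @export
repeat_cluster_spec <- function(name, chromosome, unit_length, copy_number,
                                start = NULL, inverted_block = NULL,
                                unit_seed = 1L, per_copy_sub = 0) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(chromosome), length(chromosome) == 1)
  unit_length <- as.integer(unit_length)
  copy_number <- as.integer(copy_number)
  if (unit_length < 25) stop("unit_length must be >= 25 for cluster ", name)
  if (copy_number < 1) stop("copy_number must be >= 1 for cluster ", name)
  if (!is.null(inverted_block)) {
    inverted_block <- as.integer(inverted_block)
    if (length(inverted_block) != 2 ||
        inverted_block[1] < 1 || inverted_block[2] > copy_number ||
        inverted_block[1] > inverted_block[2])
      stop("inverted_block must lie within [1, copy_number] for cluster ", name)
  }
  if (per_copy_sub < 0 || per_copy_sub >= 1)
    stop("per_copy_sub must be in [0, 1) for cluster ", name)
  structure(list(name = name, chromosome = chromosome,
                 unit_length = unit_length, copy_number = copy_number,
                 start = if (is.null(start)) NULL else as.integer(start),
                 inverted_block = inverted_block,
                 unit_seed = as.integer(unit_seed),
                 per_copy_sub = per_copy_sub),
            class = "repeat_cluster_spec")
}

#' Specify a synthetic genome
#'
#' @param chromosomes named integer vector of chromosome lengths in bp.
#'   Names are free-form but must include "X" (and usually "Y" plus one or
#'   more autosomes); any name other than "X", "Y" and "mito" is treated as
#'   autosomal.
#' @param mito_length mitochondrial genome length in bp (0 to disable).
#' @param gc GC fraction of the random background.
#' @param clusters list of [repeat_cluster_spec()] objects.
#' @param seed global integer seed; every downstream draw derives from it.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(chromosomes, mito_length = 16000, gc = 0.45,
                        clusters = list(), seed = 1L) {
  stopifnot(length(chromosomes) >= 1, !is.null(names(chromosomes)),
            all(nzchar(names(chromosomes))))
  if (anyDuplicated(names(chromosomes)))
    stop("chromosome labels must be unique")
  if ("mito" %in% names(chromosomes))
    stop("use mito_length for the mitochondrial template")
  chromosomes <- setNames(as.integer(chromosomes), names(chromosomes))
  if (any(chromosomes < 1)) stop("chromosome lengths must be positive")
  for (cl in clusters) {
    if (!inherits(cl, "repeat_cluster_spec"))
      stop("clusters must be repeat_cluster_spec objects")
    if (!cl$chromosome %in% names(chromosomes))
      stop("cluster ", cl$name, " names unknown chromosome ", cl$chromosome)
  }
  structure(list(chromosomes = chromosomes,
                 mito_length = as.integer(mito_length), gc = gc,
                 clusters = clusters, seed = as.integer(seed)),
            class = "genome_spec")
}

# deterministic sub-seed derivation, kept inside 32-bit range
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729 + 17) %%
               2147483647)
}

chrom_class <- function(labels) {
  ifelse(labels == "X", "X",
         ifelse(labels == "Y", "Y",
                ifelse(labels == "mito", "mito", "A")))
}

build_cluster_seq <- function(cl, gc, global_seed) {
  set.seed(derive_seed(global_seed, cl$unit_seed))
  unit <- random_dna(cl$unit_length, gc)
  copies <- rep(unit, cl$copy_number)
  if (cl$per_copy_sub > 0) {
    set.seed(derive_seed(global_seed, cl$unit_seed + 7L))
    copies <- mutate_seqs_cpp(copies, cl$per_copy_sub)
  }
  if (!is.null(cl$inverted_block)) {
    idx <- seq(cl$inverted_block[1], cl$inverted_block[2])
    copies[idx] <- revcomp(copies[idx])
  }
  paste(copies, collapse = "")
}

#' Build a synthetic genome with exact planted ground truth
#'
#' Emits i.i.d. background chromosomes, plants the specified tandem repeat
#' arrays (head-to-tail, with any inverted block reverse-complemented), and
#' computes the ground-truth canonical k-mer table *post hoc* from the
#' emitted sequence — so background collisions with planted repeats are
#' reflected in the truth rather than prevented.
#'
#' @param spec a [genome_spec()].
#' @param k kmer length for the truth table (default 25).
#' @return a `synthetic_genome` list with elements `sequences` (named
#'   character vector, including `mito` when enabled), `truth` (data.table:
#'   `code`, `kmer`-decodable counts `count_A`, `count_X`, `count_Y`,
#'   `count_mito`), `clusters` (data.table of planted coordinates, 1-based
#'   inclusive), `k`, and the `spec`.
#' @export
build_genome <- function(spec, k = 25) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(derive_seed(spec$seed, 1L))
  seqs <- vapply(names(spec$chromosomes), function(nm)
    random_dna(spec$chromosomes[[nm]], spec$gc), character(1))
  if (spec$mito_length > 0)
    seqs <- c(seqs, mito = random_dna(spec$mito_length, spec$gc))

  # resolve placements: explicit starts first, then left-to-right auto layout
  coords <- list()
  for (chrom in unique(vapply(spec$clusters, `[[`, character(1), "chromosome"))) {
    cls <- Filter(function(cl) cl$chromosome == chrom, spec$clusters)
    L <- spec$chromosomes[[chrom]]
    lens <- vapply(cls, function(cl) cl$unit_length * cl$copy_number, numeric(1))
    auto <- vapply(cls, function(cl) is.null(cl$start), logical(1))
    if (any(auto)) {
      gap <- floor((L - sum(lens[auto])) / (sum(auto) + 1))
      if (gap < 0)
        stop("clusters ", paste(vapply(cls[auto], `[[`, character(1), "name"),
                                collapse = ", "),
             " overflow chromosome ", chrom)
      pos <- gap + 1
      for (i in which(auto)) {
        cls[[i]]$start <- as.integer(pos)
        pos <- pos + lens[i] + gap
      }
    }
    for (i in seq_along(cls)) {
      cl <- cls[[i]]
      if (cl$start < 1 || cl$start + lens[i] - 1 > L)
        stop("cluster ", cl$name, " overflows chromosome ", chrom,
             " (needs [", cl$start, ", ", cl$start + lens[i] - 1,
             "] in 1..", L, ")")
      coords[[length(coords) + 1]] <- data.table(
        name = cl$name, chromosome = chrom, start = cl$start,
        end = as.integer(cl$start + lens[i] - 1),
        unit_length = cl$unit_length, copy_number = cl$copy_number)
      arr <- build_cluster_seq(cl, spec$gc, spec$seed)
      seqs[[chrom]] <- paste0(
        substr(seqs[[chrom]], 1, cl$start - 1), arr,
        substr(seqs[[chrom]], cl$start + nchar(arr), L))
    }
  }
  clusters <- if (length(coords)) rbindlist(coords) else
    data.table(name = character(), chromosome = character(),
               start = integer(), end = integer(),
               unit_length = integer(), copy_number = integer())

  # ground truth from the emitted sequence
  classes <- chrom_class(names(seqs))
  per_class <- lapply(c(A = "A", X = "X", Y = "Y", mito = "mito"), function(cc) {
    sub <- seqs[classes == cc]
    if (!length(sub)) return(data.table(code = numeric(), count = numeric()))
    res <- count_canonical_kmers_cpp(unname(sub), k)
    data.table(code = res$code, count = res$count)
  })
  truth <- Reduce(function(a, b) merge(a, b, by = "code", all = TRUE),
                  Map(function(dt, nm) setnames(copy(dt), "count", nm),
                      per_class, paste0("count_", names(per_class))))
  for (col in paste0("count_", names(per_class)))
    truth[is.na(get(col)), (col) := 0]
  setkey(truth, code)

  structure(list(sequences = seqs, truth = truth, clusters = clusters,
                 k = as.integer(k), spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic genome:", length(x$sequences), "sequences,",
      sum(nchar(x$sequences)), "bp;", nrow(x$truth), "distinct canonical",
      paste0(x$k, "-mers;"), nrow(x$clusters), "planted clusters\n")
  invisible(x)
}

# ploidy-weighted template copy numbers for a sampling sex
template_copies <- function(genome, sex, mito_copy_multiplier) {
  labels <- names(genome$sequences)
  cls <- chrom_class(labels)
  copies <- ifelse(cls == "A", 2,
                   ifelse(cls == "X", if (sex == "female") 2 else 1,
                          ifelse(cls == "Y", if (sex == "female") 0 else 1,
                                 mito_copy_multiplier)))
  setNames(copies, labels)
}

#' Parameters for sexed short-read simulation
#'
#' @param sex "male" (XY) or "female" (XX); autosomes are sampled at two
#'   copies, X at two (female) or one (male), Y at one (male only), and the
#'   mitochondrial template at `mito_copy_multiplier` copies.
#' @param depth fold-coverage per haploid template copy.
#' @param read_length read length in bp (> 35 so trimmed reads still span a
#'   25-mer).
#' @param error_rate i.i.d. per-base substitution rate.
#' @param mito_copy_multiplier copy number of the mitochondrial contaminant.
#' @param seed integer seed.
#' @return a `short_read_params` list.
#' @export
short_read_params <- function(sex = c("male", "female"), depth,
                              read_length = 100L, error_rate = 0.002,
                              mito_copy_multiplier = 100, seed = 1L) {
  sex <- match.arg(sex)
  stopifnot(depth >= 0, read_length > 35, error_rate >= 0, error_rate < 1,
            mito_copy_multiplier >= 0)
  structure(list(sex = sex, depth = depth,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 mito_copy_multiplier = mito_copy_multiplier,
                 seed = as.integer(seed)),
            class = "short_read_params")
}

sample_reads_from_template <- function(seq_str, n, read_length, rc_half = TRUE) {
  L <- nchar(seq_str)
  if (n == 0 || L < read_length)
    return(list(start = integer(), strand = character(), seq = character()))
  starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
  reads <- substring(seq_str, starts, starts + read_length - 1L)
  strand <- rep("+", n)
  if (rc_half) {
    flip <- runif(n) < 0.5
    if (any(flip)) reads[flip] <- revcomp_cpp(reads[flip])
    strand[flip] <- "-"
  }
  list(start = starts, strand = strand, seq = reads)
}

#' Simulate a sexed short-read library
#'
#' Uniform read starts over the ploidy-weighted template multiset with
#' i.i.d. substitution errors. Read count per template is
#' `round(depth * copies * length / read_length)`, so expected per-base
#' coverage of X sequence is `2 * depth` in females and `depth` in males.
#'
#' @param genome a [build_genome()] result.
#' @param params a [short_read_params()].
#' @return data.table with `read_id`, `chromosome` (origin), `start`
#'   (1-based on the forward template), `strand`, `sequence`.
#' @export
simulate_short_reads <- function(genome, params) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(params, "short_read_params"))
  set.seed(derive_seed(params$seed, 2L))
  copies <- template_copies(genome, params$sex, params$mito_copy_multiplier)
  out <- vector("list", length(copies))
  for (i in seq_along(copies)) {
    nm <- names(copies)[i]
    n <- round(params$depth * copies[[i]] * nchar(genome$sequences[[nm]]) /
                 params$read_length)
    smp <- sample_reads_from_template(genome$sequences[[nm]], n,
                                      params$read_length)
    out[[i]] <- data.table(chromosome = rep(nm, length(smp$start)),
                           start = smp$start, strand = smp$strand,
                           sequence = smp$seq)
  }
  reads <- rbindlist(out)
  if (nrow(reads) && params$error_rate > 0)
    reads[, sequence := mutate_seqs_cpp(sequence, params$error_rate)]
  reads[, read_id := sprintf("%s_sr_%07d", params$sex, seq_len(.N))]
  data.table::setcolorder(reads, c("read_id", "chromosome", "start",
                                   "strand", "sequence"))
  reads[]
}

#' Parameters for male long-read simulation
#'
#' Lengths are log-normal with median `mean_length` and log-scale sd
#' `sdlog`, clipped to `[min_length, max_length]` — the defaults mirror the
#' 2 kb / 100 kb window used to admit long reads downstream.
#'
#' @param n_reads number of reads; when NULL it is derived from `depth`.
#' @param depth approximate fold-coverage of the male template multiset
#'   (used only when `n_reads` is NULL).
#' @param mean_length median read length in bp.
#' @param sdlog log-scale standard deviation.
#' @param min_length,max_length clip bounds in bp (`min <= max`).
#' @param error_rate i.i.d. per-base substitution rate (long reads default
#'   noisier than short reads).
#' @param mito_copy_multiplier copy number of the mitochondrial contaminant.
#' @param seed integer seed.
#' @return a `long_read_params` list.
#' @export
long_read_params <- function(n_reads = NULL, depth = NULL,
                             mean_length = 8000, sdlog = 0.5,
                             min_length = 2000L, max_length = 100000L,
                             error_rate = 0.01, mito_copy_multiplier = 100,
                             seed = 1L) {
  stopifnot(min_length <= max_length, error_rate >= 0, error_rate < 1)
  if (is.null(n_reads) && is.null(depth))
    stop("supply n_reads or depth")
  structure(list(n_reads = if (is.null(n_reads)) NULL else as.integer(n_reads),
                 depth = depth, mean_length = mean_length, sdlog = sdlog,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 error_rate = error_rate,
                 mito_copy_multiplier = mito_copy_multiplier,
                 seed = as.integer(seed)),
            class = "long_read_params")
}

#' Simulate a male long-read library
#'
#' Reads are sampled from the male template multiset (autosomes x2, X, Y,
#' mito at its multiplier) with log-normal lengths clipped to the stated
#' bounds; a read longer than its template is clipped to the template.
#'
#' @param genome a [build_genome()] result.
#' @param params a [long_read_params()].
#' @return data.table with `read_id`, `chromosome` (origin), `start`,
#'   `strand`, `length`, `sequence`.
#' @export
simulate_long_reads <- function(genome, params) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(params, "long_read_params"))
  set.seed(derive_seed(params$seed, 3L))
  copies <- template_copies(genome, "male", params$mito_copy_multiplier)
  lens <- nchar(genome$sequences)[names(copies)]
  weights <- copies * lens
  n <- params$n_reads
  if (is.null(n)) n <- round(params$depth * sum(weights) / params$mean_length)
  if (n == 0)
    return(data.table(read_id = character(), chromosome = character(),
                      start = integer(), strand = character(),
                      length = integer(), sequence = character()))
  origin <- sample(names(copies), n, replace = TRUE,
                   prob = weights / sum(weights))
  rl <- pmin(pmax(round(rlnorm(n, log(params$mean_length), params$sdlog)),
                  params$min_length), params$max_length)
  rl <- pmin(rl, lens[origin])
  starts <- integer(n)
  seqs <- character(n)
  for (nm in unique(origin)) {
    idx <- which(origin == nm)
    L <- lens[[nm]]
    starts[idx] <- vapply(rl[idx], function(l)
      sample.int(L - l + 1L, 1L), integer(1))
    seqs[idx] <- substring(genome$sequences[[nm]], starts[idx],
                           starts[idx] + rl[idx] - 1L)
  }
  flip <- runif(n) < 0.5
  if (any(flip)) seqs[flip] <- revcomp_cpp(seqs[flip])
  if (params$error_rate > 0) seqs <- mutate_seqs_cpp(seqs, params$error_rate)
  data.table(read_id = sprintf("lr_%06d", seq_len(n)),
             chromosome = origin, start = starts,
             strand = ifelse(flip, "-", "+"),
             length = as.integer(rl), sequence = seqs)
}

#' Kmers specific to planted X clusters
#'
#' Convenience accessors over the ground truth: `x_specific_kmers()` returns
#' codes present on X and absent everywhere else; `cluster_kmers()` returns
#' the canonical kmers occurring inside one planted cluster's span.
#'
#' @param genome a [build_genome()] result.
#' @return numeric vector of canonical kmer codes.
#' @export
x_specific_kmers <- function(genome) {
  genome$truth[count_X > 0 & count_A == 0 & count_Y == 0 & count_mito == 0,
               code]
}

#' @rdname x_specific_kmers
#' @param cluster_name name of a planted cluster.
#' @export
cluster_kmers <- function(genome, cluster_name) {
  cl <- genome$clusters[name == cluster_name]
  if (nrow(cl) != 1) stop("unknown cluster ", cluster_name)
  region <- substr(genome$sequences[[cl$chromosome]], cl$start, cl$end)
  count_canonical_kmers_cpp(region, genome$k)$code
}
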