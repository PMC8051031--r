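#' Pipeline configuration
#'
#' One object drives the whole discovery workflow: simulation (or input
#' paths), census, binning and selection parameters. Every stage draws its
#' randomness from `seed`.
#'
#' @param genome_spec a [genome_spec()] describing the synthetic genome
#'   (the demo workflow; real-data runs supply read files instead through
#'   the stage functions directly).
#' @param depth short-read fold-coverage per haploid template copy, per
#'   sex.
#' @param read_length short-read length in bp.
#' @param error_rate short-read substitution error rate.
#' @param long_read_depth approximate long-read fold-coverage of the male
#'   template.
#' @param long_read_error long-read substitution error rate.
#' @param mito_copy_multiplier mitochondrial template copy number.
#' @param census a [census_params()].
#' @param thresholds a [cq_class_thresholds()].
#' @param min_len,max_len long-read admission window in bp.
#' @param mito_share mitochondrial kmer-share threshold.
#' @param dominance long-read binning dominance threshold.
#' @param xsi_min X-specificity index floor.
#' @param selection a [selection_params()].
#' @param seed master integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome_spec, depth = 20, read_length = 100L,
                            error_rate = 0.002, long_read_depth = 8,
                            long_read_error = 0.01,
                            mito_copy_multiplier = 100,
                            census = census_params(),
                            thresholds = cq_class_thresholds(),
                            min_len = 2000L, max_len = 100000L,
                            mito_share = 0.5, dominance = 0.8,
                            xsi_min = 0.995,
                            selection = selection_params(),
                            seed = 1L) {
  structure(list(genome_spec = genome_spec, depth = depth,
                 read_length = read_length, error_rate = error_rate,
                 long_read_depth = long_read_depth,
                 long_read_error = long_read_error,
                 mito_copy_multiplier = mito_copy_multiplier,
                 census = census, thresholds = thresholds,
                 min_len = min_len, max_len = max_len,
                 mito_share = mito_share, dominance = dominance,
                 xsi_min = xsi_min, selection = selection,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns every violation found (empty character vector when the config
#' is valid), rather than failing at the first.
#'
#' @param config a [pipeline_config()].
#' @return character vector of error messages.
#' @export
validate_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(inherits(config, "pipeline_config"), "not a pipeline_config")
  if (!inherits(config, "pipeline_config")) return(errs)
  chk(inherits(config$genome_spec, "genome_spec"),
      "genome_spec: not a genome_spec object")
  chk(config$depth >= 0, "depth: must be >= 0")
  chk(config$read_length > 35, "read_length: must be > 35")
  chk(config$error_rate >= 0 && config$error_rate < 1,
      "error_rate: must be in [0, 1)")
  chk(config$min_len <= config$max_len, "min_len: must be <= max_len")
  chk(config$mito_share >= 0 && config$mito_share <= 1,
      "mito_share: must be in [0, 1]")
  chk(config$dominance > 0 && config$dominance <= 1,
      "dominance: must be in (0, 1]")
  chk(config$xsi_min >= 0 && config$xsi_min <= 1,
      "xsi_min: must be in [0, 1]")
  chk(inherits(config$census, "census_params"),
      "census: not a census_params object")
  chk(inherits(config$selection, "selection_params"),
      "selection: not a selection_params object")
  if (inherits(config$selection, "selection_params")) {
    chk(config$selection$q > 0, "selection q: must be > 0")
    chk(config$selection$top_n >= 1, "selection top_n: must be >= 1")
  }
  errs
}

#' Run the discovery pipeline end to end on a synthetic design
#'
#' Builds the genome, simulates the sexed short-read libraries and the
#' male long reads, runs census -> CQ classification -> long-read
#' filtering/binning -> XSI candidacy -> percentile ranking -> PAM
#' scanning -> off-target screening -> final table, and returns all stage
#' artifacts plus a run report of per-stage record counts. Identical
#' configurations reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: when given, stage tables are written
#'   as TSV and the report as JSON.
#' @param quiet suppress stage progress messages.
#' @return a `pipeline_run` list: `genome`, `census`, `reads` (binned long
#'   reads), `stats`, `candidates`, `flagged`, `targets`, `report`,
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  say <- function(stage, ...) if (!quiet)
    message("[", stage, "] ", ...)
  k <- config$census$k
  report <- list(parameters = list(
    depth = config$depth, read_length = config$read_length,
    k = k, trimm5 = config$census$trimm5, trimm3 = config$census$trimm3,
    kmernoise = config$census$kmernoise, lsum = config$census$lsum,
    min_len = config$min_len, max_len = config$max_len,
    xsi_min = config$xsi_min, q = config$selection$q,
    top_n = config$selection$top_n, seed = config$seed))

  say("genome", "building synthetic genome")
  genome <- build_genome(config$genome_spec, k = k)
  report$genome <- list(chromosomes = length(genome$sequences),
                        bp = sum(nchar(genome$sequences)),
                        clusters = nrow(genome$clusters))

  say("simulate", "sexed short reads at depth ", config$depth)
  sr <- lapply(c(male = "male", female = "female"), function(sex)
    simulate_short_reads(genome, short_read_params(
      sex = sex, depth = config$depth, read_length = config$read_length,
      error_rate = config$error_rate,
      mito_copy_multiplier = config$mito_copy_multiplier,
      seed = derive_seed(config$seed, if (sex == "male") 11L else 12L))))
  if (!nrow(sr$male) || !nrow(sr$female))
    stop("census: empty ", if (!nrow(sr$male)) "male" else "female",
         " short-read library")
  report$short_reads <- list(male = nrow(sr$male), female = nrow(sr$female))

  say("census", "canonical ", k, "-mer census")
  census <- merge_census(count_kmers(sr$male, config$census),
                         count_kmers(sr$female, config$census),
                         config$census, config$thresholds)
  rm(sr)
  report$census <- list(
    kmers = nrow(census), dropped_noise = attr(census, "dropped"),
    by_class = as.list(table(census$kmer_class)))

  say("longreads", "simulating male long reads")
  lr <- simulate_long_reads(genome, long_read_params(
    depth = config$long_read_depth, min_length = 500L,
    max_length = 200000L, error_rate = config$long_read_error,
    mito_copy_multiplier = config$mito_copy_multiplier,
    seed = derive_seed(config$seed, 13L)))
  # simulator emits a wider length range than the admission window so the
  # length filter has work to do
  lr <- filter_long_reads(lr, config$min_len, config$max_len)
  if ("mito" %in% names(genome$sequences))
    lr <- mito_filter(lr, genome$sequences[["mito"]], config$mito_share, k)
  lr <- bin_long_reads(lr, census, config$dominance, k)
  report$long_reads <- list(
    total = nrow(lr), kept = lr[status == "kept", .N],
    too_short = lr[status == "too_short", .N],
    too_long = lr[status == "too_long", .N],
    mito = lr[status == "mito", .N],
    by_bin = as.list(table(lr[status == "kept", bin])))

  say("stats", "per-kmer long-read statistics for X candidates")
  xc <- census[kmer_class == "X", code]
  stats <- kmer_longread_stats(xc, lr, k)
  candidates <- xsi_filter(stats, census, config$xsi_min,
                           config$census$lsum)
  report$candidates <- list(x_class = length(xc),
                            after_xsi_lsum = nrow(candidates))

  say("select", "percentile ranking and targetability")
  flagged <- percentile_filter(candidates, config$selection, k)
  fl <- flagged[flagged == TRUE]
  # off-target genome: the autosomal and Y-derived long-read bins (GA is
  # excluded — ambiguous reads may be X-derived)
  background <- lr[status == "kept" & bin %in% c("A", "Y"), sequence]
  # screen flagged kmers in rank order, in batches, until top_n survive;
  # the rank-prefix property makes this identical to screening everything
  batch <- max(2L * config$selection$top_n, 50L)
  placements <- list()
  offt <- list()
  survivors <- 0L
  mm_cols <- paste0("mm", 0:config$selection$offtarget_max_mm)
  screen <- function(queue) {
    i <- 1L
    while (i <= length(queue) && survivors < config$selection$top_n) {
      ks <- queue[i:min(i + batch - 1L, length(queue))]
      pl <- rbindlist(list(pam_scan_cas9(ks), pam_scan_cas12a(ks)))
      ot <- offtarget_screen(pl$protospacer, background,
                             config$selection$max_mm)
      placements[[length(placements) + 1L]] <<- pl
      offt[[length(offt) + 1L]] <<- ot
      ok <- rowSums(as.matrix(ot[, mm_cols, with = FALSE])) <=
        config$selection$offtarget_max_hits
      survivors <<- survivors + length(unique(pl$kmer[ok]))
      i <- i + batch
    }
  }
  eligible <- fl$kmer
  screen(eligible)
  if (survivors < config$selection$top_n &&
      config$selection$combine == "intersection") {
    # the intersection ran out of targetable kmers: widen eligibility to
    # the union of the per-criterion top sets, still in rank order
    sel_union <- config$selection
    sel_union$combine <- "rank-sum"
    flagged <- percentile_filter(candidates, sel_union, k)
    extra <- setdiff(flagged[flagged == TRUE, kmer], eligible)
    eligible <- c(eligible, extra)
    screen(extra)
  }
  if (survivors < config$selection$top_n) {
    # percentile pool exhausted before top_n targetable kmers were found:
    # keep walking down the validated candidates in rank-sum order, so the
    # final table is the top_n targetable kmers with the percentile sets
    # screened first
    extra <- setdiff(flagged$kmer, eligible)
    eligible <- c(eligible, extra)
    screen(extra)
  }
  placements <- rbindlist(placements)
  offt <- rbindlist(offt)
  elig_tab <- copy(flagged)[, flagged := kmer %in% eligible]
  targets <- rank_targets(elig_tab, placements, offt, config$selection)
  report$selection <- list(flagged = nrow(fl),
                           placements = nrow(placements),
                           selected_kmers = length(unique(targets$kmer)),
                           selected_rows = nrow(targets))

  run <- structure(list(genome = genome, census = census, reads = lr,
                        stats = stats, candidates = candidates,
                        flagged = flagged, targets = targets,
                        report = report, config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat("discovery pipeline run\n",
      " short reads: ", r$short_reads$male, " male / ",
      r$short_reads$female, " female\n",
      " census kmers: ", r$census$kmers, "\n",
      " long reads kept: ", r$long_reads$kept, " of ", r$long_reads$total,
      "\n",
      " candidates after XSI/LSum: ", r$candidates$after_xsi_lsum, "\n",
      " selected target kmers: ", r$selection$selected_kmers, "\n",
      sep = "")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- run$config$census$k
  write_census_tsv(run$census, file.path(out_dir, "census.tsv"), k)
  fwrite(run$reads[, .(read_id, length, status, bin, hits_X, hits_A,
                       hits_Y)],
         file.path(out_dir, "read_bins.tsv"), sep = "\t")
  st <- copy(run$stats)[, kmer := decode_kmer(code, k)]
  fwrite(st[, .(kmer, hits_sum, max_pt, unique_bin_occurrence, hits_X,
                hits_Y, hits_A, hits_GA, xsi)],
         file.path(out_dir, "kmer_stats.tsv"), sep = "\t")
  fwrite(run$targets, file.path(out_dir, "targets.tsv"), sep = "\t")
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' The packaged demo design
#'
#' The synthetic study conditions used throughout the package's tests and
#' analyses: a ~5 Mb XY genome (3.6 Mb autosome, 1 Mb X, 0.3 Mb Y, 16 kb
#' mitochondrion at 100x copy number; autosome-dominated proportions as in
#' real XY genomes, so library-size normalisation leaves X-linked CQ near
#' 2) carrying, on X, one 1.7-kb-unit
#' array of 50 head-to-tail copies and one 4-kb-unit array of 50 copies
#' whose central block (copies 21-30) is inverted; a shared-unit decoy
#' planted on both X and the autosome; and abundant autosome-only and
#' Y-only background repeats. `scale` shrinks chromosome lengths and
#' cluster copy numbers proportionally for fast multi-seed sweeps.
#'
#' @param seed master seed.
#' @param scale linear shrink factor in (0, 1] applied to chromosome
#'   lengths and copy numbers.
#' @return a [genome_spec()].
#' @export
demo_genome_spec <- function(seed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  n <- function(x) as.integer(round(x * scale))
  cp <- function(x) max(2L, as.integer(round(x * scale)))
  blk <- max(1L, cp(50) %/% 5L)  # central ~fifth of the copies inverted
  inv <- c((cp(50) - blk) %/% 2L + 1L, (cp(50) - blk) %/% 2L + blk)
  genome_spec(
    chromosomes = c(A1 = n(3.6e6), X = n(1e6), Y = n(3e5)),
    mito_length = 16000L, gc = 0.45,
    clusters = list(
      repeat_cluster_spec("x_array_1700", "X", 1700L, cp(50),
                          unit_seed = 101L),
      repeat_cluster_spec("x_array_4000", "X", 4000L, cp(50),
                          inverted_block = inv, unit_seed = 102L),
      repeat_cluster_spec("decoy_X", "X", 1000L, cp(25), unit_seed = 103L),
      repeat_cluster_spec("decoy_A", "A1", 1000L, cp(25),
                          unit_seed = 103L),
      repeat_cluster_spec("a_repeat", "A1", 1200L, cp(30),
                          unit_seed = 104L),
      repeat_cluster_spec("y_repeat", "Y", 800L, cp(30),
                          unit_seed = 105L)),
    seed = seed)
}

#' Demo pipeline configuration
#'
#' @param seed master seed.
#' @param scale see [demo_genome_spec()].
#' @param ... overrides passed to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 1L, scale = 1, ...) {
  pipeline_config(demo_genome_spec(seed = seed, scale = scale),
                  seed = seed, ...)
}
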