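# The full-size demo run is expensive; build it once and share it across
# acceptance blocks. Seed fixed at 1.
demo_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_pipeline(demo_config(seed = 1),
                                              quiet = TRUE))
    cache
  }
})

# uniform sampling of error-free reads from one template sequence; used
# where read origin must be controlled per contig rather than per sex
sample_template_reads <- function(seq, n, read_length = 100L) {
  if (n == 0) return(character())
  starts <- sample.int(nchar(seq) - read_length + 1L, n, replace = TRUE)
  reads <- substring(seq, starts, starts + read_length - 1L)
  flip <- runif(n) < 0.5
  reads[flip] <- revcomp(reads[flip])
  reads
}
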