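# Shared fixtures, all built in code.

toy_layout <- function(n = 1, len = 3e6, peri = NULL, cen = NULL) {
  genome_layout(data.frame(name = paste0("chr", seq_len(n)),
                           length = rep(len, n)),
                pericentromere = peri, centromere = cen)
}

random_intervals <- function(n, chroms = "chr1", max_len = 1e6, seed = 1) {
  set.seed(seed)
  start <- floor(runif(n, 0, max_len - 2000))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + pmax(1, floor(runif(n, 1, 2000))),
             stringsAsFactors = FALSE)
}

# the standard study-conditions dataset, generated once per test run
acceptance_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(seed = 7))
    cache
  }
})

# raw binned_track from explicit count vectors
counts_track <- function(counts, window, chrom = "chr1") {
  v <- stats::setNames(list(as.numeric(counts)), chrom)
  binned_track(v, window, "raw", total = sum(unlist(counts)))
}
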