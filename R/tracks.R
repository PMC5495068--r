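#' Fixed-window binned track
#'
#' Per-chromosome numeric vectors at a fixed window size, with a
#' normalization tag (`raw` fragment counts or `per-million`) and the total
#' fragment count of the originating sample. Undefined bins are `NA` (masked)
#' and are excluded from downstream statistics.
#'
#' @param values named list (one numeric vector per chromosome)
#' @param window window size in bp
#' @param normalization `"raw"` or `"per-million"`
#' @param total total fragment count of the sample the track came from
#' @return object of class `binned_track`
#' @export
binned_track <- function(values, window, normalization = "raw", total = NA) {
  stopifnot(is.list(values), !is.null(names(values)), window >= 1,
            normalization %in% c("raw", "per-million"))
  structure(list(values = values, window = window,
                 normalization = normalization, total = total),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", length(x$values), "chromosome(s), window", x$window,
      "bp,", x$normalization, "\n")
  invisible(x)
}

n_bins <- function(len, window) as.integer(ceiling(len / window))

#' Bin aligned fragments into fixed windows by midpoint
#'
#' Each fragment is assigned to exactly one window by its midpoint,
#' `floor(mid / window)`, so the track conserves the total fragment count per
#' chromosome. Fragments on chromosomes absent from the layout are skipped
#' with a warning reporting how many.
#'
#' @param fragments interval data.frame of aligned fragments
#' @param layout a `genome_layout`
#' @param window window size in bp (>= 1)
#' @return raw-count `binned_track`; `total` is the sample's fragment count
#'   (all fragments, including skipped ones)
#' @export
bin_fragments <- function(fragments, layout, window) {
  stopifnot(window >= 1)
  len <- chrom_lengths(layout)
  known <- fragments$chrom %in% names(len)
  if (!all(known))
    warning(sum(!known), " fragment(s) on unknown chromosomes skipped")
  fr <- fragments[known, , drop = FALSE]
  mid <- floor((fr$start + fr$end) / 2)
  bin <- floor(mid / window) + 1L
  values <- lapply(names(len), function(ch) {
    nb <- n_bins(len[[ch]], window)
    sel <- fr$chrom == ch
    tabulate(pmin(bin[sel], nb), nbins = nb)
  })
  names(values) <- names(len)
  binned_track(values, window, "raw", total = nrow(fragments))
}

#' Scale a raw track to fragments-per-million
#'
#' Multiplies every bin by `1e6 / total`, where `total` is the sample's
#' fragment count; this is the "normalized coverage" used before forming
#' treatment/control ratios.
#' @param track raw `binned_track`
#' @return per-million `binned_track`
#' @export
normalize_per_million <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  if (track$normalization != "raw") stop("track is already normalized")
  if (is.na(track$total) || track$total == 0)
    stop("cannot normalize a track with zero total fragments")
  track$values <- lapply(track$values, function(v) v * 1e6 / track$total)
  track$normalization <- "per-million"
  track
}

#' Log2 treatment/control ratio track
#'
#' `log2((gfp + c) / (igg + c))` per bin on per-million tracks; a bin where
#' both inputs are zero is exactly 0 by construction. This is the
#' periphery-signal track plotted against Hi-C compartments.
#'
#' @param gfp,igg per-million `binned_track`s at the same window
#' @param pseudocount pseudocount `c` in per-million units (default 0.5)
#' @return `binned_track` of log2 ratios (normalization tag `per-million`)
#' @export
log2_ratio <- function(gfp, igg, pseudocount = 0.5) {
  stopifnot(inherits(gfp, "binned_track"), inherits(igg, "binned_track"))
  if (gfp$window != igg$window) stop("window mismatch between tracks")
  if (gfp$normalization != "per-million" || igg$normalization != "per-million")
    stop("log2_ratio expects per-million tracks")
  if (!identical(names(gfp$values), names(igg$values)))
    stop("chromosome mismatch between tracks")
  out <- gfp
  out$values <- Map(function(g, i) log2((g + pseudocount) / (i + pseudocount)),
                    gfp$values, igg$values)
  out$total <- NA
  out
}

#' Convert a binned track to / from bedGraph intervals
#' @param track a `binned_track`
#' @param layout a `genome_layout` (to clip the last window)
#' @return bedGraph data.frame
#' @export
track_to_bedgraph <- function(track, layout) {
  len <- chrom_lengths(layout)
  do.call(rbind, lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    start <- (seq_along(v) - 1) * track$window
    data.frame(chrom = ch, start = start,
               end = pmin(start + track$window, len[[ch]]),
               value = v, stringsAsFactors = FALSE)
  }))
}

#' @rdname track_to_bedgraph
#' @param df bedGraph data.frame aligned to a fixed window grid
#' @param window window size in bp
#' @param normalization tag stored on the resulting track
#' @export
bedgraph_to_track <- function(df, layout, window, normalization = "per-million") {
  len <- chrom_lengths(layout)
  values <- lapply(names(len), function(ch) {
    v <- rep(NA_real_, n_bins(len[[ch]], window))
    sel <- df$chrom == ch
    v[floor(df$start[sel] / window) + 1] <- df$value[sel]
    v
  })
  names(values) <- names(len)
  binned_track(values, window, normalization)
}

#' Sliding-window GC-content track
#'
#' GC fraction in windows of `window` bp advanced by `step` bp, computed per
#' sequence; windows containing `N` are masked (`NA`).
#'
#' @param seqs a [Biostrings::DNAStringSet] named by chromosome
#' @param window window size in bp (default 100)
#' @param step step size in bp (default 20)
#' @return bedGraph-style data.frame (`chrom`, `start`, `end`, `value`);
#'   `value` is the GC fraction, `NA` where the window contains `N`
#' @export
gc_track <- function(seqs, window = 100, step = 20) {
  stopifnot(methods::is(seqs, "DNAStringSet"), window >= 1, step >= 1)
  do.call(rbind, lapply(names(seqs), function(ch) {
    s <- seqs[[ch]]
    if (length(s) < window)
      stop("sequence ", ch, " shorter than one window")
    freq <- Biostrings::letterFrequencyInSlidingView(s, window, c("G", "C", "N"))
    starts <- seq(1, length(s) - window + 1, by = step)
    gc <- (freq[starts, "G"] + freq[starts, "C"]) / window
    gc[freq[starts, "N"] > 0] <- NA
    data.frame(chrom = ch, start = starts - 1, end = starts - 1 + window,
               value = gc, stringsAsFactors = FALSE)
  }))
}
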