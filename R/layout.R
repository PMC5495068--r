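#' Genome layout: chromosome geometry plus heterochromatin landmarks
#'
#' A `genome_layout` bundles the chromosome table with the centromeric and
#' pericentromeric intervals used throughout the pipeline (arm definition,
#' pericentromere-distance filtering, Hi-C arm splitting). All coordinates are
#' 0-based, half-open, in bp.
#'
#' @param chromosomes data.frame with columns `name` (unique character) and
#'   `length` (bp). Chromosome order is preserved.
#' @param pericentromere data.frame with columns `chrom`, `start`, `end`
#'   (at most one row per chromosome). Chromosomes without a row, or with
#'   `start == end`, have no pericentromere. May be `NULL`.
#' @param centromere same shape as `pericentromere`; each centromere must lie
#'   within the pericentromere of its chromosome. May be `NULL`.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, pericentromere = NULL, centromere = NULL) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  norm_landmark <- function(x, what) {
    if (is.null(x) || nrow(x) == 0) return(empty)
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    x <- x[, c("chrom", "start", "end")]
    x$chrom <- as.character(x$chrom)
    if (anyDuplicated(x$chrom))
      stop("at most one ", what, " interval per chromosome")
    if (!all(x$chrom %in% chromosomes$name))
      stop(what, " on unknown chromosome")
    len <- chromosomes$length[match(x$chrom, chromosomes$name)]
    if (any(x$start < 0) || any(x$end > len) || any(x$start > x$end))
      stop(what, " interval outside [0, chromosome length)")
    x[x$end > x$start, , drop = FALSE]
  }
  peri <- norm_landmark(pericentromere, "pericentromere")
  cen <- norm_landmark(centromere, "centromere")
  # every centromere must be contained in its chromosome's pericentromere
  if (nrow(cen)) {
    i <- match(cen$chrom, peri$chrom)
    if (anyNA(i) || any(cen$start < peri$start[i]) || any(cen$end > peri$end[i]))
      stop("centromere must be contained in the pericentromere")
  }
  structure(list(chromosomes = chromosomes,
                 pericentromere = peri,
                 centromere = cen),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Named vector of chromosome lengths
#' @param layout a `genome_layout`
#' @return named numeric vector (bp)
#' @export
chrom_lengths <- function(layout) {
  stats::setNames(layout$chromosomes$length, layout$chromosomes$name)
}

#' Chromosome-arm intervals (everything outside the pericentromere)
#' @param layout a `genome_layout`
#' @return interval data.frame (`chrom`, `start`, `end`), 0-based half-open
#' @export
arm_intervals <- function(layout) {
  whole <- data.frame(chrom = layout$chromosomes$name, start = 0,
                      end = layout$chromosomes$length, stringsAsFactors = FALSE)
  if (nrow(layout$pericentromere) == 0) return(whole)
  interval_setdiff(whole, layout$pericentromere)
}

#' Write / read a genome layout as TSV
#'
#' One row per chromosome: name, length, pericentromere start/end and
#' centromere start/end (-1 for absent landmarks).
#' @param layout a `genome_layout`
#' @param path file path
#' @export
write_layout <- function(layout, path) {
  pick <- function(tab, chrom, col) {
    i <- match(chrom, tab$chrom)
    ifelse(is.na(i), -1, tab[[col]][i])
  }
  ch <- layout$chromosomes
  out <- data.frame(name = ch$name, length = ch$length,
                    peri_start = pick(layout$pericentromere, ch$name, "start"),
                    peri_end = pick(layout$pericentromere, ch$name, "end"),
                    cen_start = pick(layout$centromere, ch$name, "start"),
                    cen_end = pick(layout$centromere, ch$name, "end"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  mk <- function(s, e) {
    keep <- s >= 0 & e >= 0
    data.frame(chrom = x$name[keep], start = s[keep], end = e[keep],
               stringsAsFactors = FALSE)
  }
  genome_layout(data.frame(name = x$name, length = x$length),
                pericentromere = mk(x$peri_start, x$peri_end),
                centromere = mk(x$cen_start, x$cen_end))
}

## ---- internal interval plumbing ------------------------------------------
## Intervals travel as data.frames (chrom/start/end, 0-based half-open);
## algebra is delegated to IRanges/GenomicRanges via these converters.

as_granges <- function(df, layout = NULL) {
  seqinfo <- NULL
  if (!is.null(layout))
    seqinfo <- GenomeInfoDb::Seqinfo(seqnames = layout$chromosomes$name,
                                      seqlengths = layout$chromosomes$length)
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[is.na(s) | s == "."] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand)
  if (!is.null(seqinfo))
    GenomeInfoDb::seqinfo(gr) <- seqinfo[as.character(GenomeInfoDb::seqlevels(gr))]
  gr
}

granges_to_df <- function(gr, strand = FALSE) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (strand) {
    s <- as.character(GenomicRanges::strand(gr))
    s[s == "*"] <- "."
    df$strand <- s
  }
  df
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

interval_union <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- granges_to_df(GenomicRanges::reduce(as_granges(df)))
  rownames(out) <- NULL
  sort_intervals(out)
}

pair_granges <- function(a, b) {
  ga <- as_granges(a)
  gb <- as_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(ga, gb)
}

interval_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  gr <- pair_granges(a, b)
  out <- granges_to_df(GenomicRanges::intersect(gr[[1]], gr[[2]],
                                                ignore.strand = TRUE))
  rownames(out) <- NULL
  sort_intervals(out)
}

interval_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0) return(interval_union(a))
  gr <- pair_granges(a, b)
  out <- granges_to_df(GenomicRanges::setdiff(gr[[1]], gr[[2]],
                                              ignore.strand = TRUE))
  rownames(out) <- NULL
  sort_intervals(out)
}

interval_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(interval_union(df)$end - interval_union(df)$start)
}

#' Base-pair Jaccard index between two interval sets
#'
#' |A intersect B| / |A union B| at single-bp resolution, the standard metric
#' for agreement between two domain calls.
#' @param a,b interval data.frames (`chrom`, `start`, `end`)
#' @return numeric in \[0, 1\] (1 when both sets are empty)
#' @export
bp_jaccard <- function(a, b) {
  inter <- interval_bp(interval_intersect(a, b))
  uni <- interval_bp(interval_union(rbind(a[, c("chrom", "start", "end")],
                                          b[, c("chrom", "start", "end")])))
  if (uni == 0) return(1)
  inter / uni
}
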