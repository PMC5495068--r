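#' Boundary-anchored metaprofile around domain borders
#'
#' For every domain boundary, 100-bp windows are laid out from `-flank` to
#' `+flank`, oriented so that positive positions point into the domain (left
#' boundaries read left-to-right, right boundaries are mirrored). For a
#' binary mark (interval data.frame without a `value` column) the window
#' value is 1 iff the window overlaps any mark region, so the profile is the
#' percent of boundaries enriched per position; for a numeric 100-bp track
#' (bedGraph data.frame with `value`) it is the mean window value. Boundaries
#' whose flank leaves the chromosome are dropped.
#'
#' @param x mark intervals or numeric bedGraph-style data.frame
#' @param domains interval data.frame
#' @param layout a `genome_layout`
#' @param flank flank size in bp (default 20 kb)
#' @param window window size in bp (default 100)
#' @return data.frame of class `meta_profile` with `position` (bp relative to
#'   the boundary, window midpoints, positive = inside), `mean`, `n`
#' @export
boundary_profile <- function(x, domains, layout, flank = 20000, window = 100) {
  len <- chrom_lengths(layout)
  offs <- seq(-flank, flank - window, by = window)
  binary <- !("value" %in% names(x))

  bounds <- rbind(
    data.frame(chrom = domains$chrom, pos = domains$start, dir = 1),
    data.frame(chrom = domains$chrom, pos = domains$end, dir = -1))
  ok <- bounds$pos - flank >= 0 & bounds$pos + flank <= len[bounds$chrom]
  bounds <- bounds[ok, , drop = FALSE]
  if (nrow(bounds) == 0) stop("no usable domain boundaries")

  nb <- nrow(bounds)
  nw <- length(offs)
  # genomic window starts for all (boundary, offset) pairs; dir mirrors right
  # boundaries so positive offsets always point into the domain
  gs <- rep(bounds$pos, each = nw) +
    ifelse(rep(bounds$dir, each = nw) == 1, rep(offs, nb),
           -rep(offs, nb) - window)
  wins <- data.frame(chrom = rep(bounds$chrom, each = nw),
                     start = gs, end = gs + window)
  if (binary) {
    vals <- as.numeric(overlap_fraction(wins, x) > 0)
  } else {
    # numeric track lookup: value of the track interval containing the
    # window midpoint
    q <- wins
    q$start <- floor((wins$start + wins$end) / 2)
    q$end <- q$start + 1
    hits <- GenomicRanges::findOverlaps(as_granges(q), as_granges(x),
                                        ignore.strand = TRUE, select = "first")
    vals <- x$value[hits]
  }
  m <- matrix(vals, nrow = nw)
  out <- data.frame(position = offs + window / 2,
                    mean = rowMeans(m, na.rm = TRUE),
                    n = rowSums(!is.na(m)))
  class(out) <- c("meta_profile", "data.frame")
  attr(out, "anchor") <- "domain_boundary"
  out
}

#' Length-normalised profile over feature bodies
#'
#' Linearly transforms each feature so that its boundaries align: the body is
#' divided into `bins` equal parts and the value of a part is the mean of the
#' 100-bp track windows overlapping it, so every feature contributes to every
#' bin regardless of length. Minus-strand features are reversed. Features
#' shorter than two track windows are skipped and counted.
#'
#' @param track bedGraph-style data.frame of per-window values (e.g.
#'   methylation ratios in 100-bp windows)
#' @param features interval data.frame (TE bodies) with optional `strand`
#' @param bins number of body bins S (default 40)
#' @return data.frame of class `meta_profile` with `position` (scaled units,
#'   bin midpoints in (0, 1)), `mean` (across features), `n`; attribute
#'   `n_skipped`
#' @export
scaled_body_profile <- function(track, features, bins = 40) {
  stopifnot(nrow(features) >= 1, bins >= 1)
  win <- stats::median(track$end - track$start)
  short <- (features$end - features$start) < 2 * win
  n_skipped <- sum(short)
  features <- features[!short, , drop = FALSE]
  if (nrow(features) == 0) stop("all features shorter than two track windows")

  tg <- as_granges(track)
  acc <- matrix(0, nrow(features), bins)
  cnt <- matrix(0, nrow(features), bins)
  for (i in seq_len(nrow(features))) {
    L <- features$end[i] - features$start[i]
    edges <- features$start[i] + L * (0:bins) / bins
    bdf <- data.frame(chrom = features$chrom[i],
                      start = floor(edges[-(bins + 1)]),
                      end = ceiling(edges[-1]))
    hits <- GenomicRanges::findOverlaps(as_granges(bdf), tg,
                                        ignore.strand = TRUE)
    v <- tapply(track$value[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_len(bins)),
                mean, na.rm = TRUE)
    v <- as.numeric(v)
    if (!is.null(features$strand) && features$strand[i] == "-") v <- rev(v)
    got <- !is.na(v)
    acc[i, got] <- v[got]
    cnt[i, got] <- 1
  }
  n <- colSums(cnt)
  out <- data.frame(position = ((seq_len(bins)) - 0.5) / bins,
                    mean = ifelse(n > 0, colSums(acc) / n, NA_real_),
                    n = n)
  class(out) <- c("meta_profile", "data.frame")
  attr(out, "anchor") <- "scaled_body"
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Split TEs by nuclear location
#'
#' Peripheral iff strictly more than 80% of the TE span lies inside the
#' domain set (the same rule as gene enrichment); the two groups partition
#' the input.
#' @param tes interval data.frame of TE bodies
#' @param domains interval data.frame
#' @return list with `peripheral` and `interior` data.frames
#' @export
group_tes_by_location <- function(tes, domains) {
  flag <- overlap_fraction(tes, domains) > 0.8
  list(peripheral = tes[flag, , drop = FALSE],
       interior = tes[!flag, , drop = FALSE])
}

#' Contrast a mutant metaprofile against wild type
#'
#' Per-bin difference (mutant - WT), ratio with pseudocount 0.01, and the
#' mean body-bin difference as a one-number summary of methylation loss.
#' @param profile_wt,profile_mutant `meta_profile`s on the same axis
#' @return list with `position`, `difference`, `ratio`, `mean_difference`
#' @export
genotype_contrast <- function(profile_wt, profile_mutant) {
  if (!isTRUE(all.equal(profile_wt$position, profile_mutant$position)))
    stop("profile axis mismatch")
  diff <- profile_mutant$mean - profile_wt$mean
  list(position = profile_wt$position,
       difference = diff,
       ratio = (profile_mutant$mean + 0.01) / (profile_wt$mean + 0.01),
       mean_difference = mean(diff, na.rm = TRUE))
}
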