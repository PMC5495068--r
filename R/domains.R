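#' Island-calling parameters
#'
#' The broad-domain caller follows the SICER island framework: fixed windows
#' of `W` bp, eligible windows chained across ineligible gaps of at most `G`
#' bp, islands scored against a Poisson background and filtered at a
#' Benjamini-Hochberg FDR. Defaults are the study settings W = 1000,
#' G = 3000, FDR < 0.01.
#'
#' @param W window size in bp (>= 1)
#' @param G maximum ineligible gap in bp (must be a multiple of W)
#' @param fdr island q-value threshold (0 < fdr < 1)
#' @param p_elig one-sided Poisson p-value below which a window is eligible
#' @return list of class `island_params`
#' @export
island_params <- function(W = 1000, G = 3000, fdr = 0.01, p_elig = 0.2) {
  stopifnot(W >= 1, G >= 0, G %% W == 0, fdr > 0, fdr < 1,
            p_elig > 0, p_elig <= 1)
  structure(list(W = W, G = G, fdr = fdr, p_elig = p_elig),
            class = "island_params")
}

#' Call broad enriched islands from windowed counts
#'
#' SICER-style calling on raw-count tracks at window `W`:
#' \enumerate{
#'   \item A window is eligible iff the one-sided Poisson upper-tail
#'     probability of its ChIP count under the genome-wide mean count per
#'     window (`lambda_bg`) is below `p_elig`.
#'   \item Islands are maximal runs of eligible windows in which consecutive
#'     eligible windows are separated by at most `G` bp of ineligible
#'     windows; the island spans first to last eligible window, internal gaps
#'     included.
#'   \item The island p-value is the Poisson upper tail of the aggregate ChIP
#'     count with mean `max(depth-scaled aggregate control count,
#'     lambda_bg * windows in span)`.
#'   \item Benjamini-Hochberg q-values across all islands; islands with
#'     `q < fdr` are kept.
#' }
#' Control depth is rescaled internally to the ChIP depth, so the output is
#' invariant under uniform rescaling of the control library. An entirely
#' empty control triggers a background-only test with a warning.
#'
#' @param chip,control raw `binned_track`s at window `W` (GFP pulldown and
#'   IgG control)
#' @param layout a `genome_layout`
#' @param params an `island_params`
#' @return data.frame of islands passing the FDR filter: `chrom`, `start`,
#'   `end`, `chip_count`, `control_scaled`, `score` (sum of -log window
#'   p-values), `pvalue`, `qvalue`
#' @export
call_islands <- function(chip, control = NULL, layout, params = island_params()) {
  stopifnot(inherits(chip, "binned_track"), chip$normalization == "raw",
            chip$window == params$W)
  chip_total <- sum(unlist(chip$values))
  if (chip_total == 0) stop("empty ChIP track")
  no_control <- is.null(control) || sum(unlist(control$values)) == 0
  if (no_control) {
    warning("empty control: islands tested against background only")
    scale <- 0
  } else {
    stopifnot(control$window == params$W, control$normalization == "raw")
    scale <- chip_total / sum(unlist(control$values))
  }
  lambda_bg <- chip_total / sum(lengths(chip$values))
  gap_win <- params$G / params$W

  islands <- list()
  for (ch in names(chip$values)) {
    counts <- chip$values[[ch]]
    ctrl <- if (no_control) rep(0, length(counts)) else control$values[[ch]]
    win_p <- stats::ppois(counts - 1, lambda_bg, lower.tail = FALSE)
    elig <- which(win_p < params$p_elig)
    if (length(elig) == 0) next
    grp <- cumsum(c(1, diff(elig) > gap_win + 1))
    for (g in unique(grp)) {
      idx <- elig[grp == g]
      first <- idx[1]; last <- idx[length(idx)]
      nwin <- last - first + 1
      agg <- sum(counts[first:last])
      ctrl_scaled <- scale * sum(ctrl[first:last])
      mu <- max(ctrl_scaled, lambda_bg * nwin)
      islands[[length(islands) + 1]] <- data.frame(
        chrom = ch,
        start = (first - 1) * params$W,
        end = min(last * params$W, chrom_lengths(layout)[[ch]]),
        chip_count = agg,
        control_scaled = ctrl_scaled,
        score = sum(-log(win_p[idx])),
        pvalue = stats::ppois(agg - 1, mu, lower.tail = FALSE))
    }
  }
  if (length(islands) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      chip_count = numeric(), control_scaled = numeric(),
                      score = numeric(), pvalue = numeric(), qvalue = numeric()))
  out <- do.call(rbind, islands)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[out$qvalue < params$fdr, , drop = FALSE]
  out <- sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Intersect replicate domain calls
#'
#' Base-pair-level intersection of two interval sets: the periphery-associated
#' domains are the regions shared between both replicates.
#' @param rep1,rep2 interval data.frames (replicate island calls)
#' @return sorted, non-overlapping interval data.frame with attribute
#'   `provenance = "intersected"`
#' @export
intersect_replicates <- function(rep1, rep2) {
  out <- interval_intersect(rep1, rep2)
  rownames(out) <- NULL
  attr(out, "provenance") <- "intersected"
  out
}

#' Summarise a domain set
#'
#' @param domains interval data.frame (intersected domains)
#' @param layout a `genome_layout`
#' @return list with `count`, `genome_coverage` and `arm_coverage`
#'   (fractions), `median_length` (bp; `NA` for an empty set)
#' @export
domain_summary <- function(domains, layout) {
  genome_bp <- sum(layout$chromosomes$length)
  arms <- arm_intervals(layout)
  lens <- domains$end - domains$start
  list(count = nrow(domains),
       genome_coverage = interval_bp(domains) / genome_bp,
       arm_coverage = interval_bp(interval_intersect(domains, arms)) /
         sum(arms$end - arms$start),
       median_length = if (nrow(domains)) stats::median(lens) else NA_real_)
}

#' Flag genes enriched at the nuclear periphery
#'
#' A gene is enriched iff strictly more than 80% of its transcribed region
#' (full annotated span) overlaps the domain set.
#' @param genes annotation data.frame
#' @param domains non-overlapping interval data.frame
#' @param threshold overlap fraction that must be exceeded (default 0.8)
#' @return logical vector, one flag per gene
#' @export
assign_enriched_genes <- function(genes, domains, threshold = 0.8) {
  overlap_fraction(genes, domains) > threshold
}

#' Filter intervals by distance from pericentromeric heterochromatin
#'
#' Keeps items located at least `min_dist` bp from the pericentromere of
#' their chromosome (inclusive: a gap of exactly `min_dist` is kept); items
#' overlapping the pericentromere are removed. Chromosomes without a
#' pericentromere keep all their items.
#'
#' @param items interval data.frame
#' @param layout a `genome_layout`
#' @param min_dist minimum distance in bp (default 1 Mb)
#' @return filtered data.frame (original columns preserved)
#' @export
filter_pericentromere_distance <- function(items, layout, min_dist = 1e6) {
  peri <- layout$pericentromere
  i <- match(items$chrom, peri$chrom)
  dist <- ifelse(is.na(i), Inf,
          ifelse(items$end <= peri$start[i], peri$start[i] - items$end,
          ifelse(items$start >= peri$end[i], items$start - peri$end[i], 0)))
  drop_overlap <- !is.na(i) & items$start < peri$end[i] & items$end > peri$start[i]
  items[!drop_overlap & dist >= min_dist, , drop = FALSE]
}

#' Overlap counts across tissues (Venn input)
#'
#' Counts members of every intersection cell of two or more named sets (e.g.
#' enriched-gene sets per tissue). Cells are labelled by the tissue
#' combination (`&`-joined names) and sum to the union size.
#' @param sets named list (>= 2) of character vectors
#' @return data.frame with `combination` and `count`
#' @export
tissue_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  counts <- table(factor(key, levels = combos))
  data.frame(combination = names(counts), count = as.integer(counts),
             row.names = NULL)
}

#' Call periphery-associated domains from two fragment replicates
#'
#' Convenience wrapper: bins GFP and IgG fragments at `W`, calls islands per
#' replicate and intersects the replicate calls.
#' @param gfp1,gfp2,igg1,igg2 fragment interval data.frames
#' @param layout a `genome_layout`
#' @param params an `island_params`
#' @return list with `rep1`, `rep2` (island data.frames) and `domains`
#'   (intersected interval data.frame)
#' @export
call_domains <- function(gfp1, igg1, gfp2, igg2, layout,
                         params = island_params()) {
  bin <- function(fr) bin_fragments(fr, layout, params$W)
  rep1 <- call_islands(bin(gfp1), bin(igg1), layout, params)
  rep2 <- call_islands(bin(gfp2), bin(igg2), layout, params)
  list(rep1 = rep1, rep2 = rep2,
       domains = intersect_replicates(rep1, rep2))
}
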