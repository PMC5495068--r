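#' Shift domains by random +/- 50/100-kb offsets
#'
#' The permutation null used for all domain-association statistics: each
#' domain is translated by a magnitude drawn from `magnitudes` with a random
#' sign. Shifted null sets keep the genome-wide distribution pattern of the
#' observed domains, unlike a uniform shuffle. A domain pushed past a
#' chromosome edge is mirrored back inside, so count and length multiset are
#' always preserved; overlaps created by shifting are left as-is.
#'
#' @param domains interval data.frame
#' @param layout a `genome_layout`
#' @param magnitudes allowed shift magnitudes in bp (default 50 kb, 100 kb)
#' @param seed optional seed
#' @return shifted, re-sorted interval data.frame
#' @export
shift_domains <- function(domains, layout, magnitudes = c(5e4, 1e5),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(domains)
  if (n == 0) return(domains)
  len <- chrom_lengths(layout)[domains$chrom]
  width <- domains$end - domains$start
  if (any(width > len)) stop("domain longer than its chromosome")
  shift <- magnitudes[sample.int(length(magnitudes), n, replace = TRUE)] *
    sample(c(-1, 1), n, replace = TRUE)
  s <- domains$start + shift
  e <- domains$end + shift
  # mirror intervals that left the chromosome back inside
  left <- e <= 0
  s[left] <- -e[left]
  e[left] <- s[left] + width[left]
  right <- s >= len
  e[right] <- 2 * len[right] - s[right]
  s[right] <- e[right] - width[right]
  # straddling cases: clamp to the nearest edge, length preserved
  s <- pmax(0, pmin(s, len - width))
  e <- s + width
  out <- domains
  out$start <- s
  out$end <- e
  out <- sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Count enriched genes of a biotype inside domains
#'
#' Applies the strict >80% transcribed-region overlap rule and counts the
#' genes of the requested biotype that pass it.
#' @param genes annotation data.frame
#' @param domains interval data.frame
#' @param biotype biotype filter (`"TE_gene"`, `"protein_coding"`,
#'   `"pseudogene"`), or `NULL` for all
#' @return integer count
#' @export
count_genes_in_domains <- function(genes, domains, biotype = NULL) {
  sel <- if (is.null(biotype)) rep(TRUE, nrow(genes)) else genes$biotype == biotype
  if (!any(sel)) return(0L)
  sum(assign_enriched_genes(genes[sel, , drop = FALSE], domains))
}

#' Coordinate-shift permutation test
#'
#' Builds a null distribution for any domain-set statistic by recomputing it
#' on `n_perm` independently shifted domain sets (per-domain sign and
#' magnitude redrawn each round) and returns empirical p-values with the +1
#' correction, so p is never 0.
#'
#' @param statistic function taking a domain interval data.frame and
#'   returning a single number
#' @param domains observed domain set
#' @param layout a `genome_layout`
#' @param n_perm number of permutations (default 999)
#' @param magnitudes shift magnitudes in bp
#' @param seed optional seed
#' @return list of class `shift_null`: `observed`, `null` (length `n_perm`),
#'   `p_greater`, `p_less`, `p_two_sided`, `magnitudes`, `n_perm`, `seed`
#' @export
permutation_test <- function(statistic, domains, layout, n_perm = 999,
                             magnitudes = c(5e4, 1e5), seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic(domains)
  null <- vapply(seq_len(n_perm), function(i) {
    shifted <- shift_domains(domains, layout, magnitudes)
    res <- tryCatch(statistic(shifted), error = function(e)
      stop("statistic failed on permutation ", i, ": ", conditionMessage(e)))
    as.numeric(res)
  }, numeric(1))
  p_greater <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_less <- (1 + sum(null <= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null,
                 p_greater = p_greater, p_less = p_less,
                 p_two_sided = min(1, 2 * min(p_greater, p_less)),
                 magnitudes = magnitudes, n_perm = n_perm, seed = seed),
            class = "shift_null")
}

#' @export
print.shift_null <- function(x, ...) {
  cat("shift-permutation null: observed =", x$observed,
      "| null mean =", signif(mean(x$null), 4),
      "| p(greater) =", signif(x$p_greater, 4), "\n")
  invisible(x)
}

#' Classify chromatin loops relative to domains
#'
#' An anchor belongs to a domain when more than half of its bp lie inside
#' that domain (domains are non-overlapping, so at most one qualifies).
#' Loops are `intra` when both anchors belong to the same domain, `across`
#' when exactly one anchor belongs to a domain or the anchors belong to
#' different domains, and `outside` otherwise. Trans-chromosomal loops are
#' excluded and counted.
#'
#' @param loops BEDPE data.frame
#' @param domains sorted non-overlapping interval data.frame
#' @return list with `intra`, `across`, `outside`, `total` (cis loops) and
#'   `n_trans`
#' @export
classify_loops <- function(loops, domains) {
  cis <- loops$chrom1 == loops$chrom2
  n_trans <- sum(!cis)
  loops <- loops[cis, , drop = FALSE]

  anchor_domain <- function(chrom, start, end) {
    anchors <- data.frame(chrom = chrom, start = start, end = end)
    if (nrow(domains) == 0 || nrow(anchors) == 0)
      return(rep(NA_integer_, nrow(anchors)))
    a <- as_granges(anchors)
    d <- as_granges(domains)
    hits <- GenomicRanges::findOverlaps(a, d, ignore.strand = TRUE)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      a[S4Vectors::queryHits(hits)], d[S4Vectors::subjectHits(hits)]))
    member <- rep(NA_integer_, nrow(anchors))
    frac <- ov / (end - start)[S4Vectors::queryHits(hits)]
    good <- frac > 0.5
    member[S4Vectors::queryHits(hits)[good]] <- S4Vectors::subjectHits(hits)[good]
    member
  }
  d1 <- anchor_domain(loops$chrom1, loops$start1, loops$end1)
  d2 <- anchor_domain(loops$chrom2, loops$start2, loops$end2)
  intra <- sum(!is.na(d1) & !is.na(d2) & d1 == d2)
  outside <- sum(is.na(d1) & is.na(d2))
  total <- nrow(loops)
  list(intra = intra, across = total - intra - outside, outside = outside,
       total = total, n_trans = n_trans)
}

#' Mann-Whitney rank-sum comparison of two expression groups
#'
#' U statistic with midranks for ties; the p-value uses the tie-corrected
#' normal approximation with continuity correction, or exact enumeration when
#' the combined sample size is at most 12 and there are no ties.
#'
#' @param a,b numeric vectors (each nonempty)
#' @return list with `U` and `p` (two-sided)
#' @export
rank_sum_compare <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, exact = (length(a) + length(b) <= 12) && !ties, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Expression-matched control gene set
#'
#' Samples `n` control genes from the non-enriched pool with the same
#' expression distribution profile as the enriched genes: enriched
#' expressions are split into `n_bins` quantile bins and controls are drawn
#' per bin proportionally to bin occupancy, without replacement (falling back
#' to replacement, with a message, only when a bin's pool is exhausted).
#'
#' @param genes annotation data.frame with `gene_id` and `expression`
#' @param enriched logical vector flagging enriched genes
#' @param n number of control genes (default 3000)
#' @param n_bins number of expression quantile bins (default 20)
#' @param seed optional seed
#' @return character vector of control gene ids
#' @export
matched_control_genes <- function(genes, enriched, n = 3000, n_bins = 20,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(enriched) == nrow(genes))
  expr_e <- genes$expression[enriched]
  pool <- genes[!enriched, , drop = FALSE]
  if (nrow(pool) == 0) stop("non-enriched pool is empty")
  if (length(expr_e) == 0) stop("no enriched genes to match")
  if (n_bins > length(unique(expr_e))) {
    n_bins <- max(1, length(unique(expr_e)) - 1)
    warning("reducing to ", n_bins, " expression bins")
  }
  breaks <- unique(stats::quantile(expr_e, probs = seq(0, 1, length.out = n_bins + 1)))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  occ <- table(cut(expr_e, breaks))
  target <- floor(as.numeric(occ) / length(expr_e) * n)
  # distribute the rounding remainder to the fullest bins
  rem <- n - sum(target)
  if (rem > 0) {
    extra <- order(as.numeric(occ) / length(expr_e) * n - target,
                   decreasing = TRUE)[seq_len(rem)]
    target[extra] <- target[extra] + 1
  }
  pool_bin <- cut(pool$expression, breaks)
  ids <- character(0)
  for (k in seq_along(target)) {
    if (target[k] == 0) next
    cand <- pool$gene_id[as.integer(pool_bin) == k]
    if (length(cand) >= target[k]) {
      ids <- c(ids, sample(cand, target[k]))
    } else {
      message("expression bin ", k, " pool exhausted; sampling with replacement")
      ids <- c(ids, cand,
               if (length(cand)) sample(cand, target[k] - length(cand),
                                        replace = TRUE) else character(0))
    }
  }
  ids
}
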