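#' Split a Hi-C matrix into chromosome-arm submatrices
#'
#' Arm bins are bins lying entirely left (or right) of the pericentromere;
#' bins overlapping the pericentromere belong to neither arm. Arms with fewer
#' than 10 bins are skipped with a warning.
#'
#' @param mat square contact matrix for one chromosome (attribute `binsize`
#'   or explicit `binsize` argument)
#' @param layout a `genome_layout`
#' @param chrom chromosome name
#' @param binsize bin size in bp
#' @return named list of arms (`left`, `right` as available), each a list
#'   with `matrix` and `bins` (1-based bin indices into the full matrix)
#' @export
split_arms <- function(mat, layout, chrom, binsize = attr(mat, "binsize")) {
  stopifnot(!is.null(binsize))
  n <- nrow(mat)
  peri <- layout$pericentromere
  i <- match(chrom, peri$chrom)
  starts <- (seq_len(n) - 1) * binsize
  ends <- starts + binsize
  if (is.na(i)) {
    sides <- list(left = seq_len(n))
  } else {
    sides <- list(left = which(ends <= peri$start[i]),
                  right = which(starts >= peri$end[i]))
  }
  out <- list()
  for (s in names(sides)) {
    bins <- sides[[s]]
    if (length(bins) == 0) next
    if (length(bins) < 10) {
      warning("arm ", s, " of ", chrom, " has fewer than 10 bins; skipped")
      next
    }
    m <- mat[bins, bins, drop = FALSE]
    attr(m, "binsize") <- binsize
    out[[s]] <- list(matrix = m, bins = bins)
  }
  out
}

#' Spearman correlation matrix of a contact matrix
#'
#' Entry (i, j) is the Spearman rank correlation of rows i and j, computed
#' over unmasked bins with the columns i and j themselves excluded (so the
#' raw diagonal never enters the rank vectors). Rows that are entirely
#' missing or have zero variance are masked (`NA` row/column); the output has
#' a unit diagonal on unmasked bins.
#'
#' @param mat square symmetric contact matrix (NA cells allowed)
#' @return symmetric correlation matrix with `NA` rows/cols for masked bins
#' @export
spearman_matrix <- function(mat) {
  n <- nrow(mat)
  stopifnot(n == ncol(mat), n >= 10)
  masked <- vapply(seq_len(n), function(i) {
    v <- mat[i, ]
    all(is.na(v)) || stats::var(v, na.rm = TRUE) == 0
  }, logical(1))
  if (all(masked)) stop("all rows constant or missing")
  good <- which(!masked)
  out <- matrix(NA_real_, n, n)
  for (a in seq_along(good)) {
    i <- good[a]
    out[i, i] <- 1
    for (b in seq_len(a - 1L)) {
      j <- good[b]
      keep <- setdiff(good, c(i, j))
      x <- mat[i, keep]; y <- mat[j, keep]
      ok <- !is.na(x) & !is.na(y)
      rho <- suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
      out[i, j] <- out[j, i] <- rho
    }
  }
  out
}

#' First principal component of a correlation matrix
#'
#' Scores are the projection of the (column-centered) correlation matrix onto
#' its leading principal axis; masked bins are reinserted as `NA`. The
#' underlying eigenvector is checked against the eigen-equation to 1e-8.
#'
#' @param cmat correlation matrix as from [spearman_matrix()]
#' @return list with `scores` (length `nrow(cmat)`, `NA` on masked bins),
#'   `vector` (leading eigenvector over unmasked bins), `lambda`
#' @export
pc1 <- function(cmat) {
  n <- nrow(cmat)
  masked <- apply(cmat, 1, function(v) all(is.na(v)))
  m <- cmat[!masked, !masked, drop = FALSE]
  if (nrow(m) < 3) stop("too few unmasked bins for PCA")
  centered <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  v <- sv$v[, 1]
  lambda <- sv$d[1]^2
  resid <- sqrt(sum((crossprod(centered) %*% v - lambda * v)^2))
  if (resid > 1e-8 * max(1, lambda))
    stop("PCA eigen-equation residual too large: ", format(resid))
  scores <- rep(NA_real_, n)
  scores[!masked] <- as.numeric(centered %*% v)
  list(scores = scores, vector = v, lambda = lambda)
}

#' Orient PC1 by the periphery signal and label compartments
#'
#' The sign of PC1 is chosen so its Spearman correlation with the periphery
#' signal (log2 GFP/IgG at the same binning) is nonnegative; bins with
#' oriented PC1 > 0 are labeled `peripheral-like`, the rest `interior-like`.
#'
#' @param scores PC1 scores (NA on masked bins)
#' @param signal numeric periphery-signal values on the same bins
#' @return list of class `compartment_result`: `scores` (oriented), `labels`
#'   (`peripheral-like` / `interior-like` / `NA`), `rho` (Spearman correlation
#'   of oriented PC1 with the signal), `flipped`
#' @export
orient_and_label <- function(scores, signal) {
  stopifnot(length(scores) == length(signal))
  ok <- !is.na(scores) & !is.na(signal)
  rho <- suppressWarnings(stats::cor(scores[ok], signal[ok],
                                     method = "spearman"))
  flipped <- FALSE
  if (is.na(rho)) {
    warning("correlation with signal undefined; keeping PC1 orientation")
    rho <- NA_real_
  } else if (rho < 0) {
    scores <- -scores
    rho <- -rho
    flipped <- TRUE
  }
  labels <- ifelse(is.na(scores), NA_character_,
                   ifelse(scores > 0, "peripheral-like", "interior-like"))
  structure(list(scores = scores, labels = labels, rho = rho,
                 flipped = flipped),
            class = "compartment_result")
}

#' Per-arm compartment analysis of one chromosome
#'
#' Splits the contact matrix at the pericentromere, computes the Spearman
#' correlation matrix and PC1 per arm, and orients each arm's PC1 by the
#' periphery-signal track.
#'
#' @param mat contact matrix for `chrom`
#' @param layout a `genome_layout`
#' @param chrom chromosome name
#' @param signal `binned_track` of periphery signal at the Hi-C bin size
#' @param binsize bin size in bp
#' @return named list of `compartment_result` per arm, each with `bins`
#'   attached
#' @export
compartment_analysis <- function(mat, layout, chrom, signal,
                                 binsize = attr(mat, "binsize")) {
  stopifnot(inherits(signal, "binned_track"), signal$window == binsize)
  sig <- signal$values[[chrom]]
  arms <- split_arms(mat, layout, chrom, binsize)
  lapply(arms, function(arm) {
    res <- orient_and_label(pc1(spearman_matrix(arm$matrix))$scores,
                            sig[arm$bins])
    res$bins <- arm$bins
    res
  })
}

#' Correlation profile against the chromosome terminus
#'
#' From the whole-chromosome Spearman correlation matrix, extracts the
#' correlation of every bin in the distal window with the terminal bin (the
#' first bin, e.g. the first 20 kb of the chromosome). Chromosome termini act
#' as telomere proxies in Hi-C, so this curve reads out telomere association.
#'
#' @param mat whole-chromosome contact matrix
#' @param span distal window in bp (default 6 Mb)
#' @param binsize bin size in bp
#' @return numeric curve of length `span / binsize` (bin 1 = terminus,
#'   value 1)
#' @export
telomere_profile <- function(mat, span = 6e6, binsize = attr(mat, "binsize")) {
  stopifnot(!is.null(binsize))
  nb <- floor(span / binsize)
  if (nrow(mat) < nb) stop("chromosome shorter than the requested span")
  cmat <- spearman_matrix(mat)
  if (is.na(cmat[1, 1])) stop("terminal bin is masked")
  cmat[1, seq_len(nb)]
}

#' Detect local valleys in a correlation curve
#'
#' Detrends the curve with a running median of half-width `k` bins and
#' reports maximal runs where the trend exceeds the curve by more than
#' `depth`.
#'
#' @param curve numeric vector
#' @param k smoothing half-width in bins (default 10)
#' @param depth minimum valley depth (default 0.1)
#' @return data.frame with `start_bin`, `end_bin` (1-based, inclusive) and
#'   `depth` (maximum trend - curve in the run)
#' @export
detect_valleys <- function(curve, k = 10, depth = 0.1) {
  stopifnot(length(curve) > 2 * k + 1)
  trend <- stats::runmed(curve, 2 * k + 1, endrule = "median")
  below <- (trend - curve) > depth
  below[is.na(below)] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_bin = starts[keep], end_bin = ends[keep],
             depth = vapply(keep, function(i)
               max(trend[starts[i]:ends[i]] - curve[starts[i]:ends[i]]),
               numeric(1)))
}
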