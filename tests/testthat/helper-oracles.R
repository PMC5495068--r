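# Independent brute-force oracles. These deliberately avoid the code paths
# they check: per-bp membership instead of interval algebra, Poisson tails by
# pmf summation instead of ppois, dense eigendecomposition instead of svd.

# per-bp membership count of query coverage by targets
oracle_overlap_fraction <- function(query, targets) {
  vapply(seq_len(nrow(query)), function(i) {
    bp <- seq(query$start[i], query$end[i] - 1)
    covered <- rep(FALSE, length(bp))
    for (j in seq_len(nrow(targets))) {
      if (targets$chrom[j] != query$chrom[i]) next
      covered <- covered | (bp >= targets$start[j] & bp < targets$end[j])
    }
    sum(covered) / length(bp)
  }, numeric(1))
}

# per-bin midpoint count
oracle_bin_counts <- function(fragments, chrom, chrom_len, window) {
  nb <- ceiling(chrom_len / window)
  counts <- integer(nb)
  for (i in seq_len(nrow(fragments))) {
    if (fragments$chrom[i] != chrom) next
    mid <- floor((fragments$start[i] + fragments$end[i]) / 2)
    b <- min(floor(mid / window) + 1, nb)
    counts[b] <- counts[b] + 1
  }
  counts
}

# Poisson upper tail P(X >= k) by pmf summation
oracle_pois_upper <- function(k, lambda) {
  if (k <= 0) return(1)
  hi <- max(k, ceiling(lambda + 20 * sqrt(lambda + 1)) + 20)
  sum(stats::dpois(k:hi, lambda))
}

# direct-scan island caller: eligibility, gap assembly, Poisson tails by
# summation, BH by the sorted-p formula
oracle_call_islands <- function(chip_counts, ctrl_counts, chrom, chrom_len,
                                W, G, fdr, p_elig) {
  lambda <- sum(chip_counts) / length(chip_counts)
  scale <- if (sum(ctrl_counts) > 0) sum(chip_counts) / sum(ctrl_counts) else 0
  elig <- vapply(chip_counts, function(k) oracle_pois_upper(k, lambda),
                 numeric(1)) < p_elig
  islands <- list()
  i <- 1
  n <- length(chip_counts)
  while (i <= n) {
    if (!elig[i]) { i <- i + 1; next }
    first <- i
    last <- i
    j <- i + 1
    gap <- 0
    while (j <= n && gap <= G / W) {
      if (elig[j]) { last <- j; gap <- 0 } else gap <- gap + 1
      j <- j + 1
    }
    agg <- sum(chip_counts[first:last])
    ctrl <- scale * sum(ctrl_counts[first:last])
    mu <- max(ctrl, lambda * (last - first + 1))
    islands[[length(islands) + 1]] <- data.frame(
      chrom = chrom, start = (first - 1) * W, end = min(last * W, chrom_len),
      chip_count = agg, control_scaled = ctrl,
      pvalue = oracle_pois_upper(agg, mu))
    i <- last + 1
    while (i <= n && !elig[i]) i <- i + 1
  }
  if (length(islands) == 0) return(NULL)
  out <- do.call(rbind, islands)
  # Benjamini-Hochberg from first principles
  m <- nrow(out)
  ord <- order(out$pvalue)
  q <- out$pvalue[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out$qvalue <- NA_real_
  out$qvalue[ord] <- q
  out[out$qvalue < fdr, , drop = FALSE]
}

# dense Spearman by explicit rank + Pearson, excluding columns i and j
oracle_spearman_matrix <- function(m) {
  n <- nrow(m)
  out <- diag(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    x <- rank(m[i, keep])
    y <- rank(m[j, keep])
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    out[i, j] <- out[j, i] <- r
  }
  out
}

# leading eigenvector of the centered cross-product via eigen()
oracle_pc1_vector <- function(cmat) {
  centered <- sweep(cmat, 2, colMeans(cmat))
  eigen(t(centered) %*% centered, symmetric = TRUE)$vectors[, 1]
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
oracle_rank_sum_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- na * (length(pooled) - na) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# empirical KS distance to Uniform(0,1]
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(p - seq_len(n) / n), abs(p - (seq_len(n) - 1) / n))
}
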