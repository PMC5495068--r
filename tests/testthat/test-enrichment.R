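test_that("domain shifting preserves lengths and mirrors at edges", {
  lay <- toy_layout(len = 3e6)
  d <- data.frame(chrom = "chr1", start = 100000, end = 110000)
  set.seed(1)
  got <- shift_domains(d, lay, magnitudes = 5e4)
  expect_true(got$start %in% c(50000, 150000))
  expect_equal(got$end - got$start, 10000)

  # domain near the left edge: a -50 kb shift reflects to [35k, 45k)
  dn <- data.frame(chrom = "chr1", start = 5000, end = 15000)
  seen <- character(0)
  for (s in 1:40) {
    set.seed(s)
    r <- shift_domains(dn, lay, magnitudes = 5e4)
    seen <- c(seen, paste(r$start, r$end))
  }
  expect_setequal(unique(seen), c("55000 65000", "35000 45000"))

  dom <- random_intervals(50, seed = 77, max_len = 2.5e6)
  set.seed(3)
  shifted <- shift_domains(dom, lay, magnitudes = c(5e4, 1e5))
  expect_equal(sort(shifted$end - shifted$start),
               sort(dom$end - dom$start))
  expect_equal(nrow(shifted), nrow(dom))
  expect_true(all(shifted$start >= 0 & shifted$end <= 3e6))

  too_long <- data.frame(chrom = "chr1", start = 0, end = 4e6)
  expect_error(shift_domains(too_long, lay), "longer than")
})

test_that("gene counting in domains matches per-gene brute force", {
  dom <- data.frame(chrom = "chr1", start = c(1e5, 5e5), end = c(2e5, 6e5))
  genes <- data.frame(
    gene_id = paste0("g", 1:5), chrom = "chr1",
    start = c(1.1e5, 1.9e5, 5.2e5, 7e5, 1.5e5),
    end = c(1.2e5, 2.5e5, 5.4e5, 7.1e5, 1.6e5),
    strand = "+",
    biotype = c("TE_gene", "TE_gene", "protein_coding", "TE_gene", "TE_gene"))
  # g1 and g5 sit fully inside domain 1; g2 overlaps only 10/60 kb
  expect_equal(count_genes_in_domains(genes, dom, "TE_gene"), 2L)
  expect_equal(count_genes_in_domains(genes, dom, "protein_coding"), 1L)
  expect_equal(count_genes_in_domains(genes, dom[0, ], "TE_gene"), 0L)
  all_in <- data.frame(chrom = "chr1", start = 0, end = 3e6)
  expect_equal(count_genes_in_domains(genes, all_in, NULL), 5L)

  brute <- sum(oracle_overlap_fraction(genes[genes$biotype == "TE_gene", ],
                                       dom) > 0.8)
  expect_equal(count_genes_in_domains(genes, dom, "TE_gene"), brute)
})

test_that("permutation p-values follow the +1 empirical formula", {
  lay <- toy_layout(len = 3e6)
  d <- data.frame(chrom = "chr1", start = c(1e6, 2e6), end = c(1.01e6, 2.01e6))

  r_const <- permutation_test(function(x) 42, d, lay, n_perm = 49, seed = 1)
  expect_equal(r_const$p_greater, 1)
  expect_equal(r_const$p_less, 1)

  # statistic maximal at the observed placement: bp overlap with itself
  obs <- d
  stat <- function(x) sum(plads:::interval_intersect(x, obs)$end -
                            plads:::interval_intersect(x, obs)$start)
  r <- permutation_test(stat, d, lay, n_perm = 99, seed = 2)
  expect_equal(r$observed, 20000)
  expect_true(all(r$null < 20000))
  expect_equal(r$p_greater, 1 / 100)
  expect_equal(length(r$null), 99)
})

test_that("loop classification follows the majority-anchor rule", {
  dom <- data.frame(chrom = "chr1", start = c(1e5, 3e5), end = c(2e5, 4e5))
  loops <- data.frame(
    chrom1 = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start1 = c(1.1e5, 1.1e5, 5e5, 1.1e5, 0),
    end1 =  c(1.2e5, 1.2e5, 5.1e5, 1.2e5, 1e4),
    chrom2 = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    start2 = c(1.5e5, 3.1e5, 6e5, 6e5, 0),
    end2 =  c(1.6e5, 3.2e5, 6.1e5, 6.1e5, 1e4))
  got <- classify_loops(loops, dom)
  expect_equal(got$intra, 1)     # both anchors in domain 1
  expect_equal(got$across, 2)    # different domains; domain->outside
  expect_equal(got$outside, 1)
  expect_equal(got$n_trans, 1)
  expect_equal(got$intra + got$across + got$outside, got$total)

  # anchor exactly half inside is NOT a member (strict >50%)
  half <- data.frame(chrom1 = "chr1", start1 = 0.5e5, end1 = 1.5e5,
                     chrom2 = "chr1", start2 = 1.1e5, end2 = 1.2e5)
  expect_equal(classify_loops(half, dom)$across, 1)

  set.seed(8)
  rl <- data.frame(chrom1 = "chr1", start1 = floor(runif(60, 0, 9e5)),
                   chrom2 = "chr1", start2 = floor(runif(60, 0, 9e5)))
  rl$end1 <- rl$start1 + 2000; rl$end2 <- rl$start2 + 2000
  rl <- rl[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]
  member <- function(s, e) {
    fr <- vapply(seq_len(nrow(dom)), function(i)
      max(0, min(e, dom$end[i]) - max(s, dom$start[i])) / (e - s), numeric(1))
    if (any(fr > 0.5)) which.max(fr) else NA
  }
  m1 <- mapply(member, rl$start1, rl$end1)
  m2 <- mapply(member, rl$start2, rl$end2)
  want_intra <- sum(!is.na(m1) & !is.na(m2) & m1 == m2)
  want_out <- sum(is.na(m1) & is.na(m2))
  got_r <- classify_loops(rl, dom)
  expect_equal(got_r$intra, want_intra)
  expect_equal(got_r$outside, want_out)
})

test_that("rank-sum comparison matches exact enumeration and edge cases", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  r <- rank_sum_compare(a, b)
  expect_equal(r$U, length(a) * length(b) / 2)
  expect_gt(r$p, 0.9)

  r2 <- rank_sum_compare(c(1, 2), c(5, 6, 7))
  expect_equal(r2$U, 0)

  set.seed(14)
  for (na in c(2, 4, 5, 6)) for (nb in c(3, 5, 6)) {
    x <- sample(seq(1, 1000), na) + runif(na) / 10
    y <- sample(seq(2000, 3000), nb) + runif(nb) / 10
    x <- x[seq_len(na)]; y <- sample(c(x + 500, y))[seq_len(nb)]
    if (anyDuplicated(c(x, y))) next
    expect_equal(rank_sum_compare(x, y)$p, oracle_rank_sum_exact(x, y),
                 tolerance = 1e-12)
  }
  expect_error(rank_sum_compare(numeric(0), 1), "empty")
})

test_that("matched controls reproduce the enriched expression profile", {
  # pool expression identical to the enriched set: the matched control is the
  # pool itself, so the distributions agree exactly
  expr <- c(rlnorm(200, 1, 0.8))
  genes <- data.frame(gene_id = paste0("g", 1:400), expression = c(expr, expr))
  enriched <- rep(c(TRUE, FALSE), each = 200)
  ids <- matched_control_genes(genes, enriched, n = 200, n_bins = 10, seed = 3)
  expect_setequal(ids, genes$gene_id[201:400])

  ids2 <- matched_control_genes(genes, enriched, n = 100, n_bins = 10, seed = 5)
  expect_identical(ids2,
                   matched_control_genes(genes, enriched, n = 100,
                                         n_bins = 10, seed = 5))

  # large synthetic pool: KS distance below 0.05 at n = 3000
  set.seed(6)
  pool_expr <- rlnorm(20000, 2, 1)
  enr_expr <- rlnorm(1500, 1, 0.8)
  g2 <- data.frame(gene_id = paste0("x", seq_len(21500)),
                   expression = c(enr_expr, pool_expr))
  e2 <- c(rep(TRUE, 1500), rep(FALSE, 20000))
  ids3 <- matched_control_genes(g2, e2, n = 3000, n_bins = 20, seed = 7)
  expect_length(ids3, 3000)
  ctrl_expr <- g2$expression[match(ids3, g2$gene_id)]
  ks <- suppressWarnings(ks.test(ctrl_expr, enr_expr)$statistic)
  expect_lt(unname(ks), 0.05)

  expect_error(matched_control_genes(g2[1:1500, ], rep(TRUE, 1500), n = 10),
               "pool is empty")
})
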