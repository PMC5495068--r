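test_that("island caller handles null, single-signal, and gap-boundary cases", {
  lay <- toy_layout(len = 100000)
  params <- island_params()

  # flat track at exactly the background mean: nothing is eligible
  flat <- counts_track(rep(10, 100), 1000)
  expect_equal(nrow(call_islands(flat, flat, lay, params)), 0)

  # one run of 10 windows at 10x background over a flat floor
  counts <- rep(2, 100); counts[41:50] <- 20
  ctrl <- rep(2, 100)
  isl <- call_islands(counts_track(counts, 1000), counts_track(ctrl, 1000),
                      lay, params)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 40000)
  expect_equal(isl$end, 50000)

  # two runs separated by 4 kb (> G) stay apart; by 3 kb (= G) merge
  mk <- function(gap) {
    v <- rep(2, 100)
    v[11:20] <- 20
    v[(21 + gap):(30 + gap)] <- 20
    counts_track(v, 1000)
  }
  expect_equal(nrow(call_islands(mk(4), counts_track(rep(2, 100), 1000),
                                 lay, params)), 2)
  expect_equal(nrow(call_islands(mk(3), counts_track(rep(2, 100), 1000),
                                 lay, params)), 1)
})

test_that("island caller matches the direct-scan oracle on random tracks", {
  lay <- toy_layout(len = 200000)
  params <- island_params()
  for (s in 1:10) {
    set.seed(400 + s)
    chip <- rpois(200, 5)
    runs <- sample(10:180, 3)
    for (r in runs) chip[r:(r + sample(3:12, 1))] <- rpois(1, 40)
    chip <- chip[1:200]
    ctrl <- rpois(200, 5)
    got <- call_islands(counts_track(chip, 1000), counts_track(ctrl, 1000),
                        lay, params)
    want <- oracle_call_islands(chip, ctrl, "chr1", 200000,
                                params$W, params$G, params$fdr, params$p_elig)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$chip_count, want$chip_count)
      expect_equal(got$pvalue, want$pvalue, tolerance = 1e-9)
      expect_equal(got$qvalue, want$qvalue, tolerance = 1e-9)
    }
  }
})

test_that("island calls are invariant under control depth rescaling", {
  lay <- toy_layout(len = 200000)
  set.seed(99)
  chip <- rpois(200, 5); chip[50:60] <- 45; chip[120:135] <- 40
  ctrl <- rpois(200, 5)
  a <- call_islands(counts_track(chip, 1000), counts_track(ctrl, 1000), lay)
  b <- call_islands(counts_track(chip, 1000), counts_track(ctrl * 7, 1000), lay)
  expect_equal(a, b)

  expect_warning(
    c0 <- call_islands(counts_track(chip, 1000),
                       counts_track(rep(0, 200), 1000), lay),
    "empty control")
  expect_gt(nrow(c0), 0)
})

test_that("BH q-values are monotone in p-value rank", {
  lay <- toy_layout(len = 500000)
  set.seed(123)
  chip <- rpois(500, 5)
  for (r in sample(20:470, 8)) chip[r:(r + 6)] <- rpois(7, 30)
  isl <- call_islands(counts_track(chip, 1000),
                      counts_track(rpois(500, 5), 1000), lay,
                      island_params(fdr = 0.5))
  ord <- order(isl$pvalue)
  expect_true(all(diff(isl$qvalue[ord]) >= -1e-12))
  expect_true(all(isl$qvalue >= isl$pvalue))
})

test_that("replicate intersection is exact, commutative and idempotent", {
  r1 <- data.frame(chrom = "chr1", start = 0, end = 10000)
  r2 <- data.frame(chrom = "chr1", start = 5000, end = 15000)
  got <- intersect_replicates(r1, r2)
  expect_equal(got, data.frame(chrom = "chr1", start = 5000, end = 10000),
               ignore_attr = TRUE)
  expect_equal(intersect_replicates(r2, r1), got, ignore_attr = TRUE)
  expect_equal(intersect_replicates(r1, r1),
               data.frame(chrom = "chr1", start = 0, end = 10000),
               ignore_attr = TRUE)
  disjoint <- data.frame(chrom = "chr1", start = 20000, end = 30000)
  expect_equal(nrow(intersect_replicates(r1, disjoint)), 0)

  a <- random_intervals(30, seed = 51)
  b <- random_intervals(30, seed = 52)
  c <- random_intervals(30, seed = 53)
  ab_c <- intersect_replicates(intersect_replicates(a, b), c)
  a_bc <- intersect_replicates(a, intersect_replicates(b, c))
  expect_equal(ab_c, a_bc, ignore_attr = TRUE)
})

test_that("domain summary reports coverage and median length", {
  lay <- toy_layout(len = 1e7,
                    peri = data.frame(chrom = "chr1", start = 4e6, end = 6e6))
  d <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  s <- domain_summary(d, lay)
  expect_equal(s$genome_coverage, 0.1)
  expect_equal(s$arm_coverage, 1e6 / 8e6)

  d3 <- data.frame(chrom = "chr1", start = c(0, 1e6, 2e6),
                   end = c(5000, 1009000, 2020000))
  expect_equal(domain_summary(d3, lay)$median_length, 9000)
  empty <- d3[0, ]
  s0 <- domain_summary(empty, lay)
  expect_equal(s0$genome_coverage, 0)
  expect_true(is.na(s0$median_length))
})

test_that("gene enrichment uses the strict >80% union rule", {
  dom <- data.frame(chrom = "chr1", start = c(0, 1100), end = c(900, 2000))
  # exactly 80% covered -> NOT enriched
  g80 <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_false(assign_enriched_genes(g80, data.frame(chrom = "chr1", start = 0,
                                                     end = 800)))
  g_in <- data.frame(chrom = "chr1", start = 100, end = 700)
  expect_true(assign_enriched_genes(g_in, dom))
  # union over two domains: 1600/1800 = 0.889 > 0.8
  g_span <- data.frame(chrom = "chr1", start = 100, end = 1900)
  expect_equal(oracle_overlap_fraction(g_span, dom), 1600 / 1800)
  expect_true(assign_enriched_genes(g_span, dom))
})

test_that("pericentromere distance filter is inclusive at the cutoff", {
  lay <- toy_layout(len = 1e7,
                    peri = data.frame(chrom = "chr1", start = 5e6, end = 7e6))
  items <- data.frame(chrom = "chr1",
                      start = c(3.9e6, 3.95e6, 5.5e6, 8.0e6, 8.1e6),
                      end = c(4.0e6, 4.05e6, 5.6e6, 8.05e6, 8.2e6))
  kept <- filter_pericentromere_distance(items, lay, 1e6)
  # gap exactly 1 Mb (item ending at 4.0e6) is kept; 0.95 Mb is not;
  # inside the pericentromere is removed; right side mirrored
  expect_equal(kept$start, c(3.9e6, 8.0e6, 8.1e6))
  strict2 <- filter_pericentromere_distance(items, lay, 2e6)
  expect_true(all(strict2$start %in% kept$start))
})

test_that("tissue overlap cells match brute-force membership", {
  sets <- list(leaf = c("a", "b", "c"), root = c("b", "c", "d"),
               flower = c("c", "e"))
  got <- tissue_overlap(sets)
  expect_equal(sum(got$count), length(unique(unlist(sets))))
  expect_equal(got$count[got$combination == "leaf&root&flower"], 1)  # c
  expect_equal(got$count[got$combination == "leaf&root"], 1)         # b
  expect_equal(got$count[got$combination == "flower"], 1)            # e

  same <- list(t1 = c("x", "y"), t2 = c("x", "y"))
  gs <- tissue_overlap(same)
  expect_equal(gs$count[gs$combination == "t1&t2"], 2)
  expect_equal(sum(gs$count), 2)

  disj <- tissue_overlap(list(t1 = "x", t2 = "y"))
  expect_equal(disj$count[disj$combination == "t1&t2"], 0)

  set.seed(61)
  rnd <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
  names(rnd) <- c("A", "B", "C")
  gr <- tissue_overlap(rnd)
  ids <- unique(unlist(rnd))
  for (k in seq_len(nrow(gr))) {
    in_sets <- strsplit(gr$combination[k], "&")[[1]]
    brute <- sum(vapply(ids, function(id)
      setequal(names(rnd)[vapply(rnd, function(s) id %in% s, logical(1))],
               in_sets), logical(1)))
    expect_equal(gr$count[k], brute)
  }
})
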