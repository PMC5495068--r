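test_that("boundary profiles orient into the domain and match brute force", {
  lay <- toy_layout(len = 1e6)
  dom <- data.frame(chrom = "chr1", start = c(1e5, 6e5), end = c(1.5e5, 6.6e5))

  # mark covering the whole chromosome: profile is 1 everywhere
  allm <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  p <- boundary_profile(allm, dom, lay, flank = 2000, window = 100)
  expect_true(all(p$mean == 1))
  expect_equal(p$n, rep(4, nrow(p)))
  expect_true(all(diff(p$position) > 0))

  # mark identical to the domains: exact step from 0 outside to 1 inside
  p2 <- boundary_profile(dom, dom, lay, flank = 2000, window = 100)
  expect_true(all(p2$mean[p2$position < 0] == 0))
  expect_true(all(p2$mean[p2$position > 0] == 1))

  # brute force on random marks, both boundary orientations
  set.seed(17)
  marks <- random_intervals(30, max_len = 9e5, seed = 18)
  p3 <- boundary_profile(marks, dom, lay, flank = 1000, window = 100)
  offs <- seq(-1000, 900, by = 100)
  hit <- function(ws, we) any(marks$start < we & marks$end > ws)
  for (k in seq_along(offs)) {
    vals <- c()
    for (i in seq_len(nrow(dom))) {
      vals <- c(vals, hit(dom$start[i] + offs[k], dom$start[i] + offs[k] + 100),
                hit(dom$end[i] - offs[k] - 100, dom$end[i] - offs[k]))
    }
    expect_equal(p3$mean[k], mean(vals))
  }

  # boundaries whose flank exits the chromosome are dropped
  edge <- data.frame(chrom = "chr1", start = c(500, 5e5), end = c(3e5, 6e5))
  pe <- boundary_profile(allm, edge, lay, flank = 2000, window = 100)
  expect_equal(unique(pe$n), 3)  # the start boundary at 500 is unusable
  both_out <- data.frame(chrom = "chr1", start = 500, end = 999500)
  expect_error(boundary_profile(allm, both_out, lay, flank = 2000),
               "no usable")
})

test_that("numeric-track boundary profile of a constant track is constant", {
  lay <- toy_layout(len = 1e5)
  dom <- data.frame(chrom = "chr1", start = 4e4, end = 6e4)
  tr <- data.frame(chrom = "chr1", start = seq(0, 99900, 100),
                   end = seq(100, 1e5, 100), value = 0.37)
  p <- boundary_profile(tr, dom, lay, flank = 5000, window = 100)
  expect_true(all(p$mean == 0.37))
})

test_that("scaled body profile aligns features of different lengths", {
  # uniform methylation: every body bin is the input value
  feats <- data.frame(chrom = "chr1", start = c(0, 10000), end = c(1000, 15000),
                      strand = c("+", "+"))
  win <- function(s, e) data.frame(chrom = "chr1",
                                   start = seq(s, e - 100, 100),
                                   end = seq(s + 100, e, 100))
  tr <- rbind(win(0, 1000), win(10000, 15000))
  tr$value <- 0.5
  p <- scaled_body_profile(tr, feats, bins = 40)
  expect_equal(p$mean, rep(0.5, 40))
  # both the 1-kb and the 5-kb feature contribute to every bin
  expect_equal(p$n, rep(2, 40))

  # 5' half 0 / 3' half 1: minus strand reverses the profile
  tr2 <- win(0, 1000)
  tr2$value <- rep(c(0, 1), each = 5)
  plus <- scaled_body_profile(tr2, data.frame(chrom = "chr1", start = 0,
                                              end = 1000, strand = "+"),
                              bins = 10)
  minus <- scaled_body_profile(tr2, data.frame(chrom = "chr1", start = 0,
                                               end = 1000, strand = "-"),
                               bins = 10)
  expect_equal(plus$mean, rep(c(0, 1), each = 5))
  expect_equal(minus$mean, rev(plus$mean))

  # invariant to feature order and to duplicating the feature list
  set.seed(19)
  tr3 <- win(0, 1000); tr3$value <- runif(10)
  f2 <- data.frame(chrom = "chr1", start = c(0, 200), end = c(1000, 900),
                   strand = c("+", "-"))
  a <- scaled_body_profile(tr3, f2, bins = 20)
  b <- scaled_body_profile(tr3, f2[2:1, ], bins = 20)
  expect_equal(a$mean, b$mean)
  dup <- scaled_body_profile(tr3, rbind(f2, f2), bins = 20)
  expect_equal(dup$mean, a$mean)
  expect_equal(dup$n, 2 * a$n)

  # short features are skipped and counted
  f3 <- rbind(f2, data.frame(chrom = "chr1", start = 0, end = 150,
                             strand = "+"))
  p3 <- scaled_body_profile(tr3, f3, bins = 20)
  expect_equal(attr(p3, "n_skipped"), 1)
})

test_that("TE location grouping uses the strict rule and partitions", {
  dom <- data.frame(chrom = "chr1", start = 0, end = 10000)
  tes <- data.frame(chrom = "chr1",
                    start = c(1000, 8000, 50000),
                    end = c(3000, 18000, 60000))
  g <- group_tes_by_location(tes, dom)
  expect_equal(nrow(g$peripheral), 1)   # fully inside
  expect_equal(nrow(g$interior), 2)     # 0.2 overlap; no overlap
  expect_equal(nrow(g$peripheral) + nrow(g$interior), nrow(tes))

  # exactly 80% overlap is interior (strict >)
  te80 <- data.frame(chrom = "chr1", start = 2000, end = 12000)
  expect_equal(nrow(group_tes_by_location(te80, dom)$peripheral), 0)
})

test_that("genotype contrast reports per-bin differences and mean loss", {
  p1 <- structure(data.frame(position = 1:5 / 5, mean = rep(0.4, 5), n = 3),
                  class = c("meta_profile", "data.frame"))
  same <- genotype_contrast(p1, p1)
  expect_equal(same$difference, rep(0, 5))
  expect_equal(same$mean_difference, 0)

  p2 <- p1; p2$mean <- p1$mean - 0.3
  d <- genotype_contrast(p1, p2)
  expect_equal(d$mean_difference, -0.3)
  expect_equal(d$ratio, rep(0.11 / 0.41, 5))

  p3 <- p1[1:4, ]
  expect_error(genotype_contrast(p1, p3), "axis mismatch")
})

test_that("methylation pathway contrasts run in the expected direction", {
  cfg <- sim_config(n_chromosomes = 2, seed = 23)
  lay <- simulate_layout(cfg)
  dom <- simulate_true_domains(lay, cfg)
  genes <- simulate_annotations(lay, dom, cfg)
  tes <- genes[genes$biotype == "TE_gene", ]
  grp <- list(peripheral = tes[tes$peripheral, ],
              interior = tes[!tes$peripheral, ])
  meth <- lapply(c(WT = "WT", cmt2 = "cmt2-like", drm = "drm12-like"),
                 function(g) simulate_methylation(genes, cfg, g))
  prof <- function(gt, grn) scaled_body_profile(meth[[gt]]$CHH, grp[[grn]])
  wt_p <- prof("WT", "peripheral"); wt_i <- prof("WT", "interior")

  cmt2_loss_p <- genotype_contrast(wt_p, prof("cmt2", "peripheral"))$mean_difference
  cmt2_loss_i <- genotype_contrast(wt_i, prof("cmt2", "interior"))$mean_difference
  drm_loss_p <- genotype_contrast(wt_p, prof("drm", "peripheral"))$mean_difference
  drm_loss_i <- genotype_contrast(wt_i, prof("drm", "interior"))$mean_difference
  expect_lt(cmt2_loss_p, cmt2_loss_i)   # cmt2: peripheral TEs lose more CHH
  expect_lt(drm_loss_i, drm_loss_p)     # drm1/2: interior TEs lose more

  # wild-type CHH higher over peripheral TE bodies in most bins
  expect_gte(mean(wt_p$mean > wt_i$mean), 0.8)
})
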