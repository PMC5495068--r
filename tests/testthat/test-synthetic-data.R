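test_that("simulated layout centres the pericentromere at the set fraction", {
  lay <- simulate_layout(sim_config(n_chromosomes = 1, chrom_length = 3e6,
                                    pericentromere_fraction = 0.2))
  expect_equal(lay$pericentromere$start, 1.2e6)
  expect_equal(lay$pericentromere$end, 1.8e6)
  # centromere = central third of the pericentromere
  expect_equal(lay$centromere$start, 1.4e6)
  expect_equal(lay$centromere$end, 1.6e6)

  lay0 <- simulate_layout(sim_config(n_chromosomes = 1,
                                     pericentromere_fraction = 0))
  expect_equal(nrow(lay0$pericentromere), 0)
  expect_equal(arm_intervals(lay0)$end, 3e6)

  lay5 <- simulate_layout(sim_config())
  expect_equal(nrow(lay5$chromosomes), 5)
  expect_equal(nrow(lay5$pericentromere), 5)
  expect_error(sim_config(pericentromere_fraction = 1.2), "fraction")
})

test_that("true domains respect coverage, spacing, arm placement and seed", {
  cfg <- sim_config(seed = 5)
  lay <- simulate_layout(cfg)
  dom <- simulate_true_domains(lay, cfg)
  arms <- arm_intervals(lay)
  arm_bp <- sum(arms$end - arms$start)
  cov <- sum(dom$end - dom$start) / arm_bp
  expect_lt(abs(cov - cfg$domain_coverage), 0.01)
  # every domain inside an arm
  expect_equal(overlap_fraction(dom, arms), rep(1, nrow(dom)))
  # non-overlapping with >= spacing between neighbours on a chromosome
  for (ch in unique(dom$chrom)) {
    d <- dom[dom$chrom == ch, ]
    expect_true(all(d$start[-1] - d$end[-nrow(d)] >= cfg$domain_spacing))
  }
  expect_identical(dom, simulate_true_domains(lay, cfg))

  # length sampler: pooled median near the configured 9 kb
  lens <- unlist(lapply(1:4, function(s)
    with(simulate_true_domains(lay, sim_config(seed = s)), end - start)))
  expect_lt(abs(median(lens) / 9000 - 1), 0.1)
})

test_that("fragment intensity follows the fold-enrichment model", {
  cfg <- sim_config(n_chromosomes = 1, pericentromere_fraction = 0,
                    n_fragments = 1e5, gfp_fold = 3, seed = 2)
  lay <- simulate_layout(cfg)
  dom <- data.frame(chrom = "chr1", start = 0, end = 3e5)  # 10% of chromosome
  fr <- simulate_fragments(lay, dom, cfg, "GFP", 1)
  # closed form: 0.1*3 / (0.1*3 + 0.9) = 0.25 of fragments inside the domain
  frac <- mean(fr$start < 3e5)
  expect_lt(abs(frac - 0.25), 0.01)
  expect_lt(abs(nrow(fr) / 1e5 - 1), 0.02)

  # fold 1: GFP indistinguishable from IgG
  cfg1 <- sim_config(n_chromosomes = 1, pericentromere_fraction = 0,
                     n_fragments = 1e4, gfp_fold = 1, seed = 3)
  g <- simulate_fragments(lay, dom, cfg1, "GFP", 1)
  i <- simulate_fragments(lay, dom, cfg1, "IgG", 1)
  expect_gt(suppressWarnings(ks.test(g$start, i$start)$p.value), 0.01)

  # replicates differ but share the intensity model
  r1 <- simulate_fragments(lay, dom, cfg, "GFP", 1)
  r2 <- simulate_fragments(lay, dom, cfg, "GFP", 2)
  expect_false(identical(r1$start, r2$start))
  expect_lt(abs(mean(r2$start < 3e5) - 0.25), 0.01)
})

test_that("annotations carry the configured TE density contrast", {
  ds <- acceptance_dataset()
  genes <- ds$genes
  lay <- ds$layout
  periph <- plads:::peripheral_regions(lay, ds$truth$domains)
  in_bp <- sum(periph$end - periph$start)
  out_bp <- sum(lay$chromosomes$length) - in_bp
  te <- genes[genes$biotype == "TE_gene", ]
  inside <- overlap_fraction(te, periph) > 0.5
  ratio <- (sum(inside) / in_bp) / (sum(!inside) / out_bp)
  expect_lt(abs(ratio / 4 - 1), 0.25)
  expect_true(all(genes$expression >= 0))
  expect_true(all(genes$biotype %in% c("protein_coding", "TE_gene",
                                       "pseudogene")))
  # every TE carries exactly one pathway class
  expect_true(all(genes$te_class[genes$biotype == "TE_gene"] %in%
                    c("CMT2-dependent", "RdDM-dependent")))
  expect_true(all(is.na(genes$te_class[genes$biotype != "TE_gene"])))
})

test_that("simulated Hi-C is symmetric, positive, and labels follow the 50% rule", {
  ds <- acceptance_dataset()
  m <- ds$hic$matrices$chr1
  expect_identical(unclass(m), t(unclass(m)))
  expect_true(all(m > 0))
  expect_true(all(ds$hic$labels$chr1 %in% 0:1))

  # label rule on a constructed case: domain covering exactly half a bin
  lay <- toy_layout(len = 60000)
  lab <- compartment_labels(lay, data.frame(chrom = "chr1", start = 0,
                                            end = 10000), binsize = 20000)
  expect_equal(lab$chr1, c(1L, 0L, 0L))
  lab2 <- compartment_labels(lay, data.frame(chrom = "chr1", start = 0,
                                             end = 9999), binsize = 20000)
  expect_equal(lab2$chr1[1], 0L)
})

test_that("methylation tracks obey genotype rules and value ranges", {
  cfg <- sim_config(seed = 4, cmt2_bias = 1)  # all peripheral TEs CMT2-dep
  lay <- simulate_layout(cfg)
  dom <- simulate_true_domains(lay, cfg)
  genes <- simulate_annotations(lay, dom, cfg)

  wt <- simulate_methylation(genes, cfg, "WT")
  for (ctx in names(wt))
    expect_true(all(wt[[ctx]]$value >= 0 & wt[[ctx]]$value <= 1))

  met1 <- simulate_methylation(genes, cfg, "met1-like")
  expect_true(all(met1$CG$value == 0))
  expect_false(all(met1$CHH$value == 0))

  # cmt2-like: CHH on pure CMT2-dependent (peripheral) TEs drops by the loss
  # factor; windows align across genotypes so means are comparable
  te <- genes[genes$biotype == "TE_gene", ]
  cmt2 <- simulate_methylation(genes, cfg, "cmt2-like")
  peri_win <- overlap_fraction(wt$CHH, te[te$peripheral, ]) > 0.5
  ratio <- mean(cmt2$CHH$value[peri_win]) / mean(wt$CHH$value[peri_win])
  expect_lt(abs(ratio / cfg$cmt2_loss - 1), 0.15)

  expect_error(simulate_methylation(genes, cfg, "ddm1"), "unknown genotype")
})

test_that("dataset generation is deterministic and files re-parse cleanly", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 1e6, n_fragments = 2e4,
                    seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth$domains, b$truth$domains)
  expect_identical(a$fragments$GFP_rep1, b$fragments$GFP_rep1)
  expect_identical(a$hic$matrices$chr1, b$hic$matrices$chr1)
  expect_identical(a$methylation$`cmt2-like`$CHH$value,
                   b$methylation$`cmt2-like`$CHH$value)
  expect_identical(a$genes, b$genes)

  outdir <- withr::local_tempdir()
  simulate_dataset(cfg, outdir = outdir)
  expect_no_warning({
    lay <- read_layout(file.path(outdir, "layout.tsv"))
    frag <- read_bed(file.path(outdir, "GFP_rep1.bed"), layout = lay)
    genes <- read_gff3_genes(file.path(outdir, "genes.gff3"))
    expr <- read_expression(file.path(outdir, "expression.tsv"))
    hic <- read_dense_matrix(file.path(outdir, "hic_chr1.tsv"))
    meth <- read_bedgraph(file.path(outdir, "meth_WT_CHH.bedGraph"))
    loops <- read_bedpe(file.path(outdir, "loops.bedpe"))
  })
  expect_equal(nrow(genes), nrow(a$genes))
  expect_equal(nrow(hic), floor(1e6 / cfg$hic_binsize))
  expect_identical(frag[, c("chrom", "start", "end")],
                   a$fragments$GFP_rep1[, c("chrom", "start", "end")])
})
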