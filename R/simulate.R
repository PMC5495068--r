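#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe the standard study conditions used throughout the test suite: a
#' 5 x 3-Mb genome with centred pericentromeres, true peripheral domains
#' covering 15% of the arms with log-normal lengths (median 9 kb), 3-fold
#' GFP fragment enrichment over an IgG-like background at 2e5 fragments per
#' sample, a two-compartment block Hi-C model with power-law distance decay,
#' and CG/CHG/CHH methylation with two TE classes whose CHH depends on
#' distinct simulated pathways (CMT2-like vs RdDM-like).
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length chromosome length in bp (all chromosomes equal)
#' @param pericentromere_fraction fraction of each chromosome occupied by the
#'   centred pericentromere (the centromere is its central third)
#' @param domain_coverage target fraction of arm bp covered by true domains
#' @param domain_median_length median true-domain length (bp, log-normal)
#' @param domain_log_sd log-sd of the domain length distribution
#' @param domain_spacing minimum gap between true domains (bp); kept at twice
#'   the island-caller gap G so distinct domains stay separable
#' @param domain_zone_coverage local domain coverage inside peripheral zones
#'   (domains cluster into one or two contiguous zones per arm)
#' @param domain_zone_share fraction of domain bp placed inside zones
#' @param gfp_fold fold enrichment of GFP fragment intensity inside true
#'   domains and pericentromeres (>= 1)
#' @param n_fragments expected fragments per sample
#' @param fragment_length fragment length in bp
#' @param pc_gene_density protein-coding genes per bp (uniform)
#' @param te_density_out TE genes per bp outside peripheral regions
#' @param te_ratio TE-gene density ratio inside/outside peripheral regions
#' @param pseudogene_density pseudogenes per bp (uniform)
#' @param pc_length_median,pc_length_sdlog protein-coding gene length model
#' @param te_length_median,te_length_sdlog TE gene length model
#' @param expr_meanlog_pc,expr_meanlog_enriched,expr_meanlog_te,expr_meanlog_pseudo,expr_sdlog
#'   log-normal expression components (enriched protein-coding genes come
#'   from the lower-mean component)
#' @param hic_binsize Hi-C bin size in bp
#' @param hic_decay_exponent power-law contact decay exponent
#' @param hic_decay_plateau distance (bp) beyond which contact decay
#'   saturates at a flat background level
#' @param hic_contrast same-compartment contact bonus (contact multiplied by
#'   `1 + contrast` when two bins share a compartment label)
#' @param hic_noise_sd sd of multiplicative log-normal contact noise
#' @param meth_window methylation window size (bp)
#' @param meth_baselines list of per-context c(peripheral, interior) mean
#'   methylation ratios
#' @param meth_concentration beta concentration of window-level noise
#' @param cmt2_loss CHH retention factor on CMT2-dependent TEs in the
#'   cmt2-like genotype
#' @param drm_loss CHH retention factor on RdDM-dependent TEs in the
#'   drm12-like genotype
#' @param cmt3_factor CHG retention factor in the cmt3-like genotype
#' @param cmt2_bias probability that a peripheral TE is CMT2-dependent (an
#'   interior TE is CMT2-dependent with probability `1 - cmt2_bias`)
#' @param gc_inside,gc_outside GC fraction of simulated sequence inside /
#'   outside peripheral regions
#' @param n_loops,loop_anchor_width,loop_p_intra,loop_p_across,loop_max_span
#'   chromatin-loop generator: number of loops, anchor width, probability of
#'   drawing an intra-domain or domain/outside loop, maximum loop span
#' @param seed root seed; all generator randomness flows from it through
#'   fixed per-component substreams
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 5,
                       chrom_length = 3e6,
                       pericentromere_fraction = 0.2,
                       domain_coverage = 0.15,
                       domain_median_length = 9000,
                       domain_log_sd = 0.4,
                       domain_spacing = 6000,
                       domain_zone_coverage = 0.6,
                       domain_zone_share = 0.8,
                       gfp_fold = 3,
                       n_fragments = 2e5,
                       fragment_length = 200,
                       pc_gene_density = 1 / 5000,
                       te_density_out = 1 / 50000,
                       te_ratio = 4,
                       pseudogene_density = 1 / 200000,
                       pc_length_median = 2000, pc_length_sdlog = 0.3,
                       te_length_median = 3000, te_length_sdlog = 0.5,
                       expr_meanlog_pc = 3,
                       expr_meanlog_enriched = 1.5,
                       expr_meanlog_te = 0.5,
                       expr_meanlog_pseudo = 0,
                       expr_sdlog = 1,
                       hic_binsize = 20000,
                       hic_decay_exponent = 1,
                       hic_decay_plateau = 60000,
                       hic_contrast = 0.6,
                       hic_noise_sd = 0.1,
                       meth_window = 100,
                       meth_baselines = list(CG = c(0.85, 0.70),
                                             CHG = c(0.55, 0.40),
                                             CHH = c(0.30, 0.18)),
                       meth_concentration = 50,
                       cmt2_loss = 0.2,
                       drm_loss = 0.2,
                       cmt3_factor = 0.1,
                       cmt2_bias = 0.8,
                       gc_inside = 0.38,
                       gc_outside = 0.36,
                       n_loops = 300,
                       loop_anchor_width = 2000,
                       loop_p_intra = 0.35,
                       loop_p_across = 0.15,
                       loop_max_span = 2e5,
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(cfg$pericentromere_fraction, cfg$domain_coverage, cfg$cmt2_bias,
             cfg$gc_inside, cfg$gc_outside, cfg$loop_p_intra, cfg$loop_p_across,
             cfg$cmt2_loss, cfg$drm_loss, cfg$cmt3_factor,
             unlist(cfg$meth_baselines))
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$pericentromere_fraction >= 1)
    stop("pericentromere fraction must be < 1")
  if (cfg$gfp_fold < 1) stop("fold enrichment must be >= 1")
  if (cfg$n_chromosomes < 1 || cfg$chrom_length < cfg$hic_binsize)
    stop("invalid genome geometry")
  structure(cfg, class = "sim_config")
}

## Deterministic per-component substreams from the root seed: every generator
## component k re-seeds with substream(seed, k), so components can be rerun
## independently and the whole dataset is a pure function of (config, seed).
substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + 31 * k) %% 2147483629L
}

#' Simulate a genome layout
#'
#' Equal-length chromosomes with the pericentromere centred on the midpoint at
#' the configured fraction; the centromere is the central third of the
#' pericentromere.
#' @param config a `sim_config`
#' @return a `genome_layout`
#' @export
simulate_layout <- function(config) {
  L <- config$chrom_length
  f <- config$pericentromere_fraction
  name <- paste0("chr", seq_len(config$n_chromosomes))
  chromosomes <- data.frame(name = name, length = rep(L, length(name)))
  if (f <= 0)
    return(genome_layout(chromosomes))
  ps <- round(L / 2 - f * L / 2)
  pe <- round(L / 2 + f * L / 2)
  cs <- round(L / 2 - f * L / 6)
  ce <- round(L / 2 + f * L / 6)
  genome_layout(chromosomes,
                pericentromere = data.frame(chrom = name, start = ps, end = pe),
                centromere = data.frame(chrom = name, start = cs, end = ce))
}

#' Simulate ground-truth peripheral domains on chromosome arms
#'
#' Places non-overlapping domains with log-normal lengths on the arms only
#' (the pericentromere is implicitly peripheral), separated by at least
#' `domain_spacing` bp, and adjusts until the realized arm coverage is within
#' 0.5 percentage points of the target. Domains are not scattered uniformly:
#' most of the domain mass concentrates in one or two contiguous "peripheral
#' zones" per arm (dense local packing, `domain_zone_coverage`), with the
#' remainder placed sparsely between zones — emulating the clustered
#' Mb-scale interstitial regions of elevated periphery signal seen on real
#' chromosome arms.
#'
#' @param layout a `genome_layout`
#' @param config a `sim_config`
#' @param seed seed (defaults to the config's domain substream)
#' @return sorted interval data.frame of true domains
#' @export
simulate_true_domains <- function(layout, config, seed = substream(config$seed, 1)) {
  set.seed(seed)
  arms <- arm_intervals(layout)
  arm_bp <- sum(arms$end - arms$start)
  target <- config$domain_coverage
  if (target <= 0 || target >= 0.8)
    stop("domain coverage target must be in (0, 0.8)")
  meanlog <- log(config$domain_median_length)
  sdlog <- config$domain_log_sd
  spacing <- config$domain_spacing
  mean_len <- exp(meanlog + sdlog^2 / 2)
  c_in <- min(config$domain_zone_coverage, mean_len / (mean_len + spacing))
  share <- config$domain_zone_share
  zf <- min(share * target / c_in, 0.9)  # zone fraction of each arm
  c_out <- min(1, (1 - share) * target / max(1 - zf, 0.1))

  walk <- function(chrom, from, to, cov) {
    if (cov <= 0 || to - from < mean_len + spacing) return(NULL)
    gap_extra <- max(mean_len * (1 - cov) / cov - spacing, 1)
    out <- list()
    pos <- from
    repeat {
      gap <- spacing + stats::rexp(1, rate = 1 / gap_extra)
      len <- max(200, round(stats::rlnorm(1, meanlog, sdlog)))
      if (pos + gap + len > to) break
      out[[length(out) + 1]] <- data.frame(chrom = chrom,
                                           start = round(pos + gap),
                                           end = round(pos + gap + len))
      pos <- pos + gap + len
    }
    do.call(rbind, out)
  }

  doms <- list()
  for (i in seq_len(nrow(arms))) {
    alen <- arms$end[i] - arms$start[i]
    n_zones <- sample(1:2, 1)
    zlen <- zf * alen / n_zones
    # place zones left-to-right without overlap
    slack <- alen - n_zones * zlen
    cuts <- sort(stats::runif(n_zones, 0, 1)) * slack
    zs <- arms$start[i] + cuts + (seq_len(n_zones) - 1) * zlen
    ze <- zs + zlen
    segs <- data.frame(from = c(arms$start[i], ze),
                       to = c(zs, arms$end[i]),
                       cov = c(rep(c_out, n_zones + 1)))
    segs <- rbind(segs, data.frame(from = zs, to = ze, cov = c_in))
    for (k in seq_len(nrow(segs)))
      doms[[length(doms) + 1]] <- walk(arms$chrom[i], segs$from[k],
                                       segs$to[k], segs$cov[k])
  }
  doms <- do.call(rbind, doms)
  if (is.null(doms) || nrow(doms) == 0)
    stop("could not place any domain; lower the coverage target or spacing")

  coverage <- function(d) sum(d$end - d$start) / arm_bp
  fails <- 0
  for (iter in seq_len(5000)) {
    cov <- coverage(doms)
    if (abs(cov - target) <= 0.005) break
    if (cov > target) {
      doms <- doms[-sample.int(nrow(doms), 1), , drop = FALSE]
    } else {
      i <- sample.int(nrow(arms), 1, prob = arms$end - arms$start)
      len <- max(200, round(stats::rlnorm(1, meanlog, sdlog)))
      lo <- arms$start[i]
      hi <- arms$end[i] - len
      if (hi <= lo) { fails <- fails + 1; next }
      s <- round(stats::runif(1, lo, hi))
      same <- doms[doms$chrom == arms$chrom[i], , drop = FALSE]
      ok <- all(s >= same$end + spacing | s + len <= same$start - spacing)
      if (ok && s >= arms$start[i] && s + len <= arms$end[i]) {
        doms <- rbind(doms, data.frame(chrom = arms$chrom[i], start = s,
                                       end = s + len))
        fails <- 0
      } else fails <- fails + 1
      if (fails > 500)
        stop("cannot place requested coverage with the spacing constraint; ",
             "lower the coverage target")
    }
  }
  if (abs(coverage(doms) - target) > 0.01)
    stop("cannot reach requested domain coverage within tolerance; ",
         "lower the coverage target")
  doms <- sort_intervals(doms)
  rownames(doms) <- NULL
  doms
}

peripheral_regions <- function(layout, domains) {
  interval_union(rbind(domains[, c("chrom", "start", "end")],
                       layout$pericentromere))
}

#' Simulate aligned RE-ChIP fragments
#'
#' Fragment positions are drawn from a piecewise-constant intensity:
#' uniform for the IgG-like control, and `gfp_fold` times the baseline inside
#' true domains and pericentromeres for the GFP pulldown. The realized count
#' is Poisson around `n_fragments`.
#'
#' @param layout a `genome_layout`
#' @param domains true-domain interval data.frame
#' @param config a `sim_config`
#' @param kind `"GFP"` or `"IgG"`
#' @param replicate replicate number (only used to derive the default seed)
#' @param seed seed
#' @return interval data.frame of fragments with attribute `sample`
#' @export
simulate_fragments <- function(layout, domains, config,
                               kind = c("GFP", "IgG"), replicate = 1,
                               seed = substream(config$seed, 10 + 2 * replicate +
                                                  (match.arg(kind) == "GFP"))) {
  kind <- match.arg(kind)
  set.seed(seed)
  len <- chrom_lengths(layout)
  periph <- peripheral_regions(layout, domains)
  whole <- data.frame(chrom = names(len), start = 0, end = unname(len))
  segs <- rbind(cbind(periph, w = if (kind == "GFP") config$gfp_fold else 1),
                cbind(interval_setdiff(whole, periph), w = 1))
  segs <- segs[order(segs$chrom, segs$start), ]
  seg_len <- segs$end - segs$start
  n <- stats::rpois(1, config$n_fragments)
  idx <- sample.int(nrow(segs), n, replace = TRUE, prob = segs$w * seg_len)
  start <- floor(segs$start[idx] + stats::runif(n) * seg_len[idx])
  fl <- config$fragment_length
  out <- data.frame(chrom = segs$chrom[idx],
                    start = pmin(start, len[segs$chrom[idx]] - fl),
                    end = pmin(start + fl, len[segs$chrom[idx]]),
                    stringsAsFactors = FALSE)
  out <- sort_intervals(out)
  rownames(out) <- NULL
  attr(out, "sample") <- paste0(kind, "_rep", replicate)
  out
}

#' Simulate gene/TE annotations with expression and TE pathway classes
#'
#' Protein-coding genes and pseudogenes are placed uniformly; TE genes are
#' placed at `te_ratio` times higher density inside peripheral regions (true
#' domains plus pericentromere). Expression is log-normal per biotype, with
#' truly enriched protein-coding genes (>80% of the span inside true domains)
#' drawn from the lower-mean component. Each TE gene is assigned a CHH
#' methylation pathway class: peripheral TEs are CMT2-dependent with
#' probability `cmt2_bias`, interior TEs with probability `1 - cmt2_bias`.
#'
#' @inheritParams simulate_fragments
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`, `expression`, `true_enriched`, `peripheral`, `te_class`
#' @export
simulate_annotations <- function(layout, domains, config,
                                 seed = substream(config$seed, 2)) {
  set.seed(seed)
  len <- chrom_lengths(layout)
  whole <- data.frame(chrom = names(len), start = 0, end = unname(len))
  periph <- peripheral_regions(layout, domains)
  interior <- interval_setdiff(whole, periph)

  place <- function(regions, density, med, sdlog, prefix) {
    reg_len <- regions$end - regions$start
    n <- stats::rpois(1, density * sum(reg_len))
    if (n == 0)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character()))
    idx <- sample.int(nrow(regions), n, replace = TRUE, prob = reg_len)
    glen <- pmax(300, round(stats::rlnorm(n, log(med), sdlog)))
    s <- floor(regions$start[idx] + stats::runif(n) * reg_len[idx])
    e <- pmin(s + glen, len[regions$chrom[idx]])
    data.frame(chrom = regions$chrom[idx], start = s, end = e,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  pc <- place(whole, config$pc_gene_density,
              config$pc_length_median, config$pc_length_sdlog)
  te_in <- place(periph, config$te_density_out * config$te_ratio,
                 config$te_length_median, config$te_length_sdlog)
  te_out <- place(interior, config$te_density_out,
                  config$te_length_median, config$te_length_sdlog)
  ps <- place(whole, config$pseudogene_density,
              config$pc_length_median, config$pc_length_sdlog)
  genes <- rbind(cbind(pc, biotype = "protein_coding"),
                 cbind(rbind(te_in, te_out), biotype = "TE_gene"),
                 cbind(ps, biotype = "pseudogene"))
  genes <- sort_intervals(genes)
  rownames(genes) <- NULL
  tag <- c(protein_coding = "PC", TE_gene = "TE", pseudogene = "PS")[genes$biotype]
  genes$gene_id <- paste0(tag, stats::ave(seq_len(nrow(genes)), tag,
                                          FUN = seq_along))
  genes$true_enriched <- overlap_fraction(genes, domains) > 0.8
  genes$peripheral <- overlap_fraction(genes, periph) > 0.8

  meanlog <- ifelse(genes$biotype == "TE_gene", config$expr_meanlog_te,
             ifelse(genes$biotype == "pseudogene", config$expr_meanlog_pseudo,
             ifelse(genes$true_enriched, config$expr_meanlog_enriched,
                    config$expr_meanlog_pc)))
  genes$expression <- stats::rlnorm(nrow(genes), meanlog, config$expr_sdlog)

  genes$te_class <- NA_character_
  is_te <- genes$biotype == "TE_gene"
  p_cmt2 <- ifelse(genes$peripheral[is_te], config$cmt2_bias,
                   1 - config$cmt2_bias)
  genes$te_class[is_te] <- ifelse(stats::runif(sum(is_te)) < p_cmt2,
                                  "CMT2-dependent", "RdDM-dependent")
  genes[, c("gene_id", "chrom", "start", "end", "strand", "biotype",
            "expression", "true_enriched", "peripheral", "te_class")]
}

#' Per-bin true compartment labels
#'
#' A bin is labeled peripheral (1) iff at least half of it overlaps true
#' domains or the pericentromere. Only full bins are labeled; a trailing
#' partial bin is dropped.
#' @inheritParams simulate_fragments
#' @param binsize bin size in bp
#' @return named list of 0/1 integer vectors, one per chromosome
#' @export
compartment_labels <- function(layout, domains, binsize = 20000) {
  periph <- peripheral_regions(layout, domains)
  len <- chrom_lengths(layout)
  out <- lapply(names(len), function(ch) {
    nb <- floor(len[[ch]] / binsize)
    if (nb == 0) return(integer(0))
    bins <- data.frame(chrom = ch, start = (seq_len(nb) - 1) * binsize,
                       end = seq_len(nb) * binsize)
    as.integer(overlap_fraction(bins, periph) >= 0.5)
  })
  names(out) <- names(len)
  out
}

#' Simulate per-chromosome Hi-C contact matrices
#'
#' `contact(i, j) = decay(|i - j|) * (1 + contrast * same(i, j)) * noise`
#' where `same` indicates a shared true compartment label and the noise is
#' log-normal, symmetric by construction. The decay is a power law
#' `(1 + d)^-alpha` that saturates at `hic_decay_plateau`, mirroring the
#' flattening of contact frequency to a background level at large distances.
#' @inheritParams simulate_fragments
#' @return list with `matrices` (named list of matrices, attribute `binsize`)
#'   and `labels` (as [compartment_labels()])
#' @export
simulate_hic <- function(layout, domains, config,
                         seed = substream(config$seed, 3)) {
  set.seed(seed)
  binsize <- config$hic_binsize
  labels <- compartment_labels(layout, domains, binsize)
  matrices <- lapply(labels, function(lab) {
    n <- length(lab)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    plateau <- max(1, round(config$hic_decay_plateau / binsize))
    same <- outer(lab, lab, "==")
    base <- (1 + pmin(d, plateau))^(-config$hic_decay_exponent) *
      (1 + config$hic_contrast * same)
    e <- matrix(0, n, n)
    ut <- upper.tri(e, diag = TRUE)
    e[ut] <- stats::rnorm(sum(ut), 0, config$hic_noise_sd)
    e <- e + t(e) - diag(diag(e))
    m <- base * exp(e)
    attr(m, "binsize") <- binsize
    m
  })
  list(matrices = matrices, labels = labels)
}

#' Simulate per-context methylation tracks over TE bodies
#'
#' Emits 100-bp-window methylation ratios over every TE gene body for one
#' genotype. Wild-type levels are context- and location-dependent (higher on
#' peripheral TEs); mutants modify them: `met1-like` zeroes CG everywhere,
#' `cmt3-like` multiplies CHG by `cmt3_factor`, `cmt2-like` multiplies CHH by
#' `cmt2_loss` on CMT2-dependent TEs only, and `drm12-like` multiplies CHH by
#' `drm_loss` on RdDM-dependent TEs only.
#'
#' @param genes annotation data.frame from [simulate_annotations()]
#' @param config a `sim_config`
#' @param genotype one of `"WT"`, `"met1-like"`, `"cmt3-like"`, `"cmt2-like"`,
#'   `"drm12-like"`
#' @param seed seed
#' @return named list of bedGraph data.frames, one per context (CG/CHG/CHH)
#' @export
simulate_methylation <- function(genes, config, genotype = "WT",
                                 seed = substream(config$seed, 4)) {
  genotypes <- c("WT", "met1-like", "cmt3-like", "cmt2-like", "drm12-like")
  if (!genotype %in% genotypes)
    stop("unknown genotype: ", genotype)
  set.seed(seed + match(genotype, genotypes))
  te <- genes[genes$biotype == "TE_gene", , drop = FALSE]
  if (nrow(te) == 0) stop("no TE genes to methylate")
  w <- config$meth_window
  nwin <- pmax(1, floor((te$end - te$start) / w))
  te_idx <- rep(seq_len(nrow(te)), nwin)
  off <- unlist(lapply(nwin, seq_len)) - 1
  win <- data.frame(chrom = te$chrom[te_idx],
                    start = te$start[te_idx] + off * w,
                    stringsAsFactors = FALSE)
  win$end <- win$start + w
  periph <- te$peripheral[te_idx]
  cmt2_dep <- te$te_class[te_idx] == "CMT2-dependent"

  out <- lapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(ctx) {
    base <- ifelse(periph, config$meth_baselines[[ctx]][1],
                   config$meth_baselines[[ctx]][2])
    level <- switch(genotype,
      "WT" = base,
      "met1-like" = if (ctx == "CG") rep(0, length(base)) else base,
      "cmt3-like" = if (ctx == "CHG") base * config$cmt3_factor else base,
      "cmt2-like" = if (ctx == "CHH")
        ifelse(cmt2_dep, base * config$cmt2_loss, base) else base,
      "drm12-like" = if (ctx == "CHH")
        ifelse(cmt2_dep, base, base * config$drm_loss) else base)
    conc <- config$meth_concentration
    value <- ifelse(level <= 0, 0,
                    stats::rbeta(length(level), level * conc,
                                 pmax((1 - level) * conc, 1e-6)))
    cbind(win, value = value)
  })
  out
}

#' Simulate genome sequence with GC contrast
#'
#' I.i.d. nucleotides with configurable GC content inside vs outside
#' peripheral regions; supports the sliding-window GC-profile analysis only.
#' @inheritParams simulate_fragments
#' @return a [Biostrings::DNAStringSet] named by chromosome
#' @export
simulate_sequence <- function(layout, domains, config,
                              seed = substream(config$seed, 5)) {
  set.seed(seed)
  len <- chrom_lengths(layout)
  periph <- peripheral_regions(layout, domains)
  seqs <- lapply(names(len), function(ch) {
    L <- len[[ch]]
    gc <- rep(config$gc_outside, L)
    p <- periph[periph$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(p))) gc[(p$start[i] + 1):p$end[i]] <- config$gc_inside
    u <- stats::runif(L)
    v <- stats::runif(L)
    base <- ifelse(u < gc, ifelse(v < 0.5, "G", "C"),
                   ifelse(v < 0.5, "A", "T"))
    paste(base, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(len)
  out
}

#' Simulate chromatin loops (BEDPE)
#'
#' Draws loops of three kinds: both anchors inside one true domain
#' (`loop_p_intra`), one anchor inside and one outside (`loop_p_across`), and
#' the remainder with both anchors outside peripheral regions. All loops are
#' intra-chromosomal with span at most `loop_max_span`.
#' @inheritParams simulate_fragments
#' @return BEDPE data.frame
#' @export
simulate_loops <- function(layout, domains, config,
                           seed = substream(config$seed, 6)) {
  set.seed(seed)
  len <- chrom_lengths(layout)
  aw <- config$loop_anchor_width
  big <- domains[domains$end - domains$start >= 2 * aw + 1000, , drop = FALSE]
  interior <- interval_setdiff(
    data.frame(chrom = names(len), start = 0, end = unname(len)),
    peripheral_regions(layout, domains))
  interior <- interior[interior$end - interior$start >= aw, , drop = FALSE]

  rand_anchor <- function(regions) {
    i <- sample.int(nrow(regions), 1, prob = regions$end - regions$start)
    s <- floor(stats::runif(1, regions$start[i], regions$end[i] - aw))
    data.frame(chrom = regions$chrom[i], start = s, end = s + aw)
  }
  loops <- vector("list", config$n_loops)
  for (k in seq_len(config$n_loops)) {
    type <- sample(c("intra", "across", "outside"), 1,
                   prob = c(config$loop_p_intra, config$loop_p_across,
                            1 - config$loop_p_intra - config$loop_p_across))
    if (type == "intra" && nrow(big)) {
      i <- sample.int(nrow(big), 1, prob = big$end - big$start)
      s1 <- floor(stats::runif(1, big$start[i], big$end[i] - aw))
      s2 <- floor(stats::runif(1, big$start[i], big$end[i] - aw))
      a1 <- data.frame(chrom = big$chrom[i], start = min(s1, s2),
                       end = min(s1, s2) + aw)
      a2 <- data.frame(chrom = big$chrom[i], start = max(s1, s2),
                       end = max(s1, s2) + aw)
    } else if (type == "across" && nrow(big)) {
      i <- sample.int(nrow(big), 1, prob = big$end - big$start)
      s1 <- floor(stats::runif(1, big$start[i], big$end[i] - aw))
      a1 <- data.frame(chrom = big$chrom[i], start = s1, end = s1 + aw)
      near <- interior[interior$chrom == a1$chrom &
                         abs((interior$start + interior$end) / 2 -
                               a1$start) < config$loop_max_span, , drop = FALSE]
      if (nrow(near) == 0) near <- interior[interior$chrom == a1$chrom, , drop = FALSE]
      a2 <- rand_anchor(near)
    } else {
      a1 <- rand_anchor(interior)
      gap <- pmax(0, pmax(interior$start - a1$end, a1$start - interior$end))
      near <- interior[interior$chrom == a1$chrom &
                         gap < config$loop_max_span, , drop = FALSE]
      a2 <- rand_anchor(near)
    }
    loops[[k]] <- data.frame(chrom1 = a1$chrom, start1 = a1$start,
                             end1 = a1$end, chrom2 = a2$chrom,
                             start2 = a2$start, end2 = a2$end)
  }
  do.call(rbind, loops)
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator component off the config's root seed (via fixed
#' substreams) and, when `outdir` is given, writes all on-disk formats the
#' pipeline reads: layout TSV, per-sample fragment BEDs, gene GFF3 and
#' expression TSV, per-chromosome dense Hi-C TSVs, per-genotype/context
#' methylation bedGraphs, loop BEDPE, and a ground-truth JSON.
#'
#' @param config a `sim_config`
#' @param outdir optional output directory (created if missing)
#' @param genotypes methylation genotypes to generate
#' @param sequence also simulate genome sequence (FASTA); off by default
#' @return (invisibly) list with `layout`, `truth` (domains, compartment
#'   labels, TE classes, per-gene enrichment flags), `fragments`, `genes`,
#'   `hic`, `methylation`, `loops`, and optionally `sequence`
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL,
                             genotypes = c("WT", "met1-like", "cmt3-like",
                                           "cmt2-like", "drm12-like"),
                             sequence = FALSE) {
  layout <- simulate_layout(config)
  domains <- simulate_true_domains(layout, config)
  fragments <- list()
  for (rep in 1:2) {
    for (kind in c("GFP", "IgG")) {
      fr <- simulate_fragments(layout, domains, config, kind, rep)
      fragments[[attr(fr, "sample")]] <- fr
    }
  }
  genes <- simulate_annotations(layout, domains, config)
  hic <- simulate_hic(layout, domains, config)
  meth <- lapply(stats::setNames(genotypes, genotypes), function(g)
    simulate_methylation(genes, config, g))
  loops <- simulate_loops(layout, domains, config)
  truth <- list(domains = domains,
                compartments = hic$labels,
                te_class = stats::setNames(
                  genes$te_class[genes$biotype == "TE_gene"],
                  genes$gene_id[genes$biotype == "TE_gene"]),
                enriched = stats::setNames(genes$true_enriched, genes$gene_id))
  out <- list(config = config, layout = layout, truth = truth,
              fragments = fragments, genes = genes, hic = hic,
              methylation = meth, loops = loops)
  if (sequence)
    out$sequence <- simulate_sequence(layout, domains, config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_layout(layout, file.path(outdir, "layout.tsv"))
    write_bed(domains, file.path(outdir, "true_domains.bed"))
    for (s in names(fragments))
      write_bed(fragments[[s]], file.path(outdir, paste0(s, ".bed")))
    write_gff3_genes(genes, file.path(outdir, "genes.gff3"))
    write_expression(genes, file.path(outdir, "expression.tsv"))
    for (ch in names(hic$matrices))
      write_dense_matrix(hic$matrices[[ch]],
                         file.path(outdir, paste0("hic_", ch, ".tsv")))
    for (g in names(meth))
      for (ctx in names(meth[[g]]))
        write_bedgraph(meth[[g]][[ctx]],
                       file.path(outdir, sprintf("meth_%s_%s.bedGraph",
                                                 gsub("-like", "", g), ctx)))
    write_bedpe(loops, file.path(outdir, "loops.bedpe"))
    if (sequence)
      Biostrings::writeXStringSet(out$sequence,
                                  file.path(outdir, "genome.fasta"))
    jsonlite::write_json(
      list(domains = domains, compartments = truth$compartments,
           te_class = as.list(truth$te_class),
           enriched = as.list(truth$enriched)),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
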