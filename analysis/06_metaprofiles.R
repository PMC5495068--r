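#!/usr/bin/env Rscript
# Stage 6: boundary profiles and TE-body methylation metaplots.
#
# Boundary profiles: percent of 100-bp windows covered by TE genes around
# domain borders (positive positions point into the domain). Methylation:
# per-context 100-bp ratios over TE bodies are linearly rescaled so all TE
# boundaries align (40 body bins), grouped by nuclear location (>80% of the
# TE inside called domains + pericentromere = peripheral) and contrasted
# across genotypes to read out the two CHH pathways.

suppressMessages(library(plads))

layout <- read_layout("results/data/layout.tsv")
genes <- read_gff3_genes("results/data/genes.gff3")
domains <- read_bed("results/domains.bed", layout)
tes <- genes[genes$biotype == "TE_gene", ]

bp <- boundary_profile(tes, domains, layout, flank = 20000, window = 100)
write.table(bp, "results/boundary_te_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
inside <- mean(bp$mean[bp$position > 0])
outside <- mean(bp$mean[bp$position < 0])
message(sprintf("TE-gene occupancy around domain borders: %.1f%% of windows inside vs %.1f%% outside",
                100 * inside, 100 * outside))

periph_regions <- plads:::interval_union(
  rbind(domains[, c("chrom", "start", "end")], layout$pericentromere))
groups <- group_tes_by_location(tes, periph_regions)
message(sprintf("TE groups by location: %d peripheral, %d interior",
                nrow(groups$peripheral), nrow(groups$interior)))

rows <- list()
for (gt in c("WT", "met1", "cmt3", "cmt2", "drm12")) {
  for (ctx in c("CG", "CHG", "CHH")) {
    meth <- read_bedgraph(sprintf("results/data/meth_%s_%s.bedGraph", gt, ctx))
    for (grp in names(groups)) {
      prof <- scaled_body_profile(meth, groups[[grp]], bins = 40)
      rows[[length(rows) + 1]] <- cbind(genotype = gt, context = ctx,
                                        group = grp, prof)
    }
  }
}
meta <- do.call(rbind, rows)
write.table(meta, "results/methylation_metaprofiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

body_mean <- function(gt, ctx, grp)
  mean(meta$mean[meta$genotype == gt & meta$context == ctx & meta$group == grp])
for (grp in c("peripheral", "interior"))
  message(sprintf("CHH loss on %s TEs: cmt2-like %.3f, drm12-like %.3f",
                  grp, body_mean("cmt2", "CHH", grp) - body_mean("WT", "CHH", grp),
                  body_mean("drm12", "CHH", grp) - body_mean("WT", "CHH", grp)))
message("wrote results/methylation_metaprofiles.tsv")
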