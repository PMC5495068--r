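#!/usr/bin/env Rscript
# Stage 5: gene-class enrichment, expression contrasts, and loop classes.
#
# Counts TE genes / protein-coding genes / pseudogenes enriched (>80% of the
# transcribed region) in the distal-arm domains and compares each count with
# a coordinate-shift null (domains moved +/-50 or +/-100 kb per round, 999
# rounds). Expression of enriched vs non-enriched protein-coding genes is
# compared by Mann-Whitney, an expression-matched control gene set is drawn,
# and chromatin loops are classified as intra-domain / across-boundary /
# outside.

suppressMessages(library(plads))
seed <- as.integer(Sys.getenv("PLADS_SEED", "7"))

layout <- read_layout("results/data/layout.tsv")
genes <- read_gff3_genes("results/data/genes.gff3")
expr <- read_expression("results/data/expression.tsv")
genes$expression <- expr$expression[match(genes$gene_id, expr$gene_id)]
domains <- read_bed("results/domains.bed", layout)
far <- read_bed("results/domains_distal.bed", layout)

report <- list()
for (bt in c("TE_gene", "protein_coding", "pseudogene")) {
  pt <- permutation_test(function(d) count_genes_in_domains(genes, d, bt),
                         far, layout, n_perm = 999, seed = seed + 101)
  message(sprintf("%-14s observed %4d | shifted-null mean %6.1f | p = %.4g",
                  bt, pt$observed, mean(pt$null), pt$p_greater))
  report[[bt]] <- list(observed = pt$observed, null_mean = mean(pt$null),
                       null_sd = sd(pt$null), p_greater = pt$p_greater)
}

enr <- assign_enriched_genes(genes, domains)
pc <- genes$biotype == "protein_coding"
mw <- rank_sum_compare(genes$expression[pc & enr], genes$expression[pc & !enr])
message(sprintf("expression, enriched vs other protein-coding genes: U = %.0f, p = %.3g (medians %.2f vs %.2f)",
                mw$U, mw$p, median(genes$expression[pc & enr]),
                median(genes$expression[pc & !enr])))
report$expression <- list(U = mw$U, p = mw$p)

controls <- matched_control_genes(genes, enr, n = min(3000, sum(!enr)),
                                  n_bins = 20, seed = seed)
writeLines(controls, "results/matched_control_genes.txt")
report$n_matched_controls <- length(controls)

loops <- read_bedpe("results/data/loops.bedpe")
lc <- classify_loops(loops, domains)
message(sprintf("loops: %d intra-domain, %d across-boundary, %d outside (of %d cis)",
                lc$intra, lc$across, lc$outside, lc$total))
for (kind in c("intra", "outside")) {
  stat <- switch(kind,
    intra = function(d) classify_loops(loops, d)$intra,
    outside = function(d) classify_loops(loops, d)$outside)
  pt <- permutation_test(stat, domains, layout, n_perm = 199, seed = seed + 7)
  message(sprintf("  %s vs shifted null: observed %d, null mean %.1f, p(greater) = %.3g",
                  kind, pt$observed, mean(pt$null), pt$p_greater))
  report[[paste0("loops_", kind)]] <- list(observed = pt$observed,
                                           null_mean = mean(pt$null),
                                           p_greater = pt$p_greater)
}
report$loops <- lc

jsonlite::write_json(report, "results/enrichment.json", auto_unbox = TRUE,
                     digits = NA)
message("wrote results/enrichment.json")
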