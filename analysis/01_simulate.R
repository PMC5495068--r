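#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the full input suite of a nuclear-periphery RE-ChIP study on a
# desk-scale genome (5 x 3 Mb): two GFP pulldown replicates plus matched IgG
# (2e5 fragments each, 3-fold enrichment over true peripheral domains and
# pericentromeres), biotype-annotated genes with expression, 20-kb Hi-C
# matrices with two-compartment block structure, per-context methylation for
# WT and four methylation-pathway mutants, and chromatin loops. Ground truth
# goes to truth.json for the recovery stages.

suppressMessages(library(plads))
seed <- as.integer(Sys.getenv("PLADS_SEED", "7"))

cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg, outdir = "results/data")

truth_cov <- 100 * sum(ds$truth$domains$end - ds$truth$domains$start) /
  sum(ds$layout$chromosomes$length)
message(sprintf("seed %d: %d true domains (%.1f%% of the genome, median %.1f kb)",
                seed, nrow(ds$truth$domains), truth_cov,
                median(ds$truth$domains$end - ds$truth$domains$start) / 1000))
message(sprintf("%d genes (%d TE genes), %d loops, %d fragments/sample",
                nrow(ds$genes), sum(ds$genes$biotype == "TE_gene"),
                nrow(ds$loops), nrow(ds$fragments$GFP_rep1)))
message("wrote results/data/")
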