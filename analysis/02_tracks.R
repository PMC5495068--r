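#!/usr/bin/env Rscript
# Stage 2: normalized coverage and log2 GFP/IgG signal tracks.
#
# Bins each sample's fragments at 50 kb (chromosome-scale overview) and
# 20 kb (the Hi-C-matched resolution), scales to fragments-per-million, and
# writes the log2 pulldown/control ratio per replicate — the periphery
# signal all later stages consume.

suppressMessages(library(plads))

layout <- read_layout("results/data/layout.tsv")
for (rep in 1:2) {
  gfp <- read_bed(sprintf("results/data/GFP_rep%d.bed", rep), layout)
  igg <- read_bed(sprintf("results/data/IgG_rep%d.bed", rep), layout)
  for (w in c(50000, 20000)) {
    lr <- log2_ratio(normalize_per_million(bin_fragments(gfp, layout, w)),
                     normalize_per_million(bin_fragments(igg, layout, w)))
    out <- sprintf("results/signal_rep%d_%dkb.bedGraph", rep, w / 1000)
    write_bedgraph(track_to_bedgraph(lr, layout), out)
    message("wrote ", out)
  }
  bg <- read_bedgraph(sprintf("results/signal_rep%d_50kb.bedGraph", rep))
  peri_mean <- mean(bg$value[overlap_fraction(bg, layout$pericentromere) > 0.5])
  arm_mean <- mean(bg$value[overlap_fraction(bg, layout$pericentromere) == 0])
  message(sprintf("rep %d: mean log2 ratio %.2f over pericentromeres vs %.2f on arms",
                  rep, peri_mean, arm_mean))
}
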