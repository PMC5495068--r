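# plads — periphery-associated chromatin domain analysis

`plads` is an R implementation of the computational pipeline behind
restriction-enzyme ChIP-seq (RE-ChIP) mapping of chromatin at the plant
nuclear periphery. Pulling down a GFP-tagged nuclear-pore protein and
comparing its fragment coverage with an IgG control reveals lamina-
associated-domain-like regions: pericentromeric heterochromatin plus
discrete interstitial stretches of the chromosome arms. The package turns
that analysis into tested, reusable functions and exercises it end to end
on synthetic data with known ground truth.

The pipeline:

* **Signal tracks** — midpoint binning of aligned fragments, per-million
  scaling, `log2((GFP + c)/(IgG + c))` with pseudocount `c = 0.5`.
* **Domain calling** — a SICER-style broad-island caller on 1-kb windows:
  windows are *eligible* when their Poisson upper-tail p under the genome
  mean λ is < 0.2, eligible windows chain across gaps ≤ G = 3 kb, islands
  are scored by `P(Pois(max(scaled IgG, λ·n)) ≥ aggregate count)` and kept
  at Benjamini–Hochberg q < 0.01; domains are the bp-level intersection of
  two replicate calls. A gene is *enriched* when > 80% of its span overlaps
  the domains.
* **Hi-C compartments** — per-arm Spearman correlation matrices of 20-kb
  contact maps, PCA, PC1 oriented by the periphery signal; peripheral-like
  vs interior-like labels, plus telomere-correlation profiles with valley
  detection.
* **Enrichment statistics** — permutation nulls built by shifting domains
  ±50/±100 kb (empirical p with +1 correction), gene-class counts,
  Mann–Whitney expression comparisons, expression-matched control gene
  sets, chromatin-loop classification (intra / across / outside).
* **Metaprofiles** — boundary-anchored 100-bp-window profiles (oriented
  into the domain) and length-normalised TE-body methylation metaplots per
  genotype and nuclear location.
* **Synthetic data** — a generator (`sim_config()`, `simulate_dataset()`)
  that emulates every input with ground truth: fragments, annotation with
  expression, block-structured Hi-C, CG/CHG/CHH methylation with two TE
  silencing pathways (CMT2-like vs RdDM-like), and loops.

## Worked example

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `06_metaprofiles.R`); each reads the previous stage's
files under `results/` and prints what it found. A condensed session:

```r
library(plads)

cfg <- sim_config(seed = 7)          # 5 x 3 Mb genome, 15% arm coverage,
rec <- domain_recovery(cfg)          # 3-fold GFP enrichment, 2 replicates
rec$coverage_pct                     # 11.03  -- % of genome in called domains
rec$median_length_kb                 # 9      -- median called-domain length
rec$jaccard                          # 0.918  -- bp-Jaccard vs ground truth
```

The called, replicate-intersected arm domains cover 11% of the genome
(truth: 15% of the arms = 12% of the genome) with a 9-kb median length,
inside the 10–20% and 7–12 kb ranges such studies report, and agree with
the planted truth at bp-Jaccard 0.92. Running the full drivers
(`PLADS_SEED=7 Rscript analysis/01_simulate.R` and so on) additionally
prints, for the same seed:

```
compartment labels match truth on 97.2% of 600 arm bins
TE_gene        observed   18 | shifted-null mean    9.4 | p = 0.007
expression, enriched vs other protein-coding genes: U = 745939, p = 4.28e-32
loops: 108 intra-domain, 50 across-boundary, 142 outside (of 300 cis)
  intra vs shifted null: observed 108, null mean 18.0, p(greater) = 0.005
CHH loss on peripheral TEs: cmt2-like -0.190, drm12-like -0.049
CHH loss on interior TEs:   cmt2-like -0.035, drm12-like -0.111
```

i.e. Hi-C compartments track the periphery signal, TE genes are enriched in
the domains relative to the coordinate-shift null, enriched protein-coding
genes are lowly expressed, intra-domain loops are overrepresented, and CHH
methylation of peripheral TEs depends on the CMT2-like pathway while
interior TEs depend on the RdDM-like pathway — the full qualitative
signature the pipeline is built to detect.

See `vignettes/periphery-domains.Rmd` for the model, parameter and design
documentation.

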