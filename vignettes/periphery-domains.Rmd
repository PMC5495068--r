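---
title: "Calling and characterising nuclear-periphery-associated chromatin domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising nuclear-periphery-associated chromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plads)
```

## The problem

In animal nuclei, lamina-associated domains (LADs) tether repressed
chromatin to the nuclear periphery. Plants lack lamins, but restriction-
enzyme-mediated ChIP (RE-ChIP) against a GFP-tagged nuclear-pore basket
protein recovers chromatin lying near the plant nuclear envelope: pulldown
coverage relative to a non-specific IgG control is elevated over
pericentromeric heterochromatin and over discrete interstitial stretches of
the chromosome arms. `plads` implements the computational arm of such a
study as a reusable, tested pipeline: signal tracks, broad-domain calling,
replicate intersection, Hi-C compartment correlation, permutation-based
gene/TE enrichment, chromatin-loop classification, and DNA-methylation
metaprofiles — exercised end to end on synthetic data with known ground
truth.

## The model and procedure

### Signal tracks

Aligned fragments are binned by midpoint into fixed windows (50 kb for
chromosome-scale overviews, 20 kb to match Hi-C, 1 kb for calling, 100 bp
for metaprofiles), scaled to fragments-per-million, and summarised as
`log2((GFP + c) / (IgG + c))` with pseudocount `c = 0.5` per-million units.
Per-million scaling is the standard depth-invariant reading of "normalized
coverage"; the pseudocount bounds log-ratios on sparse bins, and a bin where
both libraries are empty is exactly 0. Midpoint assignment (rather than
proportional overlap) makes the track conserve fragment counts, which every
downstream statistic and test relies on; with ~200-bp fragments and windows
of 1 kb or more the difference from proportional assignment is negligible.

### Island calling

Broad domains are called with a SICER-style island caller on 1-kb windows:

1. a window is *eligible* when the one-sided Poisson upper tail of its
   pulldown count under the genome-wide mean count per window is below
   `p_elig = 0.2` (the conventional eligibility threshold; configurable);
2. eligible windows chain into islands across ineligible gaps of at most
   `G = 3000` bp;
3. each island's p-value is the Poisson upper tail of its aggregate count
   with mean `max(depth-scaled IgG aggregate, genome-mean x windows in
   span)` — the control-scaled mode is the default, with a background-only
   fallback when the control is empty;
4. islands are filtered at Benjamini-Hochberg `q < 0.01`.

`W = 1000`, `G = 3000` and FDR < 0.01 are the study settings. Periphery-
associated domains are the base-pair-level intersection of the two replicate
calls; a gene is *enriched* when strictly more than 80% of its annotated
span overlaps the domain set, and the same strict rule classifies TEs as
peripheral or interior (the threshold is not restated for TEs in the source
protocol; reusing it keeps the two classifications consistent). Control
depth is rescaled to the pulldown depth internally, so calls are invariant
under uniform control rescaling.

Association analyses can be restricted to domains at least 1 Mb from
pericentromeric heterochromatin (`filter_pericentromere_distance`); the
cutoff is inclusive — "at least 1 Mb" keeps a gap of exactly 1 Mb.

### Hi-C compartments

Per chromosome arm (bins fully outside the pericentromere), the 20-kb
contact matrix is converted to a Spearman correlation matrix — entry (i, j)
correlates rows i and j with columns i and j excluded, so the raw diagonal
never enters the ranks — and PCA is run on the column-centered correlation
matrix. Whether rows, columns or both should be centered is not dictated by
the method description; column centering is the common choice for
correlation-matrix PCA and is applied consistently. The PC1 sign is fixed
by requiring a nonnegative Spearman correlation with the periphery-signal
track, and bins with oriented PC1 > 0 are labeled *peripheral-like*. The
whole-chromosome correlation of each bin with the terminal 20-kb bin gives a
telomere-proximity curve; valleys are maximal runs where a running-median
trend (half-width 10 bins) exceeds the curve by more than 0.1 — the source
describes valleys only visually, so the criterion (both parameters
configurable) is a design choice of this package, and no automatic
colocalization verdict is attached to it.

### Permutation nulls and gene statistics

Null distributions for any domain statistic are built by translating every
domain by ±50 kb or ±100 kb (sign and magnitude redrawn per domain per
round), which preserves the genome-wide distribution pattern of the domains
— the reason this null is preferred over uniform shuffles. Domains pushed
past a chromosome end are mirrored back inside so lengths and counts are
always conserved; a shifted interval that would straddle the chromosome
start or end is slid to the nearest in-bounds position of the same length
(a rare event at the magnitudes used). Empirical p-values use the +1
correction and are never 0. Expression comparisons use the Mann-Whitney
U test (midranks, tie-corrected normal approximation with continuity
correction, exact enumeration for small untied designs). Expression-matched
control gene sets are drawn per quantile bin of the enriched-gene
expression distribution, without replacement while a bin's pool lasts.
Chromatin-loop anchors belong to a domain when more than half their bp lie
inside it; loops are intra-domain, across-boundary, or outside.

### Metaprofiles

Boundary profiles lay 100-bp windows across ±20 kb of every domain border,
mirrored so positive positions always point into the domain; for binary
marks the profile is the percent of boundaries whose window overlaps the
mark. Methylation metaplots linearly rescale each TE body onto 40 bins
(each bin averages the 100-bp windows overlapping its span, so TEs of any
length contribute to every bin; minus-strand TEs are reversed) and average
across TEs per group and genotype. Flanking regions around TE bodies are
not included by default — the body-only display is the one the grouping
analysis needs — and profiles are descriptive, without attached tests,
matching how such figures are read.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale, with full ground truth. Defaults (all in `sim_config()`):

* **Genome**: 5 chromosomes x 3 Mb (< 1% of a real plant genome but enough
  to preserve multi-chromosome logic), pericentromere = central 20% of each
  chromosome, centromere = its central third.
* **True domains**: log-normal lengths (median 9 kb, log-sd 0.4), covering
  15% of the arm bp — the middle of the reported 10–20% genome coverage and
  7–12 kb median-size ranges — placed with at least 6 kb (2 x G) spacing so
  distinct domains remain separable by the caller. Most of the domain mass
  (80%) concentrates in one or two contiguous zones per arm at local
  coverage 0.6: interstitial periphery-associated regions cluster on real
  chromosome arms, and this clustering is what gives 20-kb compartment
  labels their contiguous, recoverable block structure.
* **Fragments**: 2e5 per sample, 200 bp, drawn from a piecewise-constant
  intensity; GFP intensity is 3-fold the baseline inside true domains and
  pericentromeres (the real enrichment factor is not quantified anywhere,
  so the fold is a free parameter; 3 is a realistic pulldown contrast),
  IgG is uniform.
* **Annotation**: protein-coding genes uniform (1/5 kb), TE genes 4x denser
  inside peripheral regions than outside, log-normal expression with truly
  enriched protein-coding genes drawn from a lower-mean component.
* **Hi-C**: 20-kb bins; a bin is truly peripheral when >= 50% of it overlaps
  domains or pericentromere; `contact = decay(d) * (1 + 0.6 * same
  compartment) * exp(N(0, 0.1))`. The decay is a power law that plateaus at
  60 kb: on a 1/5-scale genome the decay range must shrink accordingly,
  otherwise a smooth genome-wide gradient dominates the correlation matrix
  and PC1 reads out position rather than compartment.
* **Methylation**: 100-bp beta-distributed ratios over TE bodies with
  CG > CHG > CHH and higher levels on peripheral TEs; each TE carries one
  CHH pathway class (peripheral TEs are CMT2-dependent with probability
  0.8, interior TEs RdDM-dependent with the same bias — the real preference
  is a tendency, not a partition). The cmt2-like genotype retains 20% of
  CHH on CMT2-dependent TEs only; drm12-like mirrors this on RdDM-dependent
  TEs; met1-like zeroes CG; cmt3-like retains 10% of CHG.
* **Loops**: 35% intra-domain, 15% domain-to-outside, the rest outside,
  spans <= 200 kb.

All randomness flows from one root seed through fixed per-component
substreams, so identical (config, seed) reproduces every file byte for
byte.

### What the generator does *not* emulate

Fragments are placed independently (no restriction-site structure, no
chromatin accessibility bias, no PCR duplicates); annotation ignores
overlapping isoforms and introns; Hi-C has no TADs, no inter-chromosomal
contacts and no coverage bias needing balancing; methylation is emitted as
ratios, skipping bisulfite-read noise. Passing recovery tests therefore
demonstrates that the pipeline's inference machinery is correct under its
own model assumptions — not that those assumptions capture every property
of real RE-ChIP data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; GFF3 converts on read.
* Dense Hi-C matrices are symmetrized by averaging when asymmetry exceeds
  1e-9, with a warning; NA cells propagate as masked bins that carry no
  compartment label.
* Zero-variance correlation rows are masked before PCA; the leading
  eigenvector must satisfy its eigen-equation to 1e-8.
* An empty domain set yields coverage 0 and an undefined (NA) median; an
  empty IgG control downgrades island scoring to background-only with a
  warning; a constant periphery signal leaves PC1 unoriented with a
  warning.
* The >80% and >50% membership rules are strict inequalities; boundary
  cases (exactly 80% gene overlap, exactly half an anchor) are excluded by
  construction and covered by tests.

## Problem sizes

The test-suite and acceptance runs use the default conditions above: the
domain-recovery run bins 4 x 2e5 fragments and completes in seconds; island-
caller equivalence checks 50 random 500-window tracks against a direct-scan
oracle; permutation calibration uses 200 independent simulations of 30
domains x 400 genes at 49 rounds each; compartment recovery scores all ten
60-bin arms. These sizes were chosen so the whole suite stays interactive
while every statistic is estimated with comfortable margins.

## Known limitations

* The island caller follows the published island framework (eligibility,
  gap chaining, Poisson island scoring, BH) but is not a line-for-line port
  of any particular SICER release; W, G and the FDR are fixed to the study
  settings and the remaining internals are documented above.
* Arms shorter than 10 Hi-C bins are skipped; compartment calls on such
  stubs would be meaningless.
* The 1-Mb pericentromere-distance filter is kept at its real-genome value
  even on the desk-scale synthetic genome, where it is deliberately harsh
  (few domains survive it); analyses that need more power on synthetic data
  use the unfiltered arm domains.
* `tissue_overlap` compares enriched-gene sets between runs; the package
  does not model tissue-specific biology — different tissues are emulated
  as independent fragment draws over a shared truth.
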