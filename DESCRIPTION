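Package: plads
Title: Calling and Characterising Nuclear-Periphery-Associated Chromatin Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for restriction-enzyme ChIP-seq (RE-ChIP)
    profiling of chromatin tethered to the plant nuclear periphery. Builds
    normalized treatment/control coverage tracks, calls broad enriched domains
    with a SICER-style island caller (1-kb windows, 3-kb gaps, Benjamini-
    Hochberg FDR), intersects replicates into periphery-associated domains,
    relates them to Hi-C A/B compartments via Spearman-correlation PCA,
    quantifies gene and transposable-element enrichment against coordinate-
    shift permutation nulls, classifies chromatin loops relative to domains,
    and computes boundary-anchored and length-normalised DNA-methylation
    metaprofiles. Ships a synthetic-data generator that emulates the full
    input suite (fragments, annotation, Hi-C, methylation, loops) with ground
    truth, so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
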