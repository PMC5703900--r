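Package: enhancerscape
Title: Enhancer Landscapes and lncRNA Classification During Mesendoderm
    Specification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping active enhancer landscapes and classifying
    long non-coding RNAs from histone-mark ChIP-seq and RNA-seq data, as
    used to study embryonic stem cell to mesendoderm differentiation.
    Implements Poisson background calling of H3K27Ac-enriched 25-bp bins
    with a fold-over-input filter, constituent-enhancer assembly and
    ROSE-style super-enhancer stitching with the slope-1 rank cutoff,
    four-way epigenomic classification of lncRNAs (promoter-, super-
    enhancer-, typical-enhancer-associated, or unmarked), the normalized
    difference (ND) cell-specificity statistic, heart- and tissue-
    enrichment scores on a 12-tissue expression panel, and fragment-level
    phastCons/phyloP conservation scoring. A seeded synthetic-data
    generator plants enhancers, condition-specific transcripts,
    tissue-enriched genes and conserved promoters in a toy genome so the
    whole pipeline can be exercised and benchmarked without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
biocViews: ChIPSeq, RNASeq, Epigenetics, GeneRegulation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
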