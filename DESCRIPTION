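Package: wgbsdmr
Title: Differential DNA Methylation Analysis for Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for two-sample whole-genome bisulfite
    sequencing (WGBS) studies in plants: bisulfite read simulation with
    planted ground truth, a bisulfite-aware unique read aligner, CG/CHG/CHH
    cytosine-context methylation calling with binomial site tests against the
    measured conversion failure rate, genome-element annotation (promoters
    with proximal/intermediate/distal subregions and CpG-density classes,
    exons, introns, intergenic tiles, CpG islands and shores), chi-squared
    differentially methylated region (DMR) calling with Benjamini-Hochberg
    FDR and fold-change filters, differentially methylated gene mapping,
    hypergeometric term enrichment, average-linkage clustering of methylation
    profiles, miRNA-promoter differential methylation, and bisulfite-PCR
    clone validation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
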