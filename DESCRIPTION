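Package: srevar
Title: Rare-Variant Association Testing for Splicing Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based association analysis of rare single-nucleotide
    variants that fall in splicing regulatory elements (SREs). SNPs are
    classified as exonic or intronic against gene models and annotated by
    matching exonic splicing enhancer (ESE), exonic splicing silencer (ESS)
    and intronic splicing enhancer (ISE) hexamer motif catalogs against the
    11-mer reference window around each site. Rare variants (minor allele
    frequency below 1 percent) are grouped into gene-level bins and tested
    against a continuous phenotype with a from-scratch SKAT-O (optimal
    sequence kernel association test) supporting covariate adjustment,
    Benjamini-Hochberg false-discovery-rate control, per-locus leave-one-out
    contribution analysis, and Manhattan-plot summaries. A synthetic cohort
    generator (genome, gene models, motif lists, VCF, phenotypes, truth
    table) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
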