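Package: lsblscan
Title: Locus-Specific Branch Length Selection Scans for SNP Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting signatures of positive selection in
    structured populations from biallelic SNP array genotypes. Implements
    the Reich-Hudson unbiased F_ST estimator from allele counts, per-SNP
    locus-specific branch length (LSBL) statistics under a three-group
    contrast, empirical top-fraction outlier calling, flanking-window
    candidate-region annotation with hypergeometric gene-set enrichment,
    per-population diversity statistics (expected heterozygosity,
    proportion of polymorphic markers, rarefaction allelic richness),
    LD-based SNP pruning, allele-sharing distances with neighbor-joining
    trees, and a Balding-Nichols genotype simulator with planted selected
    loci for end-to-end validation. Reads and writes PLINK text PED/MAP
    panels, BED/GFF3 gene models and GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    fgsea,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
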