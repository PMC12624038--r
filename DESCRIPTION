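Package: varpanel
Title: Variant Filtering, Diversity Statistics and Minimal Discriminating
    SNP Panels for Multi-Sample Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis toolkit for small plant cohorts
    genotyped against a single reference: GATK-style hard filtering of SNPs
    and InDels, per-chromosome variant counts with rate and density,
    substitution and InDel-length spectra, windowed nucleotide diversity,
    Watterson's theta and Tajima's D, allele-sharing distances with
    neighbor-joining and UPGMA trees, per-chromosome SNP-density profile
    clustering, screening of HIGH-impact variants against QTL intervals,
    and selection of minimal SNP panels that discriminate every variety
    (seeded greedy random-restart heuristic plus an exact exhaustive
    solver). A seeded synthetic-cohort generator with full ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
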