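Package: asepo
Title: Allele-Specific Expression Tables and Parent-of-Origin Testing
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the post-alignment stages of allele-specific
    expression (ASE) analysis from per-SNP allelic read counts. Parses
    GATK ASEReadCounter count tables, sample sheets and (optionally
    phased) VCF genotypes; builds per-gene union-exon models from a GTF
    and annotates SNPs against them; estimates cross-sample and maternal
    contamination from homozygous sites; applies read-depth and
    contamination filters; and tests each gene for parent-of-origin
    (imprinting-like) expression bias with a cluster-robust quasi-Poisson
    regression whose SNP indicator design is rank-reduced by singular
    value decomposition. A built-in simulator generates ASE datasets with
    known parent-of-origin effects, genetic allelic effects,
    within-subject correlation, overdispersion and contamination so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    ggplot2,
    optparse
Config/testthat/edition: 3
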