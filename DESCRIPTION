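Package: aselink
Title: Allele-Specific Expression Quantification and Cis-Regulatory Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies allele-specific expression (ASE) from reads
    overlapping phased heterozygous SNPs, reporting per-locus allelic
    ratios and signed binomial allelic scores, and links allele-specific
    loci within genomic windows into candidate cis-regulatory pairs with
    an enhancing or repressive mechanism call and a linkage score.
    Includes proximity-enrichment and linkage-distance characterization,
    eQTL confirmation, GWAS-variant intersection, TAD co-localization,
    enhancer co-occurrence, cross-sample mechanism consistency,
    saturation curves, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    yaml,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
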