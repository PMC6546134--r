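Package: sumstatsim
Title: Direct Simulation of Case-Control GWAS Summary Statistics from
    Reference Haplotypes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates genome-wide association study (GWAS) summary
    statistics (Z scores, log odds ratios, standard errors and p-values)
    for a genomic region directly from phased reference haplotype
    frequencies and a user-specified multi-SNP causal model, without
    generating individual-level genotype data.  The expected
    Cochran-Armitage score statistic at every SNP is derived by
    conditioning on case-control ascertainment; sampling variability is
    added by multivariate normal draws with the regional linkage
    disequilibrium correlation structure, and per-SNP variances follow a
    method-of-moments inverse-gamma model.  Includes an individual-level
    forward-simulation oracle (score test and per-SNP logistic Wald fits)
    for validation, a synthetic reference-panel generator with controlled
    minor allele frequencies and pairwise LD, IMPUTE2 .hap/.legend and
    phased VCF input, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
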