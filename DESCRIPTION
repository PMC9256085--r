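Package: methylcaste
Title: Spike-In Calibrated RRBS Methylation Analysis for Caste and Age
    Structured Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for reduced representation bisulfite
    sequencing (RRBS) CpG methylomes from replicated caste/colony designs,
    as found in social insects. Reads Bismark-style coverage files, GFF3
    gene and repeat annotations, sample sheets and expression tables;
    estimates bisulfite non-conversion from unmethylated spike-in controls
    and calls per-CpG methylation by FDR-corrected binomial tests against
    the non-conversion floor; classifies CpGs into genomic region classes
    with exon/intron ranks and flank bins; summarises region-level and
    meta-gene methylation structure; tests per-site differential
    methylation between replicated groups with a likelihood-ratio binomial
    test, percentage-point effect thresholds and a randomized-grouping
    null for site counts; and links methylation to expression through
    overlap statistics, rank correlations, weighted binomial regressions,
    principal component analysis and variance partitioning. Ships a fully
    specified synthetic-study generator (annotation, methylomes, spike-ins,
    expression with planted effects) so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    lme4,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
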