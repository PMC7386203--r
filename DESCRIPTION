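Package: pwasR
Title: Proteome-Wide Association Studies from Variant Effect Scores
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-level association testing on predicted protein-function
    damage. Per-variant functional effect scores (0 = complete loss of
    function, 1 = intact) are combined with per-sample genotype
    probabilities and aggregated into per-sample, per-gene dominant and
    recessive functional effect scores under a probabilistic two-hit
    model that captures compound heterozygosity. Gene scores are tested
    against binary or continuous phenotypes by covariate-adjusted linear
    or logistic regression (dominant, recessive, and generalized joint
    models) with Benjamini-Hochberg FDR control and standardized effect
    sizes. Includes a synthetic-cohort generator (Hardy-Weinberg
    genotypes, configurable consequence mix and allele frequencies) and a
    statistical power simulation framework over cohort size, effect size,
    and variant-score noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    VariantAnnotation,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GenomeWideAssociationStudies, SNP, Genetics, Software,
    StatisticalMethod, VariantAnnotation
RoxygenNote: 7.3.3
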