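Package: teqtl
Title: Trans-eQTL Scanning of Transposable-Element Subfamily Expression and
    SNV-Gene-TE Trio Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico scan for candidate regulators of transposable-element
    (TE) subfamily RNA levels. Integrates genome-wide SNV genotypes with gene
    and TE-subfamily expression: variant QC (MAF, exact Hardy-Weinberg test),
    LD pruning and genotype PCA, expression filtering, normalization,
    covariate residualization and inverse normal transform, cis- and
    trans-association scans with Benjamini-Hochberg and permutation-averaged
    empirical FDR, SNV-gene-TE trio integration with LD clumping and index-SNV
    tiering, SNV-gene-TE mediation analysis with permutation p-values,
    genotype-stratified differential expression with TE family / age / region
    gene-set enrichment (weighted Kolmogorov-Smirnov), trait-category
    enrichment of hit SNVs against random SNV combinations, and a synthetic
    cohort generator with planted cis, trans and mediated effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
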